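## Morphometry of photoreceptor terminals and their mitochondria from
## label/mask images: per-terminal areas, mitochondrial counts and sizes,
## and occupancy (mitochondrial area / terminal area).

#' Measure terminals and their mitochondria
#'
#' Terminal area is the label's pixel count times the squared pixel size;
#' mitochondria are the 8-connected components of the mitochondria mask,
#' each assigned to the terminal owning the majority of its pixels. A
#' component lying wholly outside every terminal is assigned, with a
#' warning, to the nearest terminal within `outside_tol_px`; beyond that it
#' is an error.
#'
#' @param terminal_labels integer matrix; 0 = background, k > 0 = terminal k.
#' @param mito_mask logical matrix of mitochondrial profiles.
#' @param pixel_size_um micrometres per pixel.
#' @param type_map named character vector mapping terminal label (as
#'   character) to "rod" or "cone"; unnamed labels default to "rod".
#' @param outside_tol_px tolerance for out-of-terminal mitochondria
#'   (default 2).
#' @return object of class `terminal_measures`: list of data frames
#'   `terminals` (terminal_id, terminal_type, terminal_area_um2,
#'   mito_count, mito_area_um2, occupancy) and `mitochondria`
#'   (terminal_id, mito_id, area_um2).
#' @export
measure_terminals <- function(terminal_labels, mito_mask, pixel_size_um,
                              type_map = NULL, outside_tol_px = 2L) {
  assert_num1(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  if (!all(dim(terminal_labels) == dim(mito_mask))) {
    stop("terminal labels and mitochondria mask must share dimensions",
         call. = FALSE)
  }
  labs <- sort(setdiff(unique(as.integer(terminal_labels)), 0L))
  if (!length(labs)) stop("no labelled terminals", call. = FALSE)
  mito_mask <- mito_mask > 0

  mlab <- label8(mito_mask)
  n_mito <- max(mlab)
  assign_to <- integer(n_mito)
  areas_px <- tabulate(mlab[mlab > 0L], nbins = n_mito)
  for (i in seq_len(n_mito)) {
    under <- terminal_labels[mlab == i]
    owners <- under[under > 0L]
    if (length(owners)) {
      assign_to[i] <- as.integer(names(which.max(table(owners))))
    } else {
      ## search outward up to the tolerance
      grown <- mlab == i
      found <- 0L
      for (d in seq_len(outside_tol_px)) {
        grown <- dilate_px(grown, 1L)
        near <- terminal_labels[grown]
        near <- near[near > 0L]
        if (length(near)) {
          found <- as.integer(names(which.max(table(near))))
          break
        }
      }
      if (found == 0L) {
        stop("mitochondrion component ", i, " lies more than ",
             outside_tol_px, " px from any terminal", call. = FALSE)
      }
      warning("mitochondrion component ", i,
              " lies outside every terminal; assigned to nearest terminal ",
              found)
      assign_to[i] <- found
    }
  }

  term_type <- function(k) {
    tm <- type_map[as.character(k)]
    if (is.null(type_map) || is.na(tm)) "rod" else unname(tm)
  }
  terminals <- do.call(rbind, lapply(labs, function(k) {
    t_area <- sum(terminal_labels == k) * pixel_size_um^2
    mi <- which(assign_to == k)
    m_area <- sum(areas_px[mi]) * pixel_size_um^2
    data.frame(terminal_id = k, terminal_type = term_type(k),
               terminal_area_um2 = t_area,
               mito_count = length(mi),
               mito_area_um2 = m_area,
               occupancy = m_area / t_area,
               stringsAsFactors = FALSE)
  }))
  mitochondria <- if (n_mito) {
    data.frame(terminal_id = assign_to,
               mito_id = seq_len(n_mito),
               area_um2 = areas_px * pixel_size_um^2)
  } else {
    data.frame(terminal_id = integer(), mito_id = integer(),
               area_um2 = numeric())
  }
  structure(list(terminals = terminals, mitochondria = mitochondria,
                 pixel_size_um = pixel_size_um),
            class = "terminal_measures")
}

#' Summarize terminal morphometry by group
#'
#' Group means with SEM (sd / sqrt(n)) of mitochondrial size and terminal
#' size, the mitochondria-per-terminal count distribution, and (for exactly
#' two groups) an unpaired Welch t-test on terminal area and mitochondrial
#' size.
#'
#' @param measures a `terminal_measures` object (see [measure_terminals()])
#'   or a data frame shaped like its `terminals` element.
#' @param grouping column of the terminal table to group by (default
#'   `"terminal_type"`).
#' @return object of class `morphometry_summary`: list with `by_group`
#'   (data frame of means and SEMs), `count_histogram` (table of
#'   mitochondria-per-terminal by group) and `tests` (Welch two-sided
#'   p-values when two groups are present).
#' @export
summarize_morphometry <- function(measures, grouping = "terminal_type") {
  term <- if (inherits(measures, "terminal_measures")) measures$terminals
          else measures
  if (!grouping %in% names(term)) {
    stop("grouping column not found: ", grouping, call. = FALSE)
  }
  mito <- if (inherits(measures, "terminal_measures")) measures$mitochondria
          else NULL
  g <- factor(term[[grouping]])
  if (any(table(g) == 0L) || !nlevels(g)) {
    stop("every group needs at least one measure", call. = FALSE)
  }
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  by_group <- do.call(rbind, lapply(levels(g), function(lv) {
    rows <- term[g == lv, , drop = FALSE]
    msz <- if (!is.null(mito)) {
      mito$area_um2[mito$terminal_id %in% rows$terminal_id]
    } else numeric(0)
    data.frame(group = lv,
               n_terminals = nrow(rows),
               mean_terminal_area_um2 = mean(rows$terminal_area_um2),
               sem_terminal_area_um2 = sem(rows$terminal_area_um2),
               mean_mito_count = mean(rows$mito_count),
               mean_mito_area_um2 = if (length(msz)) mean(msz) else NA_real_,
               sem_mito_area_um2 = if (length(msz)) sem(msz) else NA_real_,
               mean_occupancy = mean(rows$occupancy),
               sem_occupancy = sem(rows$occupancy),
               stringsAsFactors = FALSE)
  }))
  hist_tab <- table(group = g, mito_count = term$mito_count)
  tests <- NULL
  if (nlevels(g) == 2L && all(table(g) >= 2L)) {
    lv <- levels(g)
    a <- term[g == lv[1], ]; b <- term[g == lv[2], ]
    tests <- list(
      terminal_area_p = stats::t.test(a$terminal_area_um2,
                                      b$terminal_area_um2)$p.value,
      occupancy_p = stats::t.test(a$occupancy, b$occupancy)$p.value
    )
    if (!is.null(mito)) {
      ma <- mito$area_um2[mito$terminal_id %in% a$terminal_id]
      mb <- mito$area_um2[mito$terminal_id %in% b$terminal_id]
      if (length(ma) >= 2L && length(mb) >= 2L) {
        tests$mito_area_p <- stats::t.test(ma, mb)$p.value
      }
    }
  }
  structure(list(by_group = by_group, count_histogram = hist_tab,
                 tests = tests),
            class = "morphometry_summary")
}
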