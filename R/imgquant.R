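## Confocal quantification: maximum projection, layer segmentation,
## compartmental intensities, TUNEL counting and ONL thickness.

#' Maximum intensity projection of a z-stack
#'
#' @param zstack a 3-D array (rows x cols x slices) or a list of matrices.
#' @return matrix of per-pixel maxima across slices.
#' @export
project_stack <- function(zstack) {
  if (is.list(zstack)) {
    if (!length(zstack)) stop("empty stack", call. = FALSE)
    out <- zstack[[1]]
    for (s in zstack[-1]) out <- pmax(out, s)
    return(out)
  }
  if (length(dim(zstack)) == 2L) return(zstack)
  if (length(dim(zstack)) != 3L || dim(zstack)[3] < 1L) {
    stop("empty stack", call. = FALSE)
  }
  apply(zstack, c(1, 2), max)
}

## largest run of TRUE in a logical vector; returns c(start, end) or NULL.
## `gap_tol` bridges runs separated by at most that many FALSEs.
longest_run <- function(flag, gap_tol = 0L) {
  if (gap_tol > 0L) {
    r <- rle(flag)
    short_gap <- !r$values & r$lengths <= gap_tol
    ## only bridge gaps strictly between TRUE runs
    inner <- seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
    r$values[short_gap & inner] <- TRUE
    flag <- inverse.rle(r)
  }
  r <- rle(flag)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  c(starts[best], ends[best])
}

#' Segment retinal layers into ONL/OPL/IS masks
#'
#' The OPL band is found from the thresholded union of the synaptic marker
#' channels (e.g. PSD95 and vGlut1) as the dominant horizontal band; the IS
#' band likewise from its marker on the scleral side of the OPL; the ONL is
#' the nuclei-dense band between them (or, without an IS marker, the extent
#' of the nuclei band adjacent to the OPL on the scleral side, with the IS
#' taken as a fixed-thickness band above it). Masks are full-width
#' horizontal bands, pairwise disjoint by construction. Row 1 is the
#' scleral side.
#'
#' @param nuclei_channel matrix (DAPI-like channel).
#' @param opl_marker_channels matrix or list of matrices.
#' @param pixel_size_um micrometres per pixel.
#' @param is_marker_channel optional matrix (e.g. a mitochondrial marker of
#'   the inner segments).
#' @param params list overriding `blur_sigma_px` (default 1),
#'   `threshold` ("otsu" or fixed value), `band_coverage` (default 0.5,
#'   row-coverage fraction defining a band), `nucleus_diameter_um`
#'   (default 5, small-object gate for the nuclei mask),
#'   `is_thickness_um` (default 20, fallback IS thickness).
#' @return a [layer_masks()] object.
#' @export
segment_layers <- function(nuclei_channel, opl_marker_channels, pixel_size_um,
                           is_marker_channel = NULL, params = list()) {
  p <- utils::modifyList(list(blur_sigma_px = 1, threshold = "otsu",
                              band_coverage = 0.5, nucleus_diameter_um = 5,
                              is_thickness_um = 20),
                         params)
  markers <- if (is.matrix(opl_marker_channels)) list(opl_marker_channels)
             else opl_marker_channels
  dims <- dim(nuclei_channel)
  for (ch in c(markers, if (!is.null(is_marker_channel)) list(is_marker_channel))) {
    if (!all(dim(ch) == dims)) stop("channels must share dimensions", call. = FALSE)
  }
  h <- dims[1]; w <- dims[2]

  band_from <- function(channel, name, restrict_rows = NULL) {
    mask <- threshold_mask(gaussian_blur(channel, p$blur_sigma_px), p$threshold)
    cov <- rowMeans(mask)
    if (!is.null(restrict_rows)) cov[-restrict_rows] <- 0
    run <- longest_run(cov > p$band_coverage)
    if (is.null(run)) {
      stop(sprintf("no detectable %s band in its marker channel", name),
           call. = FALSE)
    }
    run
  }

  opl_union <- Reduce(pmax, markers)
  opl_run <- band_from(opl_union, "OPL")

  if (opl_run[1] <= 2L) {
    stop("no room on the scleral side of the OPL band", call. = FALSE)
  }
  scleral_rows <- 1:(opl_run[1] - 1L)

  if (!is.null(is_marker_channel)) {
    is_run <- band_from(is_marker_channel, "IS", restrict_rows = scleral_rows)
    onl_rows <- if (is_run[2] + 1L <= opl_run[1] - 1L) {
      (is_run[2] + 1L):(opl_run[1] - 1L)
    } else integer(0)
  } else {
    ## ONL from the nuclei band adjacent to the OPL; IS as a fixed band above
    nuc_mask <- threshold_mask(gaussian_blur(nuclei_channel, p$blur_sigma_px),
                               p$threshold)
    lab <- label8(nuc_mask)
    min_px <- 0.25 * pi * (p$nucleus_diameter_um / 2 / pixel_size_um)^2
    keep <- which(tabulate(lab[lab > 0L]) >= min_px)
    nuc_mask <- matrix(lab %in% keep, h, w)
    present <- rowSums(nuc_mask) > 0
    present[-scleral_rows] <- FALSE
    gap <- ceiling(p$nucleus_diameter_um / pixel_size_um / 2)
    ## scan upward from the OPL with gap tolerance
    run <- NULL
    r <- opl_run[1] - 1L
    while (r >= 1L && !present[r]) r <- r - 1L
    if (r >= 1L) {
      top <- r
      misses <- 0L
      rr <- r
      while (rr >= 1L && misses <= gap) {
        if (present[rr]) { top <- rr; misses <- 0L } else misses <- misses + 1L
        rr <- rr - 1L
      }
      run <- c(top, opl_run[1] - 1L)
    }
    if (is.null(run)) {
      stop("no nuclei-dense band found on the scleral side of the OPL",
           call. = FALSE)
    }
    onl_rows <- run[1]:run[2]
    is_px <- round(p$is_thickness_um / pixel_size_um)
    is_run <- c(max(1L, run[1] - is_px), run[1] - 1L)
    if (is_run[2] < is_run[1]) is_run <- NULL
  }

  ## verify the ONL band is nuclei-dense
  if (!length(onl_rows) ||
      mean(nuclei_channel[onl_rows, ]) <= mean(nuclei_channel)) {
    stop("no nuclei-dense band between the IS and OPL bands", call. = FALSE)
  }

  layer_masks(
    onl = band_mask(h, w, onl_rows),
    opl = band_mask(h, w, opl_run[1]:opl_run[2]),
    is_mask = if (is.null(is_run)) matrix(FALSE, h, w)
              else band_mask(h, w, is_run[1]:is_run[2]),
    pixel_size_um = pixel_size_um,
    source = list(method = "band-segmentation", params = p)
  )
}

#' Mean fluorescence intensity per compartment
#'
#' Overlays the layer masks on a channel as ROIs and reports the arithmetic
#' mean pixel value and calibrated area per compartment.
#'
#' @param channel matrix.
#' @param masks a [layer_masks()] object.
#' @param compartments subset of `c("ONL", "OPL", "IS")`.
#' @return data frame with `compartment`, `mean_intensity`, `area_um2`.
#' @export
mean_intensity <- function(channel, masks, compartments = c("ONL", "OPL", "IS")) {
  stopifnot(inherits(masks, "layer_masks"))
  if (!all(dim(channel) == dim(masks$onl_mask))) {
    stop("channel and masks must share dimensions", call. = FALSE)
  }
  sel <- list(ONL = masks$onl_mask, OPL = masks$opl_mask, IS = masks$is_mask)
  compartments <- match.arg(compartments, several.ok = TRUE)
  rows <- lapply(compartments, function(cp) {
    m <- sel[[cp]]
    if (!any(m)) stop("requested compartment mask is empty: ", cp, call. = FALSE)
    data.frame(compartment = cp,
               mean_intensity = mean(channel[m]),
               area_um2 = sum(m) * masks$pixel_size_um^2)
  })
  do.call(rbind, rows)
}

#' Count TUNEL-positive nuclei in a region
#'
#' Thresholds the TUNEL channel inside the region, labels 8-connected
#' objects, and counts those whose area lies within
#' `[0.25, 4] x` the nominal nucleus area. Overlapping nuclei that merge
#' into one component are counted once.
#'
#' @param tunel_channel matrix.
#' @param region_mask logical matrix (e.g. the ONL mask, or the full
#'   section).
#' @param pixel_size_um micrometres per pixel.
#' @param params list overriding `blur_sigma_px` (1), `threshold`
#'   ("otsu" or fixed), `nucleus_diameter_um` (5), `size_gate`
#'   (`c(0.25, 4)`).
#' @return integer count.
#' @export
count_tunel <- function(tunel_channel, region_mask, pixel_size_um,
                        params = list()) {
  p <- utils::modifyList(list(blur_sigma_px = 1, threshold = "otsu",
                              nucleus_diameter_um = 5, size_gate = c(0.25, 4)),
                         params)
  if (!all(dim(tunel_channel) == dim(region_mask))) {
    stop("channel and region mask must share dimensions", call. = FALSE)
  }
  if (!any(region_mask > 0)) stop("region mask is empty", call. = FALSE)
  mask <- threshold_mask(gaussian_blur(tunel_channel, p$blur_sigma_px),
                         p$threshold)
  mask <- mask & (region_mask > 0)
  if (!any(mask)) return(0L)
  lab <- label8(mask)
  sizes <- tabulate(lab[lab > 0L])
  nominal <- pi * (p$nucleus_diameter_um / 2 / pixel_size_um)^2
  sum(sizes >= p$size_gate[1] * nominal & sizes <= p$size_gate[2] * nominal)
}

#' ONL thickness at randomized grid positions
#'
#' Chooses three column positions by seeded sampling from a regular column
#' grid (the grid-overlay randomization) and measures the vertical extent
#' of the ONL mask at each, in micrometres.
#'
#' @param masks a [layer_masks()] object whose ONL mask is a single band.
#' @param seed integer seed for the grid randomization.
#' @param n_positions measurements per image (default 3).
#' @param grid_spacing_px spacing of the candidate column grid (default 16).
#' @param max_retries resamples allowed when the ONL is absent at a sampled
#'   column (default 10), after which an error is thrown.
#' @return object of class `thickness_result`: list with
#'   `per_position_thickness_um`, `mean_um`, `positions` (columns used).
#' @export
measure_onl_thickness <- function(masks, seed = 1L, n_positions = 3L,
                                  grid_spacing_px = 16L, max_retries = 10L) {
  stopifnot(inherits(masks, "layer_masks"))
  onl <- masks$onl_mask
  w <- ncol(onl)
  grid <- seq.int(max(1L, grid_spacing_px %/% 2L), w, by = grid_spacing_px)
  if (length(grid) < n_positions) {
    stop("column grid too coarse for ", n_positions, " positions", call. = FALSE)
  }
  ext <- colSums(onl)
  withr::with_seed(seed, {
    chosen <- integer(0)
    pool <- grid
    retries <- 0L
    while (length(chosen) < n_positions) {
      if (!length(pool) || retries > max_retries) {
        stop("ONL absent at sampled grid columns after ", retries,
             " retries", call. = FALSE)
      }
      cand <- sample(pool, 1L)
      pool <- setdiff(pool, cand)
      if (ext[cand] > 0) {
        chosen <- c(chosen, cand)
      } else {
        warning("ONL absent at sampled column ", cand, "; resampling")
        retries <- retries + 1L
      }
    }
    th <- ext[chosen] * masks$pixel_size_um
    structure(list(per_position_thickness_um = unname(th),
                   mean_um = mean(th),
                   positions = chosen),
              class = "thickness_result")
  })
}
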