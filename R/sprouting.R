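## Dendritic-sprouting quantification. Pipeline: Gaussian blur -> threshold
## -> binary mask -> candidate extraction inside the ONL -> skeletonization
## -> calibrated path-length measurement. A candidate counts as a sprout
## only when it is rooted at the OPL/ONL boundary and penetrates the ONL by
## at least one nucleus diameter.

#' Quantify bipolar-dendrite sprouting into the ONL
#'
#' Candidate sprouts are 8-connected components of the thresholded bipolar
#' signal inside the ONL that touch the OPL/ONL boundary. A candidate is
#' retained only if it penetrates the ONL by at least
#' `min_penetration_um` (one nucleus diameter) measured normal to the
#' boundary. Each retained sprout is skeletonized and its calibrated
#' 8-connected path length reported; density is the retained sprout area
#' over the ONL area, as a percentage.
#'
#' @param bipolar_channel matrix (e.g. a PKC-alpha maximum projection).
#' @param masks a [layer_masks()] object.
#' @param params list overriding `blur_sigma_px` (default 1), `threshold`
#'   ("otsu" or a fixed value), `min_penetration_um` (default 5, one
#'   nucleus diameter), `min_branch_px` (default 3, minimum skeleton
#'   size), `root_tol_px` (default 2, distance to the boundary that still
#'   counts as rooted), `close_px` (default 1, closing radius bridging
#'   fragmented ridges) and `weak_frac` (default 0.5, hysteresis weak
#'   threshold as a fraction of the strong threshold above background).
#' @return object of class `sprouting_result`: list with `total_length_um`,
#'   `per_sprout_length_um`, `sprouted_area_um2`, `density_pct`,
#'   `n_sprouts`, and the retained `sprout_mask`.
#' @export
quantify_sprouting <- function(bipolar_channel, masks, params = list()) {
  stopifnot(inherits(masks, "layer_masks"))
  p <- utils::modifyList(list(blur_sigma_px = 1, threshold = "otsu",
                              min_penetration_um = 5, min_branch_px = 3L,
                              root_tol_px = 2L, close_px = 1L,
                              weak_frac = 0.35, boundary_margin_px = 2L),
                         params)
  if (!all(dim(bipolar_channel) == dim(masks$onl_mask))) {
    stop("channel and masks must share dimensions", call. = FALSE)
  }
  psz <- masks$pixel_size_um
  onl <- masks$onl_mask
  onl_area_px <- sum(onl)
  if (onl_area_px == 0) stop("ONL mask has zero area", call. = FALSE)

  empty <- structure(list(total_length_um = 0, per_sprout_length_um = numeric(0),
                          sprouted_area_um2 = 0, density_pct = 0,
                          n_sprouts = 0L,
                          sprout_mask = matrix(FALSE, nrow(onl), ncol(onl))),
                     class = "sprouting_result")

  blurred <- gaussian_blur(bipolar_channel, p$blur_sigma_px)
  strong <- threshold_mask(blurred, p$threshold)
  if (!any(strong)) return(empty)
  ## hysteresis: thin ridges dip below a global threshold along their
  ## length, so trace them through a weak threshold but keep only
  ## components anchored by strong pixels (the ridge-detection step)
  bg <- stats::median(blurred)
  th_strong <- if (is.numeric(p$threshold)) p$threshold else
    min(blurred[strong])
  th_weak <- bg + p$weak_frac * (th_strong - bg)
  weak <- blurred > th_weak

  ## boundary row: the vitreal edge of the ONL band (largest ONL row index).
  ## A thin strip above it is excluded from tracing: the blurred OPL plexus
  ## spills into it and would bridge all sprout roots into one component.
  boundary_row <- max(which(rowSums(onl) > 0))
  work_onl <- onl
  strip <- (boundary_row - p$boundary_margin_px + 1L):boundary_row
  work_onl[strip[strip >= 1L], ] <- FALSE

  cand <- weak & work_onl
  if (p$close_px > 0L) cand <- close_px(cand, p$close_px) & work_onl
  if (!any(cand)) return(empty)
  lab <- label8(cand)
  n_comp <- max(lab)
  if (n_comp == 0L) return(empty)

  comp_rows <- split(row(lab)[lab > 0L], lab[lab > 0L])
  per_len <- numeric(0)
  keep_labels <- integer(0)
  area_px <- 0L
  for (i in seq_len(n_comp)) {
    rows_i <- comp_rows[[as.character(i)]]
    comp <- lab == i
    if (!any(comp & strong)) next           # noise: no strong anchor
    rooted <- max(rows_i) >= boundary_row - p$boundary_margin_px - p$root_tol_px
    penetration_um <- (boundary_row - min(rows_i) + 1) * psz
    if (!rooted || penetration_um < p$min_penetration_um) next
    ## skeletonize on the component's padded bounding box for speed
    cols_i <- col(lab)[comp]
    rr <- max(1L, min(rows_i) - 1L):min(nrow(lab), max(rows_i) + 1L)
    cc <- max(1L, min(cols_i) - 1L):min(ncol(lab), max(cols_i) + 1L)
    skel <- skeletonize(lab[rr, cc, drop = FALSE] == i)
    if (sum(skel) < p$min_branch_px) next
    keep_labels <- c(keep_labels, i)
    ## a rooted component continues through the excluded boundary strip:
    ## add the vertical gap between its last row and the boundary
    root_gap_px <- boundary_row - max(rows_i)
    per_len <- c(per_len, (skeleton_length_px(skel) + root_gap_px) * psz)
    ## area from the strong mask: the weak halo traces, the core measures
    area_px <- area_px + sum(comp & strong)
  }
  if (!length(keep_labels)) return(empty)

  sprout_mask <- matrix(lab %in% keep_labels, nrow(lab), ncol(lab))
  structure(list(total_length_um = sum(per_len),
                 per_sprout_length_um = per_len,
                 sprouted_area_um2 = area_px * psz^2,
                 density_pct = 100 * area_px / onl_area_px,
                 n_sprouts = length(per_len),
                 sprout_mask = sprout_mask),
            class = "sprouting_result")
}

#' @export
print.sprouting_result <- function(x, ...) {
  cat(sprintf("Sprouting: %d sprout(s), total length %.1f um, density %.2f%% of ONL area\n",
              x$n_sprouts, x$total_length_um, x$density_pct))
  invisible(x)
}
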