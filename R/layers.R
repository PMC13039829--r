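#' Retinal layer masks
#'
#' Container for the binary compartment masks (ONL, OPL, IS) that define the
#' coordinate frame of all image quantification. Row 1 is the scleral (IS)
#' side, so the IS band sits above the ONL, which sits above the OPL.
#'
#' @param onl,opl,is_mask logical matrices of identical dimension.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @param source optional metadata list (e.g. channels used).
#' @return an object of class `layer_masks`.
#' @export
layer_masks <- function(onl, opl, is_mask, pixel_size_um, source = list()) {
  assert_num1(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  onl <- onl > 0; opl <- opl > 0; is_mask <- is_mask > 0
  if (!all(dim(onl) == dim(opl)) || !all(dim(onl) == dim(is_mask))) {
    stop("layer masks must share dimensions", call. = FALSE)
  }
  if (any(onl & opl) || any(onl & is_mask) || any(opl & is_mask)) {
    stop("layer masks must be pairwise disjoint", call. = FALSE)
  }
  structure(
    list(onl_mask = onl, opl_mask = opl, is_mask = is_mask,
         pixel_size_um = pixel_size_um, source = source),
    class = "layer_masks"
  )
}

#' @export
print.layer_masks <- function(x, ...) {
  psz <- x$pixel_size_um
  cat("Retinal layer masks (", nrow(x$onl_mask), "x", ncol(x$onl_mask),
      " px, ", psz, " um/px)\n", sep = "")
  for (nm in c("is_mask", "onl_mask", "opl_mask")) {
    cat(sprintf("  %-9s area %8.1f um^2\n", sub("_mask", "", nm),
                sum(x[[nm]]) * psz^2))
  }
  invisible(x)
}

## full-width horizontal band mask over the given (1-based, inclusive) rows
band_mask <- function(h, w, rows) {
  m <- matrix(FALSE, h, w)
  rows <- rows[rows >= 1 & rows <= h]
  if (length(rows)) m[rows, ] <- TRUE
  m
}
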