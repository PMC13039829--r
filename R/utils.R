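#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## scalar checks used across constructors
assert_num1 <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    stop(sprintf("'%s' must be %s %s", name, if (strict) ">" else ">=", lower),
         call. = FALSE)
  }
  invisible(x)
}

## deterministic child seed: keep well inside 32-bit integer range
child_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + k * 104729) %% 2147483647
}

## Otsu threshold guarded against constant images; returns a logical mask.
## `threshold` may be "otsu" or a fixed numeric value on the [0, 1] scale.
threshold_mask <- function(img, threshold = "otsu") {
  if (is.numeric(threshold)) return(img > threshold)
  rng <- range(img)
  if (diff(rng) < 1e-12) return(matrix(FALSE, nrow(img), ncol(img)))
  th <- EBImage::otsu(EBImage::Image(img), range = rng)
  img > th
}

gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  out <- EBImage::gblur(EBImage::Image(img), sigma = sigma_px)
  matrix(as.numeric(out), nrow(img), ncol(img))
}
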