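## ERG feature extraction. The a-wave amplitude is measured from the
## pre-flash baseline to the post-flash trough and the b-wave from the
## a-wave trough to the subsequent peak; implicit times are latencies from
## the flash. When a trace lacks a b-wave peak (degenerate retinas), the
## b-amplitude is read at a supplied reference implicit time (the control
## group's b-wave latency), still measured from the trough.

#' Extract a-wave and b-wave features from an ERG trace
#'
#' @param trace an [erg_trace()].
#' @param reference_implicit_ms optional latency (ms from flash) at which to
#'   read the b-amplitude instead of searching for a peak; used for traces
#'   lacking a b-wave peak, with the control group's b-wave implicit time
#'   as the reference.
#' @param params list overriding `baseline_window_ms` (default 50, the
#'   pre-flash averaging window), `a_window_ms` (default 80, the trough
#'   search window after the flash).
#' @return object of class `erg_features`: list with `a_amplitude_uV`,
#'   `a_implicit_ms`, `b_amplitude_uV`, `b_implicit_ms`, `b_a_ratio`
#'   (NA when the a-amplitude is 0) and `mode` ("peak" or "reference").
#' @export
extract_erg_features <- function(trace, reference_implicit_ms = NULL,
                                 params = list()) {
  stopifnot(inherits(trace, "erg_trace"))
  p <- utils::modifyList(list(baseline_window_ms = 50, a_window_ms = 80),
                         params)
  t <- trace$time_ms; v <- trace$voltage_uV
  flash <- trace$flash_time_ms

  base_idx <- which(t >= flash - p$baseline_window_ms & t < flash)
  if (!length(base_idx)) {
    stop("no pre-flash baseline window in the record", call. = FALSE)
  }
  baseline <- mean(v[base_idx])

  a_idx <- which(t > flash & t <= flash + p$a_window_ms)
  if (!length(a_idx)) stop("no samples after the flash", call. = FALSE)
  trough_i <- a_idx[which.min(v[a_idx])]
  if (trough_i >= length(t)) {
    stop("trough not found: record is monotone to its end after the flash",
         call. = FALSE)
  }
  a_amp <- max(0, baseline - v[trough_i])
  a_implicit <- t[trough_i] - flash

  if (is.null(reference_implicit_ms)) {
    post <- trough_i:length(t)
    peak_i <- post[which.max(v[post])]
    b_amp <- v[peak_i] - v[trough_i]
    b_implicit <- t[peak_i] - flash
    mode <- "peak"
  } else {
    t_ref <- flash + reference_implicit_ms
    if (t_ref < t[1] || t_ref > t[length(t)]) {
      stop("reference time lies outside the record", call. = FALSE)
    }
    ref_i <- which.min(abs(t - t_ref))
    b_amp <- max(0, v[ref_i] - v[trough_i])
    b_implicit <- reference_implicit_ms
    mode <- "reference"
  }
  structure(list(a_amplitude_uV = a_amp,
                 a_implicit_ms = a_implicit,
                 b_amplitude_uV = b_amp,
                 b_implicit_ms = b_implicit,
                 b_a_ratio = if (a_amp > 0) b_amp / a_amp else NA_real_,
                 mode = mode,
                 baseline_uV = baseline),
            class = "erg_features")
}

#' @export
print.erg_features <- function(x, ...) {
  cat(sprintf("ERG features (%s mode): a = %.1f uV @ %.1f ms, b = %.1f uV @ %.1f ms, b/a = %s\n",
              x$mode, x$a_amplitude_uV, x$a_implicit_ms, x$b_amplitude_uV,
              x$b_implicit_ms,
              if (is.na(x$b_a_ratio)) "NA" else sprintf("%.2f", x$b_a_ratio)))
  invisible(x)
}

#' Intensity-response table across groups
#'
#' Per flash intensity and group: mean feature value with SEM
#' (sd / sqrt(n)); for each intensity with two groups of n >= 2, an
#' unpaired two-sided t-test p-value (Welch by default, pooled-variance on
#' request). Intensities where any group has fewer than two traces are
#' flagged and not tested.
#'
#' @param traces list of [erg_trace()] objects carrying `group` labels.
#' @param feature which extracted feature to tabulate (default
#'   `"a_amplitude_uV"`).
#' @param reference_map optional named numeric vector `group ->`
#'   reference implicit time (ms) for groups lacking b-wave peaks.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param params passed to [extract_erg_features()].
#' @return data frame with one row per (intensity, group): `n`, `mean`,
#'   `sem`, plus per-intensity `p_value` and a logical `tested`.
#' @export
intensity_response <- function(traces, feature = "a_amplitude_uV",
                               reference_map = NULL, var_equal = FALSE,
                               params = list()) {
  vals <- vapply(traces, function(tr) {
    ref <- if (!is.null(reference_map) && tr$group %in% names(reference_map)) {
      reference_map[[tr$group]]
    } else NULL
    feats <- extract_erg_features(tr, reference_implicit_ms = ref,
                                  params = params)
    as.numeric(feats[[feature]])
  }, numeric(1))
  meta <- data.frame(
    intensity = vapply(traces, function(tr)
      tr$flash_intensity_log_photons_per_um2, numeric(1)),
    group = vapply(traces, function(tr) as.character(tr$group), character(1)),
    value = vals, stringsAsFactors = FALSE)

  out <- list()
  for (i_level in sort(unique(meta$intensity))) {
    sub <- meta[meta$intensity == i_level, ]
    by_g <- split(sub$value, sub$group)
    ns <- vapply(by_g, length, integer(1))
    tested <- length(by_g) == 2L && all(ns >= 2L)
    p_val <- if (tested) {
      stats::t.test(by_g[[1]], by_g[[2]], var.equal = var_equal)$p.value
    } else NA_real_
    for (gname in names(by_g)) {
      x <- by_g[[gname]]
      out[[length(out) + 1L]] <- data.frame(
        intensity = i_level, group = gname, n = length(x),
        mean = mean(x),
        sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
        p_value = p_val, tested = tested, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
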