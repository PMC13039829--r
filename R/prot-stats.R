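## The three-test differential-expression procedure for normalized spectral
## counts: a SAM-type signal-to-noise weight, a one-tail unequal-variance
## t-test, and an empirically calibrated fold-change window. A protein is a
## DEP only when all three criteria pass.

#' SAM-type weight statistic
#'
#' Group-separation weight from the group means (mu1, mu2) and sample
#' standard deviations (delta1, delta2). The printed form of the statistic
#' divides by the difference of the standard deviations; the signal-to-noise
#' form divides by their sum. Both are provided; `"sum"` is the default
#' because the conventional `|W| > 0.8` cutoff is interpretable on that
#' scale and the denominator cannot vanish for non-constant data (see the
#' package vignette).
#'
#' @param x1,x2 numeric replicate vectors, each of length >= 2.
#' @param denominator_mode `"sum"` (delta1 + delta2) or `"as_printed"`
#'   (delta1 - delta2).
#' @return the weight W. A vanishing denominator yields a signed infinity
#'   (0 for a zero numerator), with attribute `degenerate = TRUE`.
#' @export
sam_weight <- function(x1, x2, denominator_mode = c("sum", "as_printed")) {
  denominator_mode <- match.arg(denominator_mode)
  if (length(x1) < 2L || length(x2) < 2L) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  num <- mean(x1) - mean(x2)
  d1 <- stats::sd(x1); d2 <- stats::sd(x2)
  den <- if (denominator_mode == "sum") d1 + d2 else d1 - d2
  if (den == 0) {
    w <- if (num == 0) 0 else sign(num) * Inf
    attr(w, "degenerate") <- TRUE
    return(w)
  }
  num / den
}

#' One-tail Welch (unequal-variance) t-test p-value
#'
#' Welch t statistic with Welch-Satterthwaite degrees of freedom; the
#' reported p is the single-tail probability in the direction of the
#' observed mean difference, so identical groups give p = 0.5.
#'
#' @param x1,x2 numeric replicate vectors, each of length >= 2.
#' @return p-value in (0, 1] with attributes `t`, `df` and `direction`
#'   (`"up"` when mean(x1) > mean(x2)). Two constant groups with equal
#'   means return 1 (flagged `degenerate`); constant groups with unequal
#'   means return the smallest representable p (flagged).
#' @export
welch_one_tail_p <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  m1 <- mean(x1); m2 <- mean(x2)
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    p <- if (m1 == m2) 1 else .Machine$double.xmin
    attr(p, "degenerate") <- TRUE
    attr(p, "direction") <- if (m1 >= m2) "up" else "down"
    return(p)
  }
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- stats::pt(abs(t), df = df, lower.tail = FALSE)
  attr(p, "t") <- t
  attr(p, "df") <- df
  attr(p, "direction") <- if (t >= 0) "up" else "down"
  p
}

#' Fold change of group mean abundances
#'
#' Ratio of group means. To keep the ratio finite at very low counts, a
#' pseudocount is added to both means, but only when either mean falls
#' below the pseudocount itself, so typical abundances are unbiased.
#'
#' @param x1,x2 numeric non-empty replicate vectors.
#' @param pseudocount guard value (default 0.5).
#' @return fold change FC > 0 (group 1 over group 2).
#' @export
fold_change <- function(x1, x2, pseudocount = 0.5) {
  if (!length(x1) || !length(x2)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  m1 <- mean(x1); m2 <- mean(x2)
  pc <- if (min(m1, m2) < pseudocount) pseudocount else 0
  (m1 + pc) / (m2 + pc)
}

#' Empirically calibrate the fold-change significance threshold
#'
#' Re-derives the fold-change window from a control comparison (e.g. a
#' WT-vs-WT split): per-protein control ratios are restricted to the
#' inner-quartile abundance range, the ln-ln correlation R of the two
#' control means is reported, and the threshold is the 99th percentile of
#' |ln ratio| on that set, exponentiated and clamped to the
#' `[1.5, 2.0]` window.
#'
#' @param x a [spectral_count_matrix()] whose two groups form the control
#'   split (counts are normalized internally if not already).
#' @param coverage quantile of |ln ratio| defining the window
#'   (default 0.99).
#' @param clamp allowed threshold window (default `c(1.5, 2.0)`).
#' @param min_proteins minimum proteins after inner-quartile restriction
#'   (default 20); fewer is an error (unstable calibration).
#' @return object of class `fc_calibration`: list with `threshold`,
#'   `lnln_r` (Pearson correlation of the ln group means), the
#'   `fraction_within` `[1/threshold, threshold]` recomputed by direct
#'   count, `n_used` and `clamp`.
#' @export
calibrate_fc_threshold <- function(x, coverage = 0.99, clamp = c(1.5, 2.0),
                                   min_proteins = 20L) {
  stopifnot(inherits(x, "spectral_count_matrix"))
  if (nlevels(x$groups) != 2L) {
    stop("the control split must have exactly two groups", call. = FALSE)
  }
  if (min(table(x$groups)) < 2L) {
    stop("each control split needs at least 2 samples", call. = FALSE)
  }
  if (!x$normalized) x <- normalize_counts(x)
  g <- levels(x$groups)
  m1 <- rowMeans(x$counts[, x$groups == g[1], drop = FALSE])
  m2 <- rowMeans(x$counts[, x$groups == g[2], drop = FALSE])
  ok <- m1 > 0 & m2 > 0
  m1 <- m1[ok]; m2 <- m2[ok]
  ab <- (m1 + m2) / 2
  q <- stats::quantile(ab, c(0.25, 0.75))
  iq <- ab >= q[1] & ab <= q[2]
  if (sum(iq) < min_proteins) {
    stop("fewer than ", min_proteins,
         " proteins in the inner-quartile range; calibration unstable",
         call. = FALSE)
  }
  lr <- log(m1[iq]) - log(m2[iq])
  r <- stats::cor(log(m1[iq]), log(m2[iq]))
  t_raw <- exp(stats::quantile(abs(lr), coverage, names = FALSE))
  threshold <- min(max(t_raw, clamp[1]), clamp[2])
  ratios <- exp(lr)
  structure(list(threshold = threshold,
                 threshold_raw = t_raw,
                 lnln_r = r,
                 fraction_within = mean(ratios >= 1 / threshold &
                                          ratios <= threshold),
                 n_used = sum(iq),
                 clamp = clamp,
                 coverage = coverage),
            class = "fc_calibration")
}

#' @export
print.fc_calibration <- function(x, ...) {
  cat(sprintf("Fold-change calibration: threshold %.3f (raw %.3f, clamp [%.1f, %.1f])\n",
              x$threshold, x$threshold_raw, x$clamp[1], x$clamp[2]))
  cat(sprintf("  ln-ln R = %.4f; %.1f%% of %d inner-quartile control ratios within window\n",
              x$lnln_r, 100 * x$fraction_within, x$n_used))
  invisible(x)
}

## vectorised row-wise group means / sds for the DEP caller
row_group_stats <- function(counts, idx) {
  n <- length(idx)
  m <- rowMeans(counts[, idx, drop = FALSE])
  s2 <- (rowSums(counts[, idx, drop = FALSE]^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0  # numerical guard
  list(mean = m, sd = sqrt(s2), var = s2, n = n)
}

#' Call differentially expressed proteins by the triple filter
#'
#' Computes, per protein, the SAM-type weight, the one-tail
#' unequal-variance t-test p and the fold change, and flags a protein as a
#' DEP only when all three pass: `|W| >` `w_cut`, `p <` `p_cut`, and
#' `FC >= fc_cut` or `FC <= 1/fc_cut`.
#'
#' @param x a normalized [spectral_count_matrix()] with exactly two groups,
#'   each of size >= 2. Unnormalized input is refused unless
#'   `allow_unnormalized = TRUE`.
#' @param w_cut SAM weight cutoff (default 0.8, applied as `|W| > w_cut`).
#' @param p_cut one-tail p cutoff (default 0.05, applied strictly).
#' @param fc_cut fold-change cutoff (default 1.5; may be replaced by a
#'   [calibrate_fc_threshold()] result within the 1.5-2.0 window).
#' @param denominator_mode passed to the SAM weight ("sum" default).
#' @param pseudocount passed to the fold change.
#' @param allow_unnormalized override the normalization check.
#' @return a `dep_table` data frame with one row per protein: group means
#'   `mu1`, `mu2`, spreads `delta1`, `delta2`, `W`, `p_one_tail`,
#'   `direction`, `FC`, `p_bh` (Benjamini-Hochberg adjusted, for
#'   transparency only), and logical `pass_sam`, `pass_t`, `pass_fc`,
#'   `is_dep`. Thresholds and mode are recorded as attributes.
#' @export
call_deps <- function(x, w_cut = 0.8, p_cut = 0.05, fc_cut = 1.5,
                      denominator_mode = c("sum", "as_printed"),
                      pseudocount = 0.5, allow_unnormalized = FALSE) {
  stopifnot(inherits(x, "spectral_count_matrix"))
  denominator_mode <- match.arg(denominator_mode)
  if (!x$normalized && !allow_unnormalized) {
    stop("counts are not normalized; run normalize_counts() first ",
         "(or set allow_unnormalized = TRUE)", call. = FALSE)
  }
  if (nlevels(x$groups) != 2L) {
    stop("exactly two groups are required", call. = FALSE)
  }
  if (min(table(x$groups)) < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (inherits(fc_cut, "fc_calibration")) fc_cut <- fc_cut$threshold
  g <- levels(x$groups)
  s1 <- row_group_stats(x$counts, which(x$groups == g[1]))
  s2 <- row_group_stats(x$counts, which(x$groups == g[2]))

  num <- s1$mean - s2$mean
  den <- if (denominator_mode == "sum") s1$sd + s2$sd else s1$sd - s2$sd
  W <- ifelse(den == 0, ifelse(num == 0, 0, sign(num) * Inf), num / den)

  se2 <- s1$var / s1$n + s2$var / s2$n
  tstat <- ifelse(se2 == 0, ifelse(num == 0, 0, sign(num) * Inf),
                  num / sqrt(se2))
  df <- ifelse(se2 == 0, NA_real_,
               se2^2 / ((s1$var / s1$n)^2 / (s1$n - 1) +
                          (s2$var / s2$n)^2 / (s2$n - 1)))
  p <- ifelse(se2 == 0, ifelse(num == 0, 1, .Machine$double.xmin),
              stats::pt(abs(tstat), df = df, lower.tail = FALSE))

  pc <- ifelse(pmin(s1$mean, s2$mean) < pseudocount, pseudocount, 0)
  FC <- (s1$mean + pc) / (s2$mean + pc)

  out <- data.frame(
    protein = rownames(x$counts),
    mu1 = s1$mean, mu2 = s2$mean,
    delta1 = s1$sd, delta2 = s2$sd,
    W = W,
    p_one_tail = p,
    direction = ifelse(num >= 0, "up", "down"),
    FC = FC,
    p_bh = stats::p.adjust(p, method = "BH"),
    pass_sam = abs(W) > w_cut,
    pass_t = p < p_cut,
    pass_fc = FC >= fc_cut | FC <= 1 / fc_cut,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$is_dep <- out$pass_sam & out$pass_t & out$pass_fc
  attr(out, "thresholds") <- list(w_cut = w_cut, p_cut = p_cut,
                                  fc_cut = fc_cut)
  attr(out, "denominator_mode") <- denominator_mode
  attr(out, "groups") <- g
  class(out) <- c("dep_table", "data.frame")
  out
}
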