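## Two-group overdispersed spectral-count matrices with planted fold
## changes. Counts follow a negative-binomial model parameterised by mean mu
## and dispersion phi (variance mu + phi * mu^2); dispersion 0 is the
## deterministic limit used by degenerate tests.

#' Specification of a synthetic spectral-count matrix
#'
#' @param n_proteins number of proteins (rows).
#' @param group_sizes integer vector of length 2, samples per group
#'   (default `c(4, 4)`, the study's group design).
#' @param baseline_mean expected spectral count of an unperturbed protein
#'   (> 0).
#' @param dispersion negative-binomial dispersion phi >= 0
#'   (variance `mu + phi mu^2`); 0 gives deterministic rounded means.
#' @param library_size_factors per-sample multiplicative factors (length
#'   `sum(group_sizes)`, default all 1).
#' @param planted_effects named numeric vector mapping protein id to its
#'   true fold change (> 0) of group 1 over group 2.
#' @param baseline_sd log-normal spread of per-protein baseline abundances
#'   (on the log scale; 0 makes all baselines equal to `baseline_mean`).
#' @param seed integer seed.
#' @return object of class `count_table_spec`.
#' @export
count_table_spec <- function(n_proteins = 500L,
                             group_sizes = c(4L, 4L),
                             baseline_mean = 50,
                             dispersion = 0.05,
                             library_size_factors = NULL,
                             planted_effects = numeric(0),
                             baseline_sd = 0.8,
                             seed = 1L) {
  if (length(group_sizes) != 2L || any(group_sizes < 2L)) {
    stop("'group_sizes' must be two integers, each >= 2", call. = FALSE)
  }
  assert_num1(baseline_mean, "baseline_mean", 0, strict = TRUE)
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion < 0) {
    stop("'dispersion' must be a single number >= 0", call. = FALSE)
  }
  assert_num1(baseline_sd, "baseline_sd", 0)
  n_samples <- sum(group_sizes)
  library_size_factors <- library_size_factors %||% rep(1, n_samples)
  if (length(library_size_factors) != n_samples ||
      any(library_size_factors <= 0)) {
    stop("'library_size_factors' must be positive, one per sample",
         call. = FALSE)
  }
  if (length(planted_effects) && (is.null(names(planted_effects)) ||
                                  any(planted_effects <= 0))) {
    stop("'planted_effects' must be a named vector of fold changes > 0",
         call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 group_sizes = as.integer(group_sizes),
                 baseline_mean = baseline_mean,
                 dispersion = dispersion,
                 library_size_factors = library_size_factors,
                 planted_effects = planted_effects,
                 baseline_sd = baseline_sd,
                 seed = as.integer(seed)),
            class = "count_table_spec")
}

#' Generate a spectral-count matrix with known planted effects
#'
#' @param spec a [count_table_spec()].
#' @return list with `matrix` (a [spectral_count_matrix()]) and `truth`
#'   (data frame of protein id, baseline mean and true fold change).
#' @export
make_count_table <- function(spec) {
  stopifnot(inherits(spec, "count_table_spec"))
  withr::with_seed(spec$seed, make_count_table_impl(spec))
}

make_count_table_impl <- function(spec) {
  n <- spec$n_proteins
  gs <- spec$group_sizes
  ids <- sprintf("P%04d", seq_len(n))
  base <- if (spec$baseline_sd > 0) {
    spec$baseline_mean * exp(stats::rnorm(n, -spec$baseline_sd^2 / 2,
                                          spec$baseline_sd))
  } else rep(spec$baseline_mean, n)
  fc <- rep(1, n)
  names(fc) <- ids
  if (length(spec$planted_effects)) {
    unknown <- setdiff(names(spec$planted_effects), ids)
    if (length(unknown)) {
      stop("planted effect for unknown protein id: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    fc[names(spec$planted_effects)] <- spec$planted_effects
  }
  ## group 1 carries the effect; baseline is the group-2 mean
  mu <- cbind(matrix(rep(base * fc, gs[1]), n, gs[1]),
              matrix(rep(base, gs[2]), n, gs[2]))
  sf <- spec$library_size_factors
  mu <- sweep(mu, 2, sf, "*")
  counts <- if (spec$dispersion > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$dispersion),
           n, ncol(mu))
  } else {
    round(mu)
  }
  dimnames(counts) <- list(ids, c(sprintf("g1_s%d", seq_len(gs[1])),
                                  sprintf("g2_s%d", seq_len(gs[2]))))
  groups <- factor(rep(c("g1", "g2"), gs), levels = c("g1", "g2"))
  truth <- data.frame(protein = ids, baseline_mean = base,
                      true_fc = unname(fc),
                      planted = ids %in% names(spec$planted_effects))
  list(matrix = spectral_count_matrix(counts, groups), truth = truth)
}
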