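#' Spectral-count matrix with group labels
#'
#' Proteins x samples matrix of (raw or normalized) spectral counts plus a
#' two-or-more-level group factor partitioning the sample columns.
#'
#' @param counts numeric matrix, proteins in rows, samples in columns;
#'   counts must be >= 0. Row and column names identify proteins and
#'   samples.
#' @param groups factor (or coercible) of length `ncol(counts)`.
#' @param normalized logical; TRUE once column totals have been equalised.
#' @return object of class `spectral_count_matrix`.
#' @export
spectral_count_matrix <- function(counts, groups, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and >= 0", call. = FALSE)
  }
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) {
    stop("'groups' must have one label per sample column", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("P%04d", seq_len(nrow(counts)))
  }
  structure(list(counts = counts, groups = groups,
                 normalized = isTRUE(normalized)),
            class = "spectral_count_matrix")
}

#' @export
print.spectral_count_matrix <- function(x, ...) {
  cat("Spectral-count matrix: ", nrow(x$counts), " proteins x ",
      ncol(x$counts), " samples (",
      paste(sprintf("%s n=%d", levels(x$groups), table(x$groups)),
            collapse = ", "),
      "); ", if (x$normalized) "normalized" else "raw", "\n", sep = "")
  invisible(x)
}

#' Normalize spectral counts across samples
#'
#' Scales every sample column so its total equals the mean (or median)
#' column total of the input, the usual normalized-spectral-count (N-SC)
#' scaling for label-free relative quantification. Idempotent.
#'
#' @param x a [spectral_count_matrix()].
#' @param target "mean" (default) or "median" column total.
#' @return a normalized `spectral_count_matrix`.
#' @export
normalize_counts <- function(x, target = c("mean", "median")) {
  stopifnot(inherits(x, "spectral_count_matrix"))
  target <- match.arg(target)
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    stop("sample column(s) with zero total cannot be normalized: ",
         paste(colnames(x$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  tgt <- if (target == "mean") mean(totals) else stats::median(totals)
  out <- sweep(x$counts, 2, tgt / totals, "*")
  spectral_count_matrix(out, x$groups, normalized = TRUE)
}

#' Filter a peptide-evidence table and roll it up to protein counts
#'
#' Applies the identification-level filters of a Scaffold-style workflow:
#' peptides must be longer than `min_peptide_length` residues, must not be
#' singly charged (no MH+1 charge states), and must exceed the peptide
#' probability cut; proteins must retain at least
#' `min_peptides_per_protein` surviving peptides, exceed the protein
#' probability cut and fall under the FDR cut. Per-protein counts are the
#' per-sample sums of surviving peptide counts.
#'
#' @param table data frame with columns `protein_id`, `peptide_sequence`,
#'   `length_aa`, `charge_state`, `peptide_probability_pct`,
#'   `protein_probability_pct`, `protein_fdr_pct`, plus one numeric count
#'   column per sample.
#' @param groups factor of group labels, one per count column.
#' @param count_cols names of the per-sample count columns; defaults to all
#'   columns not in the required metadata set.
#' @param thresholds list overriding any of `min_peptide_length` (strictly
#'   greater, default 5), `excluded_charge` (default 1),
#'   `min_peptide_probability_pct` (strictly greater, default 80),
#'   `min_peptides_per_protein` (default 2), `min_protein_probability_pct`
#'   (strictly greater, default 99), `max_protein_fdr_pct` (strictly less,
#'   default 1).
#' @return list with `proteins` (surviving ids), `matrix` (a raw
#'   [spectral_count_matrix()]) and `peptides` (the surviving peptide rows).
#' @export
filter_peptides <- function(table, groups, count_cols = NULL,
                            thresholds = list()) {
  required <- c("protein_id", "peptide_sequence", "length_aa", "charge_state",
                "peptide_probability_pct", "protein_probability_pct",
                "protein_fdr_pct")
  missing <- setdiff(required, names(table))
  if (length(missing)) {
    stop("peptide table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  th <- utils::modifyList(list(min_peptide_length = 5,
                               excluded_charge = 1,
                               min_peptide_probability_pct = 80,
                               min_peptides_per_protein = 2,
                               min_protein_probability_pct = 99,
                               max_protein_fdr_pct = 1),
                          thresholds)
  count_cols <- count_cols %||% setdiff(names(table), required)
  if (!length(count_cols)) {
    stop("no per-sample count columns found", call. = FALSE)
  }

  pep_ok <- table$length_aa > th$min_peptide_length &
    table$charge_state != th$excluded_charge &
    table$peptide_probability_pct > th$min_peptide_probability_pct
  surv <- table[pep_ok, , drop = FALSE]

  n_pep <- table(surv$protein_id)
  prot_meta <- unique(surv[, c("protein_id", "protein_probability_pct",
                               "protein_fdr_pct")])
  prot_ok <- prot_meta$protein_id[
    prot_meta$protein_probability_pct > th$min_protein_probability_pct &
      prot_meta$protein_fdr_pct < th$max_protein_fdr_pct]
  prot_ok <- intersect(
    prot_ok, names(n_pep)[n_pep >= th$min_peptides_per_protein])
  prot_ok <- sort(unique(prot_ok))

  surv <- surv[surv$protein_id %in% prot_ok, , drop = FALSE]
  counts <- matrix(0, length(prot_ok), length(count_cols),
                   dimnames = list(prot_ok, count_cols))
  if (nrow(surv)) {
    counts <- rowsum(as.matrix(surv[, count_cols, drop = FALSE]),
                     group = factor(surv$protein_id, levels = prot_ok))
  }
  list(proteins = prot_ok,
       matrix = spectral_count_matrix(counts, groups),
       peptides = surv)
}
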