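## DEP ranking, set comparison across conditions, and gene-set
## over-representation by the hypergeometric upper tail.

#' Rank DEPs by p-value and compare two conditions
#'
#' Sorts each table's DEPs ascending by the one-tail p, truncates each list
#' at `top_n`, and reports the Venn counts of the full DEP sets.
#'
#' @param dep_a,dep_b `dep_table` objects (see [call_deps()]) sharing a
#'   protein-id namespace.
#' @param top_n list truncation (default 40).
#' @return list with `top_a`, `top_b` (truncated ranked tables) and `venn`
#'   (list `overlap`, `only_a`, `only_b`, plus the id vectors).
#' @export
rank_and_compare <- function(dep_a, dep_b, top_n = 40L) {
  ranked <- function(d) {
    d <- d[d$is_dep, , drop = FALSE]
    d <- d[order(d$p_one_tail, d$protein), , drop = FALSE]
    utils::head(d, top_n)
  }
  a_ids <- dep_a$protein[dep_a$is_dep]
  b_ids <- dep_b$protein[dep_b$is_dep]
  shared <- intersect(a_ids, b_ids)
  list(top_a = ranked(dep_a),
       top_b = ranked(dep_b),
       venn = list(overlap = length(shared),
                   only_a = length(setdiff(a_ids, b_ids)),
                   only_b = length(setdiff(b_ids, a_ids)),
                   overlap_ids = sort(shared),
                   a_ids = sort(a_ids),
                   b_ids = sort(b_ids)))
}

#' Read a GMT gene-set collection
#'
#' @param path path to a tab-delimited GMT file (set name, description,
#'   member ids).
#' @return named list of member-id character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Gene-set over-representation of a DEP list
#'
#' Hypergeometric upper-tail test per gene set: the probability of an
#' overlap at least as large as observed when `n` DEPs are drawn from a
#' universe of `N` proteins of which `m` belong to the set. Sets are ranked
#' ascending by p and truncated at `top_n`.
#'
#' @param dep_ids character vector of DEP protein ids.
#' @param gene_sets named list of member-id vectors (e.g. [read_gmt()]).
#' @param universe_ids all quantified protein ids; gene sets are
#'   intersected with the universe, and DEP ids outside it are dropped with
#'   a warning.
#' @param top_n ranked-list truncation (default 20).
#' @param fc_tables optional named list of `dep_table`s (e.g.
#'   `list(young = ..., old = ...)`); when given, a companion long table of
#'   member-protein fold changes per reported set and condition is attached
#'   as `member_fc` (dumbbell-style export).
#' @return data frame with columns `set`, `overlap_k`, `set_size_m`,
#'   `dep_n`, `universe_N`, `p_hyper`, `rank`, truncated at `top_n`;
#'   optional attribute `member_fc`.
#' @export
enrich_sets <- function(dep_ids, gene_sets, universe_ids, top_n = 20L,
                        fc_tables = NULL) {
  universe_ids <- unique(universe_ids)
  if (!length(universe_ids)) stop("empty universe", call. = FALSE)
  outside <- setdiff(dep_ids, universe_ids)
  if (length(outside)) {
    warning(length(outside), " DEP id(s) outside the universe were dropped")
    dep_ids <- intersect(dep_ids, universe_ids)
  }
  dep_ids <- unique(dep_ids)
  N <- length(universe_ids)
  n <- length(dep_ids)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], universe_ids)
    m <- length(members)
    k <- length(intersect(members, dep_ids))
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(set = nm, overlap_k = k, set_size_m = m, dep_n = n,
               universe_N = N, p_hyper = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_hyper, out$set), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  if (!is.null(fc_tables)) {
    fc_long <- do.call(rbind, lapply(names(fc_tables), function(cond) {
      d <- fc_tables[[cond]]
      do.call(rbind, lapply(out$set, function(nm) {
        members <- intersect(gene_sets[[nm]], d$protein)
        if (!length(members)) return(NULL)
        idx <- match(members, d$protein)
        data.frame(set = nm, condition = cond, protein = members,
                   FC = d$FC[idx], p_one_tail = d$p_one_tail[idx],
                   is_dep = d$is_dep[idx], stringsAsFactors = FALSE)
      }))
    }))
    attr(out, "member_fc") <- fc_long
  }
  out
}
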