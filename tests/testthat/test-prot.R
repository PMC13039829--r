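test_that("peptide filtering matches hand-applied identification rules", {
  tab <- toy_peptide_table()
  res <- filter_peptides(tab, toy_groups)
  expect_identical(res$proteins, c("PROT_A", "PROT_F"))
  ## per-protein counts are sums of surviving peptide counts
  expect_equal(unname(res$matrix$counts["PROT_A", ]),
               c(3 + 1, 4 + 0, 5 + 2, 6 + 1))
  expect_equal(unname(res$matrix$counts["PROT_F", ]),
               c(4 + 2, 3 + 3, 5 + 1, 4 + 2))
  expect_error(filter_peptides(tab[, -3], toy_groups), "length_aa")
})

test_that("borderline peptides fall on the correct side of each rule", {
  tab <- toy_peptide_table()
  ## length exactly 5 is excluded (rule is strictly > 5)
  expect_false("PROT_B" %in% filter_peptides(tab, toy_groups)$proteins)
  ## relaxing the length rule to >4 rescues PROT_B (2 surviving peptides)
  res <- filter_peptides(tab, toy_groups,
                         thresholds = list(min_peptide_length = 4))
  expect_true("PROT_B" %in% res$proteins)
  ## the 1+ charge state and the 80 percent probability peptide both fail,
  ## so PROT_E never survives
  expect_false("PROT_E" %in% res$proteins)
})

test_that("normalization equalises column totals and is idempotent", {
  m <- matrix(c(60, 40, 120, 80), nrow = 2,
              dimnames = list(c("P1", "P2"), c("a", "b")))
  x <- spectral_count_matrix(m, c("g1", "g2"))
  nx <- normalize_counts(x)
  ## totals 100 and 200 -> target 150 -> factors 1.5 and 0.75
  expect_equal(nx$counts[, "a"], m[, "a"] * 1.5)
  expect_equal(nx$counts[, "b"], m[, "b"] * 0.75)
  tot <- colSums(nx$counts)
  expect_lt(diff(range(tot)) / mean(tot), 1e-9)
  expect_equal(normalize_counts(nx)$counts, nx$counts)

  same <- spectral_count_matrix(cbind(a = c(10, 20), b = c(15, 15)),
                                c("g1", "g2"))
  expect_equal(normalize_counts(same)$counts, same$counts)
  zero <- spectral_count_matrix(cbind(a = c(1, 2), b = c(0, 0)),
                                c("g1", "g2"))
  expect_error(normalize_counts(zero), "zero total")
})

test_that("the SAM weight follows the signal-to-noise arithmetic", {
  x1 <- c(10, 12, 14, 12); x2 <- c(6, 8, 7, 7)
  w <- sam_weight(x1, x2)
  expect_equal(w, (mean(x1) - mean(x2)) / (sd(x1) + sd(x2)))
  expect_equal(w, 2.0412, tolerance = 1e-4)
  expect_equal(sam_weight(x2, x1), -w)
  expect_equal(sam_weight(x1, x2, "as_printed"),
               (mean(x1) - mean(x2)) / (sd(x1) - sd(x2)))
  expect_equal(sam_weight(c(1, 2, 3), c(1, 2, 3)), 0)
  ## constant groups: vanishing denominator is flagged
  w_inf <- sam_weight(c(5, 5, 5), c(1, 1, 1))
  expect_identical(as.numeric(w_inf), Inf)
  expect_true(attr(w_inf, "degenerate"))
  expect_error(sam_weight(c(1), c(1, 2)), "replicates")
})

test_that("the one-tail Welch p has the expected symmetries", {
  expect_equal(as.numeric(welch_one_tail_p(c(1, 2, 3), c(1, 2, 3))), 0.5)
  set.seed(7)
  x1 <- rnorm(5, 10); x2 <- rnorm(6, 8)
  p1 <- welch_one_tail_p(x1, x2)
  ## one tail is half of the two-tail p for the same data
  expect_equal(as.numeric(p1),
               stats::t.test(x1, x2)$p.value / 2, tolerance = 1e-12)
  ## degenerate zero-variance cases
  p_eq <- welch_one_tail_p(c(2, 2, 2), c(2, 2, 2))
  expect_identical(as.numeric(p_eq), 1)
  expect_true(attr(p_eq, "degenerate"))
  p_ne <- welch_one_tail_p(c(3, 3, 3), c(1, 1, 1))
  expect_gt(as.numeric(p_ne), 0)
  expect_lt(as.numeric(p_ne), 1e-100)
})

test_that("fold changes guard zero means without biasing typical counts", {
  expect_equal(fold_change(c(10, 10), c(10, 10)), 1)
  expect_equal(fold_change(c(19, 21), c(9, 11), pseudocount = 0), 2)
  expect_equal(fold_change(c(4, 6), c(0, 0)), (5 + 0.5) / 0.5)
  expect_equal(fold_change(c(20, 20), c(10, 10)), 2)  # pseudocount inactive
  expect_error(fold_change(numeric(0), c(1)), "non-empty")
})

test_that("statistics match independent oracles on random fixtures", {
  set.seed(11)
  for (i in 1:100) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x1 <- round(rnorm(n1, 50, 10), 2)
    x2 <- round(rnorm(n2, 40, 12), 2)
    if (sd(x1) == 0 || sd(x2) == 0) next
    expect_equal(sam_weight(x1, x2),
                 (sum(x1) / n1 - sum(x2) / n2) /
                   (sqrt(var(x1)) + sqrt(var(x2))),
                 tolerance = 1e-10)
    alt <- if (mean(x1) >= mean(x2)) "greater" else "less"
    expect_equal(as.numeric(welch_one_tail_p(x1, x2)),
                 stats::t.test(x1, x2, alternative = alt)$p.value,
                 tolerance = 1e-6)
    expect_equal(fold_change(x1, x2, pseudocount = 0),
                 mean(x1) / mean(x2), tolerance = 1e-10)
  }
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  universe <- sprintf("G%02d", 1:20)
  sets <- list(hit = universe[1:5], dud = universe[16:20])
  deps <- c(universe[1:3], universe[18])   # k = 3 of the 'hit' set
  res <- enrich_sets(deps, sets, universe, top_n = 20)
  ## N = 20, m = 5, n = 4, k = 3: brute-force sum over k in {3, 4}
  brute <- sum(sapply(3:4, function(k)
    choose(5, k) * choose(15, 4 - k) / choose(20, 4)))
  expect_equal(res$p_hyper[res$set == "hit"], brute, tolerance = 1e-10)
  ## zero overlap gives p = 1
  res0 <- enrich_sets(universe[6:9], sets["dud"], universe)
  expect_identical(res0$p_hyper, 1)
  ## random fixtures against enumeration
  set.seed(21)
  for (i in 1:100) {
    N <- sample(10:40, 1); m <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
    k <- sample(0:min(m, n), 1)
    brute <- sum(sapply(k:min(m, n), function(j)
      choose(m, j) * choose(N - m, n - j) / choose(N, n)))
    expect_equal(phyper(k - 1, m, N - m, n, lower.tail = FALSE), brute,
                 tolerance = 1e-10)
  }
})

test_that("enrichment truncates, ranks, and validates the universe", {
  universe <- sprintf("G%03d", 1:100)
  sets <- setNames(lapply(1:25, function(i) sample(universe, 10)),
                   sprintf("set%02d", 1:25))
  res <- enrich_sets(universe[1:10], sets, universe)
  expect_lte(nrow(res), 20)
  expect_identical(res$rank, seq_len(nrow(res)))
  expect_false(is.unsorted(res$p_hyper))
  expect_error(enrich_sets("G001", sets, character(0)), "universe")
  expect_warning(enrich_sets(c("G001", "NOT_THERE"), sets, universe),
                 "dropped")
})

test_that("gene sets round-trip through GMT", {
  sets <- list(tca_cycle = c("CS", "ACO2", "IDH3A"),
               phototransduction = c("RHO", "GNAT1", "PDE6A", "PDE6B"))
  path <- write_gmt_file(sets)
  got <- read_gmt(path)
  expect_identical(got[order(names(got))], sets[order(names(sets))])
})

test_that("fold-change calibration respects its window and coverage contract", {
  ## identical control replicates: every ratio is 1, threshold clamps to 1.5
  m <- matrix(rep(rpois(50, 80), 4), ncol = 4,
              dimnames = list(sprintf("P%02d", 1:50), letters[1:4]))
  x <- spectral_count_matrix(m, c("c1", "c1", "c2", "c2"))
  cal <- calibrate_fc_threshold(x)
  expect_equal(cal$threshold, 1.5)
  expect_equal(cal$fraction_within, 1)
  expect_equal(cal$lnln_r, 1)

  ## simulated control splits: threshold in [1.5, 2], coverage >= 0.99 by
  ## direct count on the same input
  for (sd in 1:3) {
    sim <- make_count_table(count_table_spec(n_proteins = 400, seed = sd))
    ctrl <- normalize_counts(sim$matrix)
    cal <- calibrate_fc_threshold(ctrl)
    expect_gte(cal$threshold, 1.5)
    expect_lte(cal$threshold, 2.0)
    g <- ctrl$groups
    m1 <- rowMeans(ctrl$counts[, g == levels(g)[1]])
    m2 <- rowMeans(ctrl$counts[, g == levels(g)[2]])
    ok <- m1 > 0 & m2 > 0
    ab <- (m1[ok] + m2[ok]) / 2
    q <- quantile(ab, c(0.25, 0.75))
    r <- (m1[ok] / m2[ok])[ab >= q[1] & ab <= q[2]]
    expect_gte(mean(r >= 1 / cal$threshold & r <= cal$threshold), 0.99)
    expect_equal(cal$fraction_within,
                 mean(r >= 1 / cal$threshold & r <= cal$threshold))
  }
  tiny <- spectral_count_matrix(matrix(5, 10, 4), c(1, 1, 2, 2))
  expect_error(calibrate_fc_threshold(tiny), "inner-quartile")
})

test_that("the DEP caller is the exact conjunction of its three criteria", {
  sim <- make_count_table(count_table_spec(
    n_proteins = 300,
    planted_effects = setNames(rep(3, 10), sprintf("P%04d", 1:10)),
    seed = 31))
  deps <- call_deps(normalize_counts(sim$matrix))
  expect_identical(deps$is_dep, deps$pass_sam & deps$pass_t & deps$pass_fc)
  ## row-wise agreement with the scalar statistics (brute force per protein)
  x <- normalize_counts(sim$matrix)
  g <- x$groups
  for (i in sample(nrow(x$counts), 25)) {
    x1 <- x$counts[i, g == "g1"]; x2 <- x$counts[i, g == "g2"]
    expect_equal(deps$W[i], as.numeric(sam_weight(x1, x2)), tolerance = 1e-12)
    expect_equal(deps$p_one_tail[i], as.numeric(welch_one_tail_p(x1, x2)),
                 tolerance = 1e-12)
    expect_equal(deps$FC[i], fold_change(x1, x2), tolerance = 1e-12)
  }
})

test_that("two identical groups produce no DEPs", {
  half <- matrix(rpois(200 * 4, 50), 200, 4)
  m <- cbind(half, half)
  colnames(m) <- sprintf("s%d", 1:8)
  x <- spectral_count_matrix(m, rep(c("g1", "g2"), each = 4))
  deps <- call_deps(normalize_counts(x))
  expect_identical(sum(deps$is_dep), 0L)
  expect_true(all(deps$W == 0))
  expect_true(all(deps$FC == 1))
  expect_true(all(deps$p_one_tail %in% c(0.5, 1)))  # 1 for constant rows
})

test_that("a constructed fixture yields exactly the designed DEPs", {
  ## 3 strong planted positives among 17 null proteins with modest noise
  set.seed(5)
  null_part <- matrix(rpois(17 * 8, 100), 17, 8)
  hit_part <- rbind(c(200, 205, 195, 202, 100, 98, 101, 99),
                    c(55, 52, 50, 54, 104, 99, 100, 103),
                    c(320, 310, 305, 315, 102, 100, 97, 101))
  m <- rbind(hit_part, null_part)
  rownames(m) <- sprintf("Q%02d", seq_len(nrow(m)))
  x <- spectral_count_matrix(m, rep(c("g1", "g2"), each = 4))
  deps <- call_deps(x, allow_unnormalized = TRUE)
  expect_identical(deps$protein[deps$is_dep], c("Q01", "Q02", "Q03"))
  ## and the brute-force evaluation of each criterion agrees
  for (i in 1:3) {
    x1 <- m[i, 1:4]; x2 <- m[i, 5:8]
    expect_true(abs(sam_weight(x1, x2)) > 0.8)
    expect_true(welch_one_tail_p(x1, x2) < 0.05)
    fc <- fold_change(x1, x2)
    expect_true(fc >= 1.5 || fc <= 1 / 1.5)
  }
})

test_that("unnormalized input is refused unless overridden", {
  sim <- make_count_table(count_table_spec(n_proteins = 30, seed = 2))
  expect_error(call_deps(sim$matrix), "normalize")
  expect_s3_class(call_deps(sim$matrix, allow_unnormalized = TRUE),
                  "dep_table")
})

test_that("the DEP table is invariant to per-sample scaling after normalization", {
  sim <- make_count_table(count_table_spec(
    n_proteins = 200, baseline_mean = 80,
    planted_effects = setNames(rep(2.5, 10), sprintf("P%04d", 1:10)),
    seed = 9))
  base <- call_deps(normalize_counts(sim$matrix))
  scaled <- sim$matrix$counts
  scaled[, 3] <- scaled[, 3] * 7
  x2 <- spectral_count_matrix(scaled, sim$matrix$groups)
  rescaled <- call_deps(normalize_counts(x2))
  expect_equal(rescaled$W, base$W, tolerance = 1e-9)
  expect_equal(rescaled$p_one_tail, base$p_one_tail, tolerance = 1e-9)
  expect_equal(rescaled$FC, base$FC, tolerance = 1e-9)
  expect_identical(rescaled$is_dep, base$is_dep)
})

test_that("under a Gaussian null the one-tail pass rate is within its level band", {
  ## a one-tail test taken toward the observed direction rejects in either
  ## tail, so its size lies in [alpha, 2*alpha]; Welch's estimated df keeps
  ## it below the upper bound at small n
  set.seed(17)
  m <- matrix(rnorm(5000 * 8, mean = 100, sd = 10), 5000, 8)
  x <- spectral_count_matrix(m, rep(c("g1", "g2"), each = 4),
                             normalized = TRUE)
  deps <- call_deps(x)
  rate <- mean(deps$pass_t)
  se <- sqrt(0.1 * 0.9 / 5000)
  expect_gte(rate, 0.05 - 4 * se)
  expect_lte(rate, 0.10 + 4 * se)
})

test_that("DEP ranking and Venn comparison count overlaps correctly", {
  a <- fake_dep_table(c("A", "B", "C"))
  b <- fake_dep_table(c("B", "C", "D"))
  rc <- rank_and_compare(a, b)
  expect_equal(rc$venn$overlap, 2)
  expect_equal(rc$venn$only_a, 1)
  expect_equal(rc$venn$only_b, 1)
  expect_identical(rank_and_compare(a, fake_dep_table(c("X", "Y")))$venn$overlap, 0L)
  expect_equal(rank_and_compare(a, a)$venn$overlap, 3)
  ## ranking is ascending in p and truncated
  big <- fake_dep_table(sprintf("P%02d", 1:50), p = rev(seq_len(50)) / 100)
  rc2 <- rank_and_compare(big, big, top_n = 40)
  expect_equal(nrow(rc2$top_a), 40)
  expect_false(is.unsorted(rc2$top_a$p_one_tail))
})
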