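test_that("spearman_rho reproduces the hand-evaluated closed form", {
  x <- c(3, 7, 11, 15)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, rev(x)), -1)
  expect_equal(spearman_rho(1:4, c(2, 1, 4, 3)), 0.6)  # 1 - 6*4/(4*15)
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  r <- spearman_rho(c(1, 1, 1), 1:3)
  expect_true(is.na(r))
  expect_equal(attr(r, "reason"), "zero rank variance")
})

test_that("spearman_rho matches independent oracles on random permutations", {
  set.seed(13)
  for (i in 1:300) {
    x <- sample(10)
    y <- sample(10)
    expect_equal(spearman_rho(x, y), oracle_spearman_eq3(x, y),
                 tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), oracle_spearman_pearson(x, y),
                 tolerance = 1e-12)
  }
})

test_that("bag_summary reports the mean and sd of sorted consecutive gaps", {
  s <- bag_summary(c(11.09, 2.89, 7.96, 5.66, 9.00))  # order-independent
  expect_equal(s$mean, 2.05)
  expect_equal(round(s$sd, 2), 0.73)
})

test_that("minbag_sample always satisfies the gap invariant", {
  set.seed(77)
  for (i in 1:50) {
    pba <- runif(sample(30:300, 1), 2, 14)
    minbag <- sample(c(0.05, 0.1, 0.5, 1.0), 1)
    idx <- minbag_sample(pba, minbag)
    expect_gte(length(idx), 3)
    expect_false(is.unsorted(pba[idx]))
    expect_true(all(diff(pba[idx]) >= minbag))
  }
})

test_that("closest-point mapping is the identity on a matching grid", {
  pba <- seq(2, 12, by = 0.5)
  set.seed(4)
  idx <- minbag_sample(pba, 0.5, subsample_frac = 1)
  expect_equal(idx, seq_along(pba))
})

test_that("minbag_sample is deterministic under a fixed seed", {
  pba <- runif(200, 2, 14)
  set.seed(123); a <- minbag_sample(pba, 0.1)
  set.seed(123); b <- minbag_sample(pba, 0.1)
  expect_identical(a, b)
  # subsampling keeps three-quarters (floor) of the survivors
  set.seed(9)
  full <- minbag_sample(pba, 0.5, subsample_frac = 1)
  set.seed(9)
  sub <- minbag_sample(pba, 0.5)
  expect_equal(length(sub), floor(0.75 * length(full)))
})

test_that("resample_statistic collapses on perfectly (anti)monotone metrics", {
  rd <- make_ranking_dataset(n = 100, link = "monotone")
  set.seed(1)
  rs <- resample_statistic(rd$records, rd$metric, minbag = 0.1, n_reps = 50)
  expect_equal(rs$mean, 1)
  expect_equal(rs$median, 1)
  expect_equal(c(rs$ci_low, rs$ci_high), c(1, 1))
  expect_gte(rs$mean_gap, 0.1)
  anti <- make_ranking_dataset(n = 100, link = "anti")
  set.seed(2)
  rs2 <- resample_statistic(anti$records, anti$metric, minbag = 0.1,
                            n_reps = 50)
  expect_equal(rs2$median, -1)
})

test_that("resampled correlation of a noisy metric tracks the full-set value", {
  rd <- make_ranking_dataset(n = 285, link = "noisy", noise_sd = 3.5,
                             seed = 42)
  full_rho <- oracle_spearman_pearson(rd$records$pba, unname(rd$metric))
  set.seed(7)
  rs <- resample_statistic(rd$records, rd$metric, minbag = 0.1, n_reps = 200)
  expect_lt(abs(rs$median - full_rho), 0.1)
})

test_that("eroce matches the definitional oracle and its anchors", {
  expect_equal(eroce(make_screening_dataset(5, 95, "first")), 1)
  w <- eroce(make_screening_dataset(1, 1000, "fpr", fpr = 0.05))
  expect_equal(w, exp(-32.19 * 0.05))
  expect_equal(round(w, 2), 0.2)
  set.seed(31)
  for (i in 1:100) {
    lab <- make_screening_dataset(10, 190, "random", seed = i)
    expect_equal(eroce(lab), oracle_eroce(lab), tolerance = 1e-12)
  }
  expect_error(eroce(rep(TRUE, 5)), "active and one decoy")
})

test_that("eroce is monotone under upward swaps and bounded", {
  set.seed(17)
  for (i in 1:30) {
    lab <- make_screening_dataset(5, 45, "random", seed = 1000 + i)
    e0 <- eroce(lab)
    expect_gte(e0, exp(-32.19))
    expect_lte(e0, 1)
    # swap the first active that sits right after a decoy upward one place
    pos <- which(lab & c(FALSE, !lab[-length(lab)]))
    if (length(pos)) {
      p <- pos[1]
      lab2 <- lab
      lab2[c(p - 1, p)] <- lab[c(p, p - 1)]
      expect_gte(eroce(lab2), e0)
    }
  }
})

test_that("tied decoys receive half credit when scores are supplied", {
  lab <- c(FALSE, TRUE, FALSE)
  scores <- c(3, 2, 2)  # one decoy strictly before, one tied with the active
  expect_equal(eroce(lab, alpha = 1, scores = scores), exp(-1 * 1.5 / 2))
})

test_that("enrichment_factor follows Eq-style hand evaluations", {
  # worked list: N = 200, NA = 10, 4 actives among the top 10 (5%)
  lab <- rep(FALSE, 200)
  lab[c(1, 4, 7, 9, seq(30, 140, length.out = 6))] <- TRUE
  expect_equal(sum(lab), 10)
  expect_equal(unname(enrichment_factor(lab, 0.05)), 4 / (10 * 0.05))
  # all actives in the top 1%: EF hits its ceiling 1/f
  top <- make_screening_dataset(2, 198, "first")
  expect_equal(unname(enrichment_factor(top, 0.01)), 100)
  # EF at fraction 1 is exactly 1 for any ranking
  set.seed(3)
  any_rank <- make_screening_dataset(7, 93, "random", seed = 5)
  expect_equal(unname(enrichment_factor(any_rank, 1)), 1)
  expect_error(enrichment_factor(lab, 0), "fraction")
})

test_that("random placement gives EF near 1 in expectation", {
  set.seed(55)
  efs <- replicate(2000, {
    lab <- sample(c(rep(TRUE, 10), rep(FALSE, 90)))
    unname(enrichment_factor(lab, 0.10))
  })
  se <- sd(efs) / sqrt(length(efs))
  expect_lt(abs(mean(efs) - 1), 3 * se + 0.02)
})

test_that("vs_success applies the strict eROCE > 0.1 rule", {
  expect_true(vs_success(1))
  expect_false(vs_success(0.1))
  expect_true(vs_success(0.100001))
  ev <- screening_eval(make_screening_dataset(5, 95, "first"))
  expect_true(ev$success)
  expect_identical(vs_success(ev), ev$success)
})

test_that("bin_by_success assigns fractions to the documented intervals", {
  # one complex, 34 scoring functions, 8 successes -> 8/34 < 25%
  tab <- data.frame(pdb_id = "p1", dsf_id = sprintf("d%02d", 1:34),
                    rmsd = c(rep(1.0, 8), rep(3.0, 26)))
  g <- bin_by_success(tab)
  expect_equal(unname(g$counts["<25%"]), 1L)
  # all perfect redockings -> >95% bin
  tab2 <- data.frame(pdb_id = "p2", dsf_id = sprintf("d%02d", 1:34), rmsd = 0)
  expect_equal(unname(bin_by_success(tab2)$counts[">95%"]), 1L)
  # RMSD exactly at the threshold counts as failure (strict <)
  tab3 <- data.frame(pdb_id = "p3", dsf_id = c("d1", "d2"), rmsd = c(2.0, 0.5))
  expect_equal(unname(bin_by_success(tab3)$fractions["p3"]), 0.5)
  # a fraction of exactly 0.95 stays in the fourth bin
  tab4 <- data.frame(pdb_id = "p4", dsf_id = sprintf("d%02d", 1:20),
                     rmsd = c(rep(0.5, 19), 5))
  expect_equal(unname(bin_by_success(tab4)$counts["75-95%"]), 1L)
})

test_that("bin_by_success partitions complexes and handles missing RMSDs", {
  set.seed(66)
  ids <- sprintf("p%03d", 1:40)
  tab <- expand.grid(pdb_id = ids, dsf_id = sprintf("d%02d", 1:34),
                     stringsAsFactors = FALSE)
  tab$rmsd <- runif(nrow(tab), 0, 6)
  g <- bin_by_success(tab)
  expect_equal(sum(g$counts), 40L)
  expect_setequal(unlist(g$groups), ids)
  tab$rmsd[1] <- NA
  expect_warning(g2 <- bin_by_success(tab), "missing")
  expect_equal(sum(g2$counts), 40L)
  # per-group metric distributions are carried through
  metric <- setNames(runif(40), ids)
  g3 <- bin_by_success(tab[!is.na(tab$rmsd), ], metric_values = metric)
  expect_equal(sum(lengths(g3$per_group_values)), 40L)
})

test_that("pairwise_wilcoxon flags separated groups and only them", {
  set.seed(88)
  same <- list(a = rnorm(50), b = rnorm(50))
  res_same <- pairwise_wilcoxon(same)
  expect_gt(res_same$p["a", "b"], 0.05)
  sep <- list(a = rnorm(50), b = rnorm(50, mean = 5))
  expect_true(pairwise_wilcoxon(sep)$significant["a", "b"])
  three <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50, mean = 5))
  res3 <- pairwise_wilcoxon(three)
  expect_true(res3$significant["a", "c"])
  expect_true(res3$significant["b", "c"])
  expect_false(res3$significant["a", "b"])
  expect_equal(res3$p, t(res3$p))
})

test_that("pairwise_wilcoxon marks undersized groups not assessable", {
  set.seed(89)
  g <- list(a = rnorm(20), b = rnorm(2), c = rnorm(20, 3))
  res <- pairwise_wilcoxon(g)
  expect_true(is.na(res$p["a", "b"]))
  expect_true(is.na(res$p["b", "c"]))
  expect_false(is.na(res$p["a", "c"]))
})
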