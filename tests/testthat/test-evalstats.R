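test_that("DSC identities: perfect overlap, disjoint masks, hand-counted case", {
  pair <- handmade_pair()
  expect_equal(as.numeric(dsc(pair$ref, pair$ref, 1L)), 1)
  expect_equal(as.numeric(dsc(pair$pred, pair$ref, 1L)), 2 * 2 / 6)
  disj <- array(0L, dim = c(4, 4, 4)); disj[4, 4, 4] <- 1L
  expect_equal(as.numeric(dsc(labelmap(disj), pair$ref, 1L)), 0)
  # class absent from both: defined-empty value 1, flagged
  d2 <- dsc(pair$pred, pair$ref, 2L)
  expect_equal(as.numeric(d2), 1)
  expect_true(attr(d2, "both_empty"))
  # geometry mismatch
  expect_error(dsc(labelmap(array(0L, dim = c(2, 2, 2))), pair$ref, 1L),
               "match")
})

test_that("aggregated Dice pools counts across cases and is robust to one all-miss case", {
  pair <- handmade_pair()
  expect_equal(as.numeric(agg_dsc(list(pair), 1L)),
               as.numeric(dsc(pair$pred, pair$ref, 1L)))
  # pair A: overlap 2 of 3/3; pair B: disjoint single voxels
  bp <- array(0L, dim = c(4, 4, 4)); bp[1, 1, 1] <- 1L
  br <- array(0L, dim = c(4, 4, 4)); br[4, 4, 4] <- 1L
  pairs <- list(pair, list(pred = labelmap(bp), ref = labelmap(br)))
  expect_equal(as.numeric(agg_dsc(pairs, 1L)), 2 * 2 / (6 + 2))
  mean_percase <- mean(c(2 * 2 / 6, 0))
  expect_equal(mean_percase, 1 / 3, tolerance = 1e-12)
  expect_gt(as.numeric(agg_dsc(pairs, 1L)), mean_percase)
  # perfect agreement everywhere
  expect_equal(as.numeric(agg_dsc(list(list(pred = pair$ref, ref = pair$ref)),
                                  1L)), 1)
})

test_that("aggregated Dice is volume-weighted where the per-case mean is not", {
  pair <- handmade_pair()
  tile <- function(m) {
    big <- array(0L, dim = c(8, 8, 8))
    for (dx in c(0, 4)) for (dy in c(0, 4)) for (dz in c(0, 4))
      big[dx + 1:4, dy + 1:4, dz + 1:4] <- m$labels
    labelmap(big)
  }
  perfect <- list(pred = pair$ref, ref = pair$ref)
  small <- list(pair, perfect)
  inflated <- list(list(pred = tile(pair$pred), ref = tile(pair$ref)), perfect)
  mean_small <- mean(c(2 / 3, 1))
  mean_inflated <- mean(c(2 / 3, 1))
  expect_equal(mean_small, mean_inflated)
  expect_lt(as.numeric(agg_dsc(inflated, 1L)), as.numeric(agg_dsc(small, 1L)))
})

test_that("dsc and agg_dsc match the brute-force set oracle on random grids", {
  set.seed(31)
  for (i in 1:100) {
    shape <- sample(3:6, 3, TRUE)
    a <- random_labelmap(shape); b <- random_labelmap(shape)
    for (lab in 1:2)
      expect_equal(as.numeric(dsc(a, b, lab)), dice_oracle(a, b, lab),
                   tolerance = 1e-12)
  }
  set.seed(32)
  pairs <- lapply(1:6, function(i) {
    shape <- c(4, 4, 4)
    list(pred = random_labelmap(shape), ref = random_labelmap(shape))
  })
  for (lab in 1:2)
    expect_equal(as.numeric(agg_dsc(pairs, lab)), aggdice_oracle(pairs, lab),
                 tolerance = 1e-12)
})

test_that("Wilcoxon p-values match exhaustive sign enumeration for small n", {
  set.seed(41)
  # assorted cases, including ties in |d| and within-vector ties
  cases <- list(
    list(a = c(1, 2, 3, 4, 5, 6), b = c(2, 1, 5, 2, 8, 3)),
    list(a = rnorm(8), b = rnorm(8)),
    list(a = c(1, 1, 2, 2, 3, 3, 4), b = c(0, 2, 1, 3, 2, 4, 2)),
    list(a = round(rnorm(10), 1), b = round(rnorm(10), 1))
  )
  for (cs in cases) {
    keep <- cs$a != cs$b
    got <- wilcoxon_paired(cs$a, cs$b)
    expect_equal(got$p, wilcoxon_oracle(cs$a, cs$b), tolerance = 1e-12)
    expect_equal(got$n_used, sum(keep))
  }
  # constant positive shift, n = 8: minimal exact two-sided p = 2 / 2^8
  a <- 1:8 / 10 + 0.5
  got <- wilcoxon_paired(a, a - 0.5)
  expect_equal(got$p, 2 / 2^8, tolerance = 1e-12)
  expect_true(got$significant)
})

test_that("Wilcoxon agrees with stats::wilcox.test where both are exact", {
  set.seed(42)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    while (anyDuplicated(abs(a - b))) b <- rnorm(12)
    got <- wilcoxon_paired(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_equal(as.numeric(got$statistic), as.numeric(ref$statistic))
  }
  # large-n path: normal approximation with tie correction
  set.seed(43)
  a <- rnorm(30); b <- a + rnorm(30, 0.3)
  got <- wilcoxon_paired(a, b)
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("identical inputs are degenerate and non-significant", {
  got <- wilcoxon_paired(rep(1, 6), rep(1, 6))
  expect_true(got$degenerate)
  expect_false(got$significant)
  expect_equal(got$p, 1)
})

test_that("evaluation results carry per-case and aggregated scores", {
  set.seed(51)
  pairs <- lapply(1:4, function(i) {
    shape <- c(6, 6, 4)
    list(pred = random_labelmap(shape), ref = random_labelmap(shape))
  })
  names(pairs) <- sprintf("case_%d", 1:4)
  ev <- evaluate_pairs(pairs)
  expect_equal(ev$n_cases, 4L)
  expect_equal(ev$aggregated$avg_agg_dsc,
               (ev$aggregated$agg_dsc_gtvp + ev$aggregated$agg_dsc_gtvn) / 2)
  expect_true(all(ev$per_case$mean_dsc >= 0 & ev$per_case$mean_dsc <= 1))
  expect_equal(ev$per_case$mean_dsc,
               (ev$per_case$dsc_gtvp + ev$per_case$dsc_gtvn) / 2)
})

test_that("report tables star significantly different configurations only", {
  set.seed(52)
  ref_maps <- lapply(1:8, function(i) random_labelmap(c(6, 6, 4), p_fg = 0.4))
  good <- lapply(ref_maps, function(r) list(pred = r, ref = r))
  bad <- lapply(ref_maps, function(r) {
    p <- r$labels
    flip <- which(p > 0)
    p[flip[seq_len(ceiling(length(flip) * 0.6))]] <- 0L
    list(pred = labelmap(p), ref = r)
  })
  names(good) <- names(bad) <- sprintf("case_%d", 1:8)
  rep1 <- eval_report(list(good = evaluate_pairs(good),
                           worse = evaluate_pairs(bad)))
  expect_equal(rep1$best, "good")
  expect_equal(rep1$summary$star[rep1$summary$configuration == "worse"], "*")
  expect_equal(colnames(rep1$summary),
               c("configuration", "agg_dsc_gtvp", "agg_dsc_gtvn",
                 "avg_agg_dsc", "p_vs_best", "star"))

  rep2 <- eval_report(list(a = evaluate_pairs(good), b = evaluate_pairs(good)))
  expect_false(any(rep2$summary$star == "*"))

  other <- good; names(other) <- sprintf("case_%d", 11:18)
  expect_error(eval_report(list(a = evaluate_pairs(good),
                                b = evaluate_pairs(other))), "case sets")
})

test_that("report CSVs are written when requested", {
  set.seed(53)
  pairs <- lapply(1:3, function(i) {
    r <- random_labelmap(c(5, 5, 3)); list(pred = r, ref = r)
  })
  names(pairs) <- sprintf("case_%d", 1:3)
  out <- withr::local_tempdir()
  eval_report(list(only = evaluate_pairs(pairs)), out_dir = out)
  expect_true(file.exists(file.path(out, "summary.csv")))
  got <- read.csv(file.path(out, "per_case.csv"))
  expect_equal(nrow(got), 3)
  expect_true(all(got$mean_dsc == 100))
})
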