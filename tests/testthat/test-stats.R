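# Normalization, imputation, two-group testing, fold change, overlap tests.

mini_pt <- function(x) {
  rownames(x) <- sprintf("S%d", seq_len(nrow(x)))
  colnames(x) <- paste0(seq_len(ncol(x)) + 100, "+")
  peak_table(x)
}

test_that("total-sum, transforms and scalings behave by definition", {
  pt <- mini_pt(matrix(1, 2, 2))
  expect_equal(unname(normalize_peaks(pt, "total-sum")$intensities),
               matrix(0.5, 2, 2))
  expect_equal(normalize_peaks(pt)$intensities, pt$intensities)  # identity

  set.seed(5)
  pt2 <- mini_pt(matrix(rexp(60, 0.01), 10, 6))
  sc <- normalize_peaks(pt2, scale = "auto")$intensities
  expect_equal(unname(colMeans(sc)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(sc, 2, sd)), rep(1, 6), tolerance = 1e-9)

  lg <- normalize_peaks(pt2, transform = "log10")$intensities
  expect_equal(lg, log10(pt2$intensities + 1))

  zero <- mini_pt(rbind(c(1, 2), c(0, 0)))
  expect_error(normalize_peaks(zero, "total-sum"), "S2")
})

test_that("imputation fills every cell without touching observed data", {
  set.seed(6)
  x <- matrix(rlnorm(80, 8, 1), 10, 8)
  x[sample(80, 12)] <- NA
  pt <- mini_pt(x)
  for (st in c("half-min", "knn", "rf")) {
    out <- impute_missing(pt, st, seed = 42)
    expect_false(anyNA(out$intensities))
    obs <- !is.na(x)
    expect_equal(out$intensities[obs], x[obs])
  }
  # half-min definition
  x2 <- matrix(c(10, 20, NA, 40), 4, 1)
  expect_equal(impute_missing(mini_pt(x2), "half-min")$intensities[3, 1], 5)
  # identity when complete
  full <- mini_pt(matrix(1:12, 3, 4) * 1.0)
  expect_equal(impute_missing(full, "rf")$intensities, full$intensities)
})

test_that("stochastic imputation is reproducible under a fixed seed", {
  set.seed(7)
  x <- matrix(rlnorm(60, 8, 1), 10, 6)
  x[sample(60, 8)] <- NA
  pt <- mini_pt(x)
  a <- impute_missing(pt, "rf", seed = 11)
  b <- impute_missing(pt, "rf", seed = 11)
  expect_identical(a$intensities, b$intensities)
})

test_that("features with no observations are dropped with a warning", {
  x <- matrix(rlnorm(20), 5, 4)
  x[, 2] <- NA
  expect_warning(out <- impute_missing(mini_pt(x), "half-min"), "dropping 1")
  expect_equal(ncol(out$intensities), 3)
})

test_that("two-group t-tests flag degenerate features and control inputs", {
  exp1 <- gen_peak_experiment(n_per_group = 10, n_features = 30,
                              n_planted = 5, effect = 3, seed = 21)
  res <- ttest_all(exp1$peaks, exp1$meta, "group")
  expect_equal(nrow(res), 30)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12, na.rm = TRUE))
  expect_true(all(res$p_adjusted <= 1, na.rm = TRUE))
  # BH is order-preserving in p
  ok <- !is.na(res$p_value)
  expect_equal(order(res$p_value[ok]), order(res$p_adjusted[ok], res$p_value[ok]))

  # constant features: flagged, not tested
  x <- matrix(7, 4, 4)
  pt <- mini_pt(x)
  ids <- rownames(pt$intensities)
  meta <- data.frame(sample = ids, group = c("a", "a", "b", "b"))
  res2 <- ttest_all(pt, meta, "group")
  expect_true(all(res2$constant))
  expect_true(all(is.na(res2$p_value)))

  # paired test where both members of every pair agree: difference constant
  xp <- matrix(rep(c(1, 2, 1, 2), 4), 4, 4)
  ptp <- mini_pt(xp)
  resp <- ttest_all(ptp, meta, "group", paired = TRUE)
  expect_true(all(resp$constant))
  expect_true(all(is.na(resp$p_value)))

  meta3 <- data.frame(sample = ids, group = c("a", "b", "c", "c"))
  expect_error(ttest_all(pt, meta3, "group"), "multivariate")
})

test_that("planted shifts are recovered at FDR 0.05", {
  exp1 <- gen_peak_experiment(n_per_group = 20, n_features = 200,
                              n_planted = 20, effect = 2, seed = 22)
  res <- ttest_all(exp1$peaks, exp1$meta, "group")
  hit <- res$feature[!is.na(res$p_adjusted) & res$p_adjusted < 0.05]
  planted <- exp1$truth$feature[exp1$truth$planted]
  expect_gte(length(intersect(hit, planted)), 16)   # >= 80% power
  # discoveries are strongly enriched for planted features
  expect_gt(mean(hit %in% planted), 0.5)
})

test_that("paired tests detect consistent within-pair shifts", {
  set.seed(23)
  n <- 12
  base <- matrix(rlnorm(n * 5, 8, 0.5), n, 5)
  after <- base * matrix(rep(c(1.6, 1, 1, 1, 1), each = n), n, 5) *
    rlnorm(n * 5, 0, 0.05)
  x <- rbind(base, after)
  pt <- mini_pt(x)
  meta <- data.frame(sample = rownames(pt$intensities),
                     time = rep(c("pre", "post"), each = n))
  res <- ttest_all(pt, meta, "time", paired = TRUE)
  expect_lt(res$p_adjusted[1], 0.01)
})

test_that("fold change is a raw-scale log2 ratio with flagged zeros", {
  x <- rbind(matrix(1, 3, 2), matrix(c(4, 4, 4, 1, 1, 1), 3, 2))
  pt <- mini_pt(x)
  meta <- data.frame(sample = rownames(pt$intensities),
                     group = rep(c("g1", "g2"), each = 3))
  fc <- fold_change(pt, meta, "group")
  expect_equal(fc$log2_fc, c(2, 0))
  expect_false(any(fc$fc_undefined))

  x0 <- rbind(matrix(0, 3, 1), matrix(2, 3, 1))
  fc0 <- fold_change(mini_pt(x0), data.frame(
    sample = sprintf("S%d", 1:6), group = rep(c("g1", "g2"), each = 3)),
    "group")
  expect_true(fc0$fc_undefined)
})

test_that("volcano input is consistent with the test results", {
  exp1 <- gen_peak_experiment(n_per_group = 8, n_features = 20, seed = 30)
  res <- ttest_all(exp1$peaks, exp1$meta, "group")
  vd <- volcano_data(res)
  i <- match(vd$feature, res$feature)
  expect_equal(vd$log2_fc, res$log2_fc[i])
  expect_equal(vd$neg_log10_p, -log10(res$p_adjusted[i]))
})

test_that("hypergeometric overlap p matches exhaustive enumeration", {
  cases <- list(c(10, 4, 5), c(12, 6, 4), c(15, 5, 6), c(20, 8, 6),
                c(18, 3, 9))
  for (cs in cases) {
    N <- cs[1]; nA <- cs[2]; nB <- cs[3]
    for (k in 0:min(nA, nB)) {
      a <- paste0("f", seq_len(nA))
      # construct lists with exactly k overlapping members
      b <- c(if (k > 0) paste0("f", seq_len(k)),
             if (k < nB) paste0("f", seq(nA + 1, length.out = nB - k)))
      p <- hypergeom_overlap(a, b, N)
      expect_equal(p, enumerate_overlap_p(N, nA, nB, k), tolerance = 1e-12)
    }
  }
})

test_that("hypergeometric overlap handles the degenerate and bound cases", {
  u <- paste0("f", 1:8)
  expect_equal(hypergeom_overlap(u, u, u), 1.0)
  # zero overlap: p is the chance of >= 0 overlap, i.e. exactly 1
  a <- paste0("f", 1:3); b <- paste0("f", 4:6)
  p0 <- hypergeom_overlap(a, b, u)
  expect_true(p0 > 0 && p0 <= 1)
  expect_error(hypergeom_overlap(c(a, "zz"), b, u), "zz")
})

test_that("sample subsetting keeps peaks and metadata consistent", {
  exp1 <- gen_peak_experiment(n_per_group = 6, n_features = 10, seed = 40)
  all_in <- subset_samples(exp1$peaks, exp1$meta, function(m) rep(TRUE, nrow(m)))
  expect_equal(all_in$peaks$intensities, exp1$peaks$intensities)

  cases <- subset_samples(exp1$peaks, exp1$meta,
                          function(m) m$group == "case")
  controls <- subset_samples(exp1$peaks, exp1$meta,
                             function(m) m$group == "control")
  expect_equal(nrow(cases$peaks$intensities) + nrow(controls$peaks$intensities),
               nrow(exp1$peaks$intensities))
  expect_equal(ncol(cases$peaks$intensities), ncol(exp1$peaks$intensities))

  # statistics on a subset equal statistics on a manually filtered copy
  manual <- exp1$peaks
  keep <- exp1$meta$group == "case"
  manual$intensities <- manual$intensities[keep, , drop = FALSE]
  expect_equal(colMeans(cases$peaks$intensities),
               colMeans(manual$intensities))
  expect_error(subset_samples(exp1$peaks, exp1$meta,
                              function(m) rep(FALSE, nrow(m))),
               "no samples")
})
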