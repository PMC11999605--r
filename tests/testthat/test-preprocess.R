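make_conc <- function(values, censored, condition = "stimulated") {
  rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  colnames(values) <- sprintf("M%02d", seq_len(ncol(values)))
  dimnames(censored) <- dimnames(values)
  concentration_matrix(condition, values, censored)
}

test_that("detection filter excludes at >= 80% censored in both groups", {
  # 10 + 10 samples, one metabolite per censoring scenario
  cens_counts <- rbind(c(8, 8),   # boundary: excluded ("at least 80%")
                       c(8, 7),   # kept: only one group at the boundary
                       c(10, 8),  # excluded
                       c(0, 0))   # kept, fractions 0
  m <- nrow(cens_counts)
  vals <- matrix(1, 20, m)
  cens <- matrix(FALSE, 20, m)
  for (j in seq_len(m)) {
    cens[seq_len(cens_counts[j, 1]), j] <- TRUE
    cens[10 + seq_len(cens_counts[j, 2]), j] <- TRUE
  }
  vals[cens] <- 0
  cm <- make_conc(vals, cens)
  groups <- rep(c("A", "B"), each = 10)
  res <- detection_filter(cm, groups, threshold = 0.8)
  expect_identical(res$kept, c("M02", "M04"))
  expect_equal(res$report$frac_censored_a, c(0.8, 0.8, 1.0, 0))
  expect_equal(res$report$frac_censored_b, c(0.8, 0.7, 0.8, 0))
  expect_error(detection_filter(cm, rep("A", 20)), "two groups")
  expect_error(detection_filter(cm, groups, threshold = 0), "threshold")
})

test_that("raising the filter threshold never drops a kept metabolite", {
  set.seed(42)
  for (rep_i in 1:5) {
    vals <- matrix(runif(20 * 8), 20, 8)
    cens <- matrix(runif(20 * 8) < runif(1, 0.3, 0.95), 20, 8)
    vals[cens] <- 0
    cm <- make_conc(vals, cens)
    groups <- rep(c("A", "B"), each = 10)
    kept <- lapply(c(0.5, 0.7, 0.9), function(t)
      detection_filter(cm, groups, t)$kept)
    expect_true(all(kept[[1]] %in% kept[[2]]))
    expect_true(all(kept[[2]] %in% kept[[3]]))
  }
})

test_that("substitution schemes replace exactly the censored cells", {
  vals <- matrix(c(0, 0.5, 0, 0.8), 4, 1)
  cens <- matrix(c(TRUE, FALSE, TRUE, FALSE), 4, 1)
  cm <- make_conc(vals, cens)
  pan <- panel("M01", "COX", lod = 0.01)
  z <- substitute_censored(cm, pan, "zero")
  expect_equal(sum(z$values == 0), 2L)
  expect_equal(unname(z$values[c(2, 4), 1]), c(0.5, 0.8))
  h <- substitute_censored(cm, pan, "half_lod")
  expect_equal(unname(h$values[c(1, 3), 1]), c(0.005, 0.005))
  # no censored cells: identity under every scheme
  cm2 <- make_conc(matrix(c(0.2, 0.3), 2, 1), matrix(FALSE, 2, 1))
  for (s in c("zero", "half_lod", "km"))
    expect_equal(substitute_censored(cm2, pan, s)$values, cm2$values)
})

test_that("reversed Kaplan-Meier matches the independent product-limit", {
  # no censoring: reduces to the empirical distribution
  v <- c(0.21, 0.34, 0.55, 0.8)
  km <- km_left_censored(v, rep(FALSE, 4), lod = 0.1)
  expect_equal(km$mean, mean(v))
  expect_equal(km$p_below_lod, 0)

  # the worked example: one value below LOD 0.1, three detected
  v <- c(0, 0.2, 0.3, 0.4)
  cens <- c(TRUE, FALSE, FALSE, FALSE)
  km <- km_left_censored(v, cens, lod = 0.1)
  orc <- oracle_km(v, cens, lod = 0.1)
  expect_equal(km$mean, orc$mean)
  expect_equal(km$mean, 0.25 * (0.2 + 0.3 + 0.4) + 0.25 * 0.05)
  expect_equal(km$p_below_lod, 0.25)
  expect_equal(km$mean_below_lod, 0.05)

  # single uncensored value v0 with one censored: hand product-limit
  # puts mass 1/2 on v0 and 1/2 below the LOD
  km <- km_left_censored(c(0.3, 0), c(FALSE, TRUE), lod = 0.1)
  expect_equal(km$dist$prob, c(0.5, 0.5))
  expect_equal(km$mean, 0.3 / 2 + 0.05 / 2)

  # interleaved case (a detected value below the nominal LOD) and larger
  # random cases against the oracle
  v <- c(0.05, 0.2, 0.35, 0, 0)
  cens <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  km <- km_left_censored(v, cens, lod = 0.1)
  orc <- oracle_km(v, cens, lod = 0.1)
  expect_equal(km$mean, orc$mean)
  set.seed(7)
  for (i in 1:5) {
    n <- sample(5:12, 1)
    v <- round(rlnorm(n, log(0.2), 1), 4)
    cens <- v < 0.1
    if (all(cens) || !any(cens)) next
    v[cens] <- 0
    expect_equal(km_left_censored(v, cens, 0.1)$mean,
                 oracle_km(v, cens, 0.1)$mean)
  }
  expect_error(km_left_censored(c(0, 0), c(TRUE, TRUE), 0.1),
               "all values censored")
})

test_that("km substitution falls back to zero when nothing is detected", {
  vals <- matrix(0, 3, 1)
  cens <- matrix(TRUE, 3, 1)
  cm <- make_conc(vals, cens)
  pan <- panel("M01", "COX", lod = 0.01)
  expect_warning(out <- substitute_censored(cm, pan, "km"), "falls back")
  expect_equal(unname(out$values), matrix(0, 3, 1))
})

test_that("baseline subtraction is cellwise, sign-preserving and linear", {
  a <- make_conc(matrix(c(0.5, 0.1), 2, 1), matrix(FALSE, 2, 1))
  b <- make_conc(matrix(c(0.2, 0.4), 2, 1), matrix(FALSE, 2, 1),
                 condition = "baseline")
  d <- baseline_subtract(a, b)
  expect_equal(unname(d), matrix(c(0.3, -0.3), 2, 1))
  expect_equal(unname(baseline_subtract(a, a)), matrix(0, 2, 1))
  # shift invariance: (a + c) - (b + c) = a - b
  shift <- matrix(0.7, 2, 1)
  a2 <- make_conc(a$values + shift, matrix(FALSE, 2, 1))
  b2 <- make_conc(b$values + shift, matrix(FALSE, 2, 1),
                  condition = "baseline")
  expect_equal(baseline_subtract(a2, b2), d)
})

test_that("WBC normalization divides rows by the subject's count", {
  diffs <- matrix(c(0.3, 0.3), 2, 1,
                  dimnames = list(c("s1", "s2"), "M01"))
  sm <- sample_meta(c("s1", "s2"), c("control", "moderate"),
                    c(FALSE, FALSE), c(6.0, 7.87))
  net <- wbc_normalize(diffs, sm)
  expect_equal(net$values["s1", 1], 0.05)
  expect_equal(net$values["s2", 1], 0.3 / 7.87)
  # equal raw differences, table-level WBC means: asthma rows scaled by
  # the WBC ratio relative to controls
  expect_equal(net$values["s2", 1] / net$values["s1", 1], 6.0 / 7.87)
  expect_error(wbc_normalize(diffs, sample_meta(c("s1", "s2"),
                                                c("control", "moderate"),
                                                FALSE, c(6, -1))), "wbc")
})

test_that("equal WBC counts leave the rank tests unchanged", {
  set.seed(31)
  vals <- matrix(rlnorm(16 * 3), 16, 3)
  groups <- rep(c("control", "moderate"), each = 8)
  net1 <- make_net(vals, groups, wbc = 6)
  net5 <- make_net(vals, groups, wbc = 5)  # common positive rescale
  f1 <- run_contrast(net1, CTRL_VS_MOD, B = 300, seed = 2)
  f5 <- run_contrast(net5, CTRL_VS_MOD, B = 300, seed = 2)
  expect_identical(f1$p_raw, f5$p_raw)
  expect_identical(f1$statistic, f5$statistic)
})

test_that("any common sub-detection constant gives identical rank tests", {
  # censored cells replaced by different constants below every uncensored
  # value: Wilcoxon statistics and permutation p-values cannot change
  set.seed(12)
  vals <- matrix(rlnorm(20 * 4, log(0.3), 0.8), 20, 4)
  cens <- vals < 0.15
  groups <- rep(c("control", "moderate"), each = 10)
  fits <- lapply(c(0, 0.075, 0.1), function(const) {
    v <- vals
    v[cens] <- const
    run_contrast(make_net(v, groups), CTRL_VS_MOD, B = 400, seed = 9)
  })
  expect_identical(fits[[1]]$p_raw, fits[[2]]$p_raw)
  expect_identical(fits[[1]]$p_adj, fits[[3]]$p_adj)
  expect_identical(fits[[1]]$stat_centered, fits[[3]]$stat_centered)
})
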