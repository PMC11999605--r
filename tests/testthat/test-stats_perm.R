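test_that("rank_sum uses pooled midranks", {
  expect_equal(rank_sum(c(1, 2, 3), c(4, 5, 6)), 6)        # minimum
  expect_equal(rank_sum(c(1, 1), c(1, 2)), 4)              # midranks 2,2,2,4
  x <- c(2, 5, 9)
  expect_equal(rank_sum(x, x), 3 * (6 + 1) / 2)            # symmetry
  expect_error(rank_sum(numeric(0), 1), "empty")
  expect_error(rank_sum(c(1, NA), c(2, 3)), "finite")
})

test_that("ensembles preserve group sizes and reproduce from the seed", {
  is_a <- rep(c(TRUE, FALSE), c(3, 5))
  e1 <- build_ensemble(is_a, B = 500, seed = 11)
  e2 <- build_ensemble(is_a, B = 500, seed = 11)
  expect_identical(e1, e2)
  expect_identical(e1$labels[1, ], is_a)                   # identity first
  expect_true(all(rowSums(e1$labels) == 3))
  e3 <- build_ensemble(is_a, B = 500, seed = 12)
  expect_false(identical(e1$labels, e3$labels))
  expect_error(build_ensemble(is_a, B = 0), "B")
  expect_error(build_ensemble(rep(TRUE, 4)), "non-empty")

  ex <- build_ensemble(rep(c(TRUE, FALSE), each = 3), exhaustive = TRUE)
  expect_equal(nrow(ex$labels), choose(6, 3))              # all 20
  expect_false(anyDuplicated(ex$labels) > 0)
  expect_identical(ex$labels[1, ], rep(c(TRUE, FALSE), each = 3))
})

test_that("perm_pvalue follows the (1 + b) / (B + 1) convention", {
  expect_equal(perm_pvalue(10, rep(1, 99)), 1 / 100)  # strictly most extreme
  expect_equal(perm_pvalue(5, rep(5, 99)), 1)         # ties count as extreme
  expect_equal(perm_pvalue(0, rep(5, 9)), 1)
  # constant data: every assignment gives the same statistic, p = 1
  fit <- run_contrast(toy_net(rep(2, 5), rep(2, 5)), CTRL_VS_MOD,
                      B = 200, seed = 1)
  expect_equal(fit$p_raw, 1)
  expect_equal(fit$p_adj, 1)
})

test_that("exhaustive mode equals brute-force and exact Wilcoxon", {
  set.seed(5)
  for (sizes in list(c(3, 3), c(4, 2), c(5, 5), c(6, 6), c(4, 8))) {
    x <- round(rnorm(sizes[1]), 3)
    y <- round(rnorm(sizes[2], 0.5), 3)
    stopifnot(!anyDuplicated(c(x, y)))
    fit <- run_contrast(toy_net(x, y), CTRL_VS_MOD, B = 50, seed = 1)
    expect_true(attr(fit, "exhaustive"))
    expect_equal(fit$p_raw, enum_perm_p(x, y))
    # independent exact-enumeration oracle from base R
    expect_equal(fit$p_raw,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # worked enumeration: {1,2,3} vs {4,5,6} -> 2 of 20 assignments extreme
  fit <- run_contrast(toy_net(c(1, 2, 3), c(4, 5, 6)), CTRL_VS_MOD,
                      B = 50, seed = 1)
  expect_equal(fit$p_raw, 0.1)
})

test_that("random-ensemble p approaches the exhaustive p as B grows", {
  x <- c(0.3, 1.2, 2.2, 0.9)
  y <- c(1.7, 2.9, 3.4, 2.6)
  exact <- enum_perm_p(x, y)
  fit <- run_contrast(toy_net(x, y), CTRL_VS_MOD, B = 20000, seed = 3,
                      exhaustive_max_n = 0)   # force random sampling
  expect_false(attr(fit, "exhaustive"))
  expect_lt(abs(fit$p_raw - exact), 3 * sqrt(exact * (1 - exact) / 20000) +
              1 / 20000)
})

test_that("step-down adjustment honours its contracts", {
  # single hypothesis: adjusted equals raw (minP degenerates)
  fit <- run_contrast(toy_net(c(1, 2, 3), c(4, 5, 6)), CTRL_VS_MOD,
                      B = 100, seed = 1)
  expect_equal(fit$p_adj, fit$p_raw)

  # all raw p = 1 stays 1
  expect_equal(stepdown_adjust(rep(1, 4), matrix(1, 4, 10)), rep(1, 4))
  expect_equal(stepdown_adjust(rep(1, 4), method = "bh"), rep(1, 4))

  # BH by hand
  expect_equal(stepdown_adjust(c(0.01, 0.02, 0.03), method = "bh"),
               rep(0.03, 3))

  # duplicated (perfectly correlated) metabolites: minP adjusts nothing
  set.seed(8)
  x <- rnorm(12); y <- rnorm(12, 1)
  vals <- matrix(rep(c(x, y), 4), ncol = 4)
  fit <- run_contrast(make_net(vals, rep(c("control", "moderate"),
                                         each = 12)),
                      CTRL_VS_MOD, B = 500, seed = 21)
  expect_equal(fit$p_adj, fit$p_raw)

  # monotone in the raw-p ordering, never below raw, never above 1
  vals <- matrix(rnorm(24 * 6), 24, 6)
  fit <- run_contrast(make_net(vals, rep(c("control", "moderate"),
                                         each = 12)),
                      CTRL_VS_MOD, B = 400, seed = 5)
  ord <- order(fit$p_raw)
  expect_true(all(diff(fit$p_adj[ord]) >= 0))
  expect_true(all(fit$p_adj >= fit$p_raw))
  expect_true(all(fit$p_adj <= 1))
  fit_bh <- run_contrast(make_net(vals, rep(c("control", "moderate"),
                                            each = 12)),
                         CTRL_VS_MOD, B = 400, seed = 5, method = "bh")
  expect_true(all(fit_bh$p_adj >= fit_bh$p_raw))
})

test_that("results are invariant to subject row order", {
  set.seed(17)
  vals <- matrix(rlnorm(20 * 3), 20, 3,
                 dimnames = list(sprintf("s%02d", 1:20), c("A", "B", "C")))
  groups <- rep(c("control", "moderate"), each = 10)
  net <- make_net(vals, groups)
  perm <- sample(20)
  net_shuf <- make_net(vals[perm, ], groups[perm])
  f1 <- run_contrast(net, CTRL_VS_MOD, B = 300, seed = 4)
  f2 <- run_contrast(net_shuf, CTRL_VS_MOD, B = 300, seed = 4)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
})

test_that("missing cells are dropped pairwise per metabolite", {
  set.seed(23)
  vals <- matrix(rnorm(16 * 2), 16, 2)
  vals[1:3, 2] <- NA
  net <- make_net(vals, rep(c("control", "moderate"), each = 8))
  fit <- run_contrast(net, CTRL_VS_MOD, B = 200, seed = 6)
  expect_equal(fit$n_a, c(8L, 5L))
  expect_equal(fit$n_b, c(8L, 8L))
  expect_true(all(fit$p_raw > 0 & fit$p_raw <= 1))
  # a fully missing group is an error
  vals[1:8, 2] <- NA
  expect_error(run_contrast(make_net(vals, rep(c("control", "moderate"),
                                               each = 8)),
                            CTRL_VS_MOD, B = 100, seed = 1),
               "empty group")
})

test_that("a strongly planted single effect wins the adjusted ranking", {
  wins <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    mets <- data.frame(metabolite = sprintf("M%02d", 1:8),
                       pathway = "COX", lod = 1e-6,
                       base_med = 0.1, base_sd = 0.5,
                       rel_med = 0.1, rel_sd = 1)
    cfg <- sim_config(mets, n = c(control = 30, moderate = 30, severe = 0),
                      effects = data.frame(metabolite = "M01",
                                           subgroup = "moderate", fold = 4),
                      seed = 5000 + r)
    net <- net_release(generate_cohort(cfg))
    fit <- run_contrast(net, CTRL_VS_MOD, B = 400, seed = r)
    wins <- wins + (which.min(fit$p_adj) == 1L &&
                      fit$p_adj[1] == min(fit$p_adj))
  }
  expect_gte(wins / reps, 0.95)
})
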