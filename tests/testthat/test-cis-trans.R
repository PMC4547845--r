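test_that("delta-method SE matches hand arithmetic and Monte-Carlo propagation", {
  se <- splicecistrans:::log_ratio_se(0.8, 0.0016, 0.4, 0.0024)
  expect_equal(se, sqrt(0.0016 / 0.64 + 0.0024 / 0.16), tolerance = 1e-12)
  expect_equal(se, 0.1323, tolerance = 1e-3)
  expect_equal(log(0.8) - log(0.4), log(2))

  # Monte-Carlo check from Beta posteriors
  set.seed(61)
  a1 <- 81; b1 <- 21; a2 <- 41; b2 <- 61
  x1 <- rbeta(2e5, a1, b1); x2 <- rbeta(2e5, a2, b2)
  mc_sd <- sd(log(x1) - log(x2))
  p1 <- a1 / (a1 + b1); v1 <- a1 * b1 / ((a1 + b1)^2 * (a1 + b1 + 1))
  p2 <- a2 / (a2 + b2); v2 <- a2 * b2 / ((a2 + b2)^2 * (a2 + b2 + 1))
  expect_equal(splicecistrans:::log_ratio_se(p1, v1, p2, v2), mc_sd,
               tolerance = 0.05)
})

test_that("ratio_and_se pools replicates and shrinks with depth", {
  counts <- tibble::tibble(
    event_id = "e1", sample = rep(c("parent_B", "parent_S"), each = 3),
    replicate = rep(1:3, 2), allele = "pooled",
    n_inclusion = c(40L, 42L, 38L, 20L, 22L, 18L),
    n_exclusion = c(10L, 8L, 12L, 30L, 28L, 32L)
  )
  r <- ratio_and_se(counts, "parent_B", "parent_S")
  expect_equal(r$psi1, (120 + 1) / (150 + 2))
  expect_gt(r$log_ratio, 0)
  doubled <- dplyr::mutate(counts, n_inclusion = n_inclusion * 2L,
                           n_exclusion = n_exclusion * 2L)
  expect_lt(ratio_and_se(doubled, "parent_B", "parent_S")$se, r$se)
  # identical sides give a zero log ratio
  same <- dplyr::mutate(counts, n_inclusion = 30L, n_exclusion = 20L)
  expect_equal(ratio_and_se(same, "parent_B", "parent_S")$log_ratio, 0)
})

test_that("the interaction z-test matches the normal CDF oracle", {
  par <- tibble::tibble(event_id = c("a", "b"), log_ratio = c(0.5, 0.3),
                        se = c(0.1, 0.2))
  all_ <- tibble::tibble(event_id = c("a", "b"), log_ratio = c(0.0, 0.3),
                         se = c(0.1, 0.1))
  tz <- trans_z_test(par, all_)
  expect_equal(tz$z_value[1], 0.5 / sqrt(0.02))
  expect_equal(tz$z_value[1], 3.5355, tolerance = 1e-4)
  expect_equal(tz$p_value[1], 2 * (1 - pnorm(0.5 / sqrt(0.02))))
  expect_equal(tz$p_value[1], 4.1e-4, tolerance = 2e-2)
  expect_equal(tz$z_value[2], 0)
  expect_equal(tz$p_value[2], 1)
  bad <- dplyr::mutate(par, se = 0)
  expect_error(trans_z_test(bad, all_), "positive")
})

test_that("the trans test is calibrated on pure-cis data", {
  cfg <- sim_config(n_events = 2000, frac_cis = 1, frac_trans = 0,
                    frac_both = 0, depth_mean = 200, seed = 62)
  ds <- simulate_dataset(cfg)
  par <- dplyr::filter(ds$counts, sample %in% c("parent_B", "parent_S"))
  hyb <- dplyr::filter(ds$counts, sample == "hybrid")
  tz <- trans_z_test(ratio_and_se(par, "parent_B", "parent_S"),
                     ratio_and_se(hyb, "B", "S", by = "allele"))
  expect_lte(mean(tz$p_value < 0.05), 1.5 * 0.05)
})

test_that("Storey q-values behave on degenerate and uniform input", {
  expect_equal(storey_qvalues(rep(1, 200)), rep(1, 200))
  expect_equal(storey_qvalues(numeric()), numeric())
  set.seed(63)
  p <- runif(10000)
  q <- storey_qvalues(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  # recover pi0 ~ 1 under the uniform null
  pi0_hat <- max(q)  # q at the largest p equals pi0 * m * p / m ~ pi0
  expect_true(pi0_hat >= 0.9 && pi0_hat <= 1)
  # with planted signal, small p-values get small q-values
  p2 <- c(rep(1e-8, 50), runif(950))
  q2 <- storey_qvalues(p2)
  expect_true(all(q2[1:50] < 0.01))
})

test_that("classification implements the category truth table", {
  mk_calls <- function(div) tibble::tibble(event_id = sprintf("e%d", 1:5),
                                           divergent = div)
  par <- mk_calls(c(TRUE, TRUE, TRUE, TRUE, FALSE))
  all_ <- mk_calls(c(TRUE, TRUE, FALSE, FALSE, FALSE))
  tr <- tibble::tibble(event_id = sprintf("e%d", 1:5),
                       z_value = c(0.1, 5, 5, 0.1, 0.1),
                       p_value = c(0.9, 1e-8, 1e-8, 0.9, 0.9))
  cl <- classify_cis_trans(par, all_, tr, trans_fdr_cutoff = 0.05)
  expect_equal(cl$category,
               c("cis_only", "cis_and_trans", "trans_only", "unexplained",
                 "conserved"))
  # categories partition the event set
  expect_equal(sort(cl$event_id), sprintf("e%d", 1:5))
  expect_error(classify_cis_trans(par, all_[1:3, ], tr), "same events")
})

test_that("global strain swap flips ratios but preserves categories", {
  cfg <- sim_config(n_events = 400, frac_cis = 0.3, frac_trans = 0.1,
                    frac_both = 0, depth_mean = 300, seed = 64)
  ds <- simulate_dataset(cfg)
  keep <- coverage_filter(ds$counts, 20)
  cnt <- dplyr::filter(ds$counts, event_id %in% keep)
  par <- dplyr::filter(cnt, sample %in% c("parent_B", "parent_S"))
  hyb <- dplyr::filter(cnt, sample == "hybrid")
  run_one <- function(par, hyb, s1, s2, a1, a2) {
    dp <- divergence_calls(par, s1, s2)
    da <- divergence_calls(hyb, a1, a2, by = "allele")
    tz <- trans_z_test(ratio_and_se(par, s1, s2),
                       ratio_and_se(hyb, a1, a2, by = "allele"))
    classify_cis_trans(dp$calls, da$calls, tz, trans_fdr_cutoff = 0.05)
  }
  straight <- run_one(par, hyb, "parent_B", "parent_S", "B", "S")
  swapped <- run_one(par, hyb, "parent_S", "parent_B", "S", "B")
  expect_equal(abs(straight$z_value), abs(swapped$z_value), tolerance = 1e-12)
  expect_equal(straight$category, swapped$category)
})

test_that("cis share among explained events tracks the planted ratio at high depth", {
  cfg <- sim_config(n_events = 2000, frac_cis = 0.3, frac_trans = 0.1,
                    frac_both = 0, effect_size_range = c(0.3, 0.3),
                    depth_mean = 500, seed = 301)
  ds <- simulate_dataset(cfg)
  res <- run_pipeline(ds, n_permutations = 30)
  cl <- tidy(res)
  n_cis <- sum(cl$category %in% c("cis_only", "cis_and_trans"))
  n_trans <- sum(cl$category %in% c("trans_only", "cis_and_trans"))
  share <- n_cis / (n_cis + n_trans)
  expect_lt(abs(share - 0.3 / 0.4), 0.10)
})
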