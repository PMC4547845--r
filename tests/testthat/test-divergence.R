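test_that("coverage filter demands the threshold in every replicate", {
  counts <- tibble::tibble(
    event_id = rep(c("e1", "e2"), each = 3),
    sample = "parent_B", replicate = rep(1:3, 2), allele = "pooled",
    n_inclusion = c(20L, 25L, 9L, 10L, 10L, 10L),
    n_exclusion = c(5L, 5L, 10L, 10L, 10L, 10L)
  )
  expect_setequal(coverage_filter(counts, 20), "e2")  # e1 has a 19-read rep
  expect_setequal(coverage_filter(counts, 25), character())
  expect_equal(coverage_filter(counts[0, ]), character())
})

test_that("divergence rule requires every BF and the mean signed delta", {
  expect_true(call_divergent(c(6, 7, 8), c(0.2, 0.1, 0.15)))
  expect_false(call_divergent(c(6, 7, 4.9), c(0.5, 0.5, 0.5)))
  expect_false(call_divergent(c(10, 10, 10), c(0.3, -0.3, 0)))
  expect_true(call_divergent(c(10, 10, 10), c(0.3, -0.3, 0.31),
                             mean_of = "absolute"))
  # strictness at the boundary
  expect_false(call_divergent(c(5, 6, 7), c(0.2, 0.2, 0.2)))
  expect_false(call_divergent(c(6, 7, 8), c(0.1, 0.1, 0.1)))
  expect_error(call_divergent(c(6, 7), c(0.2, 0.2, 0.2)), "equal length")
  # replicate order is irrelevant
  expect_equal(call_divergent(c(6, 9, 7), c(0.2, 0.1, 0.3)),
               call_divergent(c(7, 6, 9), c(0.3, 0.2, 0.1)))
})

test_that("replicate-paired calls match scalar recomputation", {
  set.seed(51)
  counts <- tidyr::expand_grid(
    event_id = sprintf("e%02d", 1:20), sample = c("parent_B", "parent_S"),
    replicate = 1:3
  ) |>
    dplyr::mutate(
      allele = "pooled",
      n_inclusion = rbinom(dplyr::n(), 120,
                           ifelse(sample == "parent_B", 0.7, 0.4)),
      n_exclusion = 120 - n_inclusion
    )
  dc <- divergence_calls(counts, "parent_B", "parent_S")
  expect_equal(nrow(dc$replicates), 60)
  for (ev in c("e01", "e13")) {
    r <- dc$replicates[dc$replicates$event_id == ev, ]
    k <- counts[counts$event_id == ev, ]
    kb <- k[k$sample == "parent_B", ]
    ks <- k[k$sample == "parent_S", ]
    expect_equal(r$bf, bayes_factor(kb$n_inclusion, kb$n_exclusion,
                                    ks$n_inclusion, ks$n_exclusion))
    expect_equal(r$delta_psi,
                 (kb$n_inclusion + 1) / (122) - (ks$n_inclusion + 1) / (122))
    expect_equal(dc$calls$divergent[dc$calls$event_id == ev],
                 call_divergent(r$bf, r$delta_psi))
  }
})

test_that("permutation FDR follows its defining formula and vanishes without FP", {
  # strong, replicate-consistent signal: sign-flipped nulls cannot pass
  repl <- tidyr::expand_grid(event_id = sprintf("e%02d", 1:80), replicate = 1:3) |>
    dplyr::mutate(bf = 100, delta_psi = 0.105)
  fdr <- permutation_fdr(repl, cutoffs = c(0.05, 0.1), seed = 1)
  expect_equal(fdr$n_real, c(80, 80))
  # null statistic per event is |d1 - d2 - d3|/3 = 0.035 -> no FP at 0.05
  expect_equal(fdr$fdr_mean, c(0, 0))
  # cutoff above the real effect: no real positives -> undefined FDR
  fdr2 <- permutation_fdr(repl, cutoffs = 0.2, seed = 1)
  expect_true(is.na(fdr2$fdr_mean))

  # mixed magnitudes: FP counts over permutations divided by real positives
  set.seed(52)
  repl3 <- tidyr::expand_grid(event_id = sprintf("e%03d", 1:200),
                              replicate = 1:3) |>
    dplyr::mutate(bf = 100, delta_psi = rnorm(dplyr::n(), 0, 0.15))
  fdr3 <- permutation_fdr(repl3, cutoffs = seq(0.01, 0.2, 0.01),
                          n_permutations = 50, seed = 2)
  # estimates stay within [0, ~1] range and broadly decrease with cutoff
  expect_true(all(fdr3$fdr_mean >= 0, na.rm = TRUE))
  ok <- !is.na(fdr3$fdr_mean)
  expect_gte(fdr3$fdr_mean[ok][1], dplyr::last(fdr3$fdr_mean[ok]) - 0.05)
})

test_that("on null data almost nothing is called divergent", {
  cfg <- sim_config(n_events = 1500, frac_cis = 0, frac_trans = 0,
                    frac_both = 0, depth_mean = 200, seed = 53)
  ds <- simulate_dataset(cfg)
  par <- dplyr::filter(ds$counts, sample %in% c("parent_B", "parent_S"))
  keep <- coverage_filter(par, 20)
  dc <- divergence_calls(dplyr::filter(par, event_id %in% keep),
                         "parent_B", "parent_S")
  expect_lt(mean(dc$calls$divergent), 0.01)
})

test_that("control selection enforces all four criteria", {
  repl <- function(bf, psi1, psi2) {
    tibble::tibble(event_id = "e", replicate = 1:3, bf = bf,
                   psi1 = psi1, psi2 = psi2, delta_psi = psi1 - psi2)
  }
  ok <- repl(c(0.5, 0.8, 0.9), c(0.5, 0.51, 0.5), c(0.5, 0.5, 0.51))
  expect_equal(select_controls(ok), "e")
  expect_length(select_controls(repl(c(0.5, 1.2, 0.3), c(0.5, 0.5, 0.5),
                                     c(0.5, 0.5, 0.5))), 0)
  expect_length(select_controls(repl(c(0.5, 0.8, 0.9), c(0.5, 0.96, 0.5),
                                     c(0.5, 0.5, 0.5))), 0)
  expect_length(select_controls(repl(c(0.5, 0.8, 0.9), c(0.58, 0.58, 0.58),
                                     c(0.5, 0.5, 0.5))), 0)
})
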