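#' Log PSI ratio and delta-method standard error
#'
#' Pools counts across replicates on each side, takes posterior PSI means
#' and variances, and returns the natural-log ratio
#' `log(psi1) - log(psi2)` with its delta-method standard error
#' `sqrt(var1/psi1^2 + var2/psi2^2)` (independent sides). This is the
#' per-comparison summary entering the interaction test of parental versus
#' allelic ratios.
#'
#' @param counts Count tibble covering both sides.
#' @param sample1,sample2 Side labels (ratio is side1 / side2).
#' @param by Column distinguishing the sides, `"sample"` or `"allele"`.
#' @param events Optional catalog for informativeness constants.
#' @return Tibble: `event_id`, `log_ratio`, `se`, plus the pooled PSI means.
#' @export
# Delta-method SE of log(psi1) - log(psi2) for independent estimates.
log_ratio_se <- function(psi1, var1, psi2, var2) {
  sqrt(var1 / psi1^2 + var2 / psi2^2)
}

ratio_and_se <- function(counts, sample1, sample2, by = "sample",
                         events = NULL) {
  side <- counts[[by]]
  pool <- function(lbl) {
    counts[side == lbl, ] |>
      group_by(.data$event_id) |>
      summarise(n_inclusion = sum(.data$n_inclusion),
                n_exclusion = sum(.data$n_exclusion), .groups = "drop") |>
      psi_posterior(events = events)
  }
  p1 <- pool(sample1)
  p2 <- pool(sample2)
  if (any(p1$n_total == 0) || any(p2$n_total == 0)) {
    abort("zero total reads on one side; apply the coverage filter first")
  }
  inner_join(
    p1 |> select("event_id", psi1 = "psi_mean", var1 = "psi_var"),
    p2 |> select("event_id", psi2 = "psi_mean", var2 = "psi_var"),
    by = "event_id"
  ) |>
    mutate(
      log_ratio = log(.data$psi1) - log(.data$psi2),
      se = log_ratio_se(.data$psi1, .data$var1, .data$psi2, .data$var2)
    ) |>
    select("event_id", "log_ratio", "se", "psi1", "psi2")
}

#' Interaction Z-test of parental versus allelic PSI ratios
#'
#' Compares the between-strain PSI ratio with the between-allele ratio in
#' the F1 hybrid. Under pure cis regulation the two log ratios agree (both
#' alleles see one shared trans environment); a significant difference
#' indicates a trans contribution. The statistic is
#' `z = (logR_parental - logR_allelic) / sqrt(se_p^2 + se_a^2)` with a
#' two-sided standard-normal p-value (the standard ratio-comparison test of
#' two independent estimates).
#'
#' @param parental,allelic Tibbles from [ratio_and_se()] for the parental
#'   and allelic comparisons.
#' @return Tibble: `event_id`, `log_ratio_parental`, `log_ratio_allelic`,
#'   `se_parental`, `se_allelic`, `z_value`, `p_value`.
#' @export
trans_z_test <- function(parental, allelic) {
  j <- inner_join(
    parental |> select("event_id", log_ratio_parental = "log_ratio",
                       se_parental = "se"),
    allelic |> select("event_id", log_ratio_allelic = "log_ratio",
                      se_allelic = "se"),
    by = "event_id"
  )
  if (any(!is.finite(j$se_parental) | !is.finite(j$se_allelic) |
            j$se_parental <= 0 | j$se_allelic <= 0)) {
    abort("standard errors must be finite and positive")
  }
  j |>
    mutate(
      z_value = (.data$log_ratio_parental - .data$log_ratio_allelic) /
        sqrt(.data$se_parental^2 + .data$se_allelic^2),
      p_value = 2 * pnorm(-abs(.data$z_value))
    )
}

#' Storey q-values
#'
#' Converts p-values to q-values with Storey's procedure: pi0 is estimated
#' on the lambda grid 0.05, 0.10, ..., 0.95 and extrapolated with a cubic
#' smoothing spline evaluated at the largest lambda; for fewer than 100
#' tests the estimate falls back to the single point lambda = 0.5. pi0 is
#' capped at 1, and `q_i = min over p >= p_i of pi0 * m * p / rank(p)`,
#' clipped to `[0, 1]`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
storey_qvalues <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  if (m < 100) {
    pi0 <- min(1, mean(p > 0.5) / 0.5)
  } else {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- min(1, stats::predict(fit, x = max(lambda))$y)
  }
  pi0 <- max(pi0, 1e-8)
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o]), 1)
  q
}

#' Classify divergent events as cis, trans, or both
#'
#' Combines the parental and allelic divergence flags with the trans-test
#' significance into the final per-event category:
#'
#' * `cis_only`: parental and allelic divergence, trans test not significant;
#' * `trans_only`: parental divergence, no allelic divergence, trans
#'   significant;
#' * `cis_and_trans`: parental and allelic divergence with a significant
#'   trans component;
#' * `unexplained`: parental divergence with neither allelic divergence nor
#'   trans significance;
#' * `conserved`: retained but not parentally divergent.
#'
#' @param calls_parental,calls_allelic Call tibbles from
#'   [divergence_calls()]`$calls` for the parental and allelic comparisons.
#' @param trans_results Tibble from [trans_z_test()].
#' @param trans_fdr_cutoff Q-value cutoff for trans significance; by design
#'   this matches the permutation-estimated FDR of the divergence threshold
#'   on the same dataset. Default 0.05.
#' @return Tibble: `event_id`, the three flags, `z_value`, `p_value`,
#'   `q_value`, `category`.
#' @export
classify_cis_trans <- function(calls_parental, calls_allelic, trans_results,
                               trans_fdr_cutoff = 0.05) {
  ids <- sort(unique(calls_parental$event_id))
  for (nm in list(allelic = calls_allelic$event_id,
                  trans = trans_results$event_id)) {
    missing <- setdiff(ids, nm)
    extra <- setdiff(nm, ids)
    if (length(missing) > 0 || length(extra) > 0) {
      abort(sprintf(
        "inputs must cover the same events; mismatched: %s",
        paste(utils::head(c(missing, extra), 5), collapse = ", ")))
    }
  }
  tr <- trans_results |>
    mutate(q_value = storey_qvalues(.data$p_value))
  out <- tibble(event_id = ids) |>
    left_join(calls_parental |> select("event_id", parental_divergent = "divergent"),
              by = "event_id") |>
    left_join(calls_allelic |> select("event_id", allelic_divergent = "divergent"),
              by = "event_id") |>
    left_join(tr |> select("event_id", "z_value", "p_value", "q_value"),
              by = "event_id") |>
    mutate(trans_significant = .data$q_value <= trans_fdr_cutoff)
  out |>
    mutate(category = dplyr::case_when(
      !parental_divergent ~ "conserved",
      allelic_divergent & !trans_significant ~ "cis_only",
      allelic_divergent & trans_significant ~ "cis_and_trans",
      !allelic_divergent & trans_significant ~ "trans_only",
      TRUE ~ "unexplained"
    ))
}
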