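#' Coverage filter for divergence testing
#'
#' Retains events supported by at least `threshold` reads
#' (spliced-in + spliced-out) in every replicate of every sample entering
#' the comparison.
#'
#' @param counts Count tibble.
#' @param threshold Minimum reads per record. Default 20.
#' @return Character vector of retained `event_id`s.
#' @export
coverage_filter <- function(counts, threshold = 20) {
  if (nrow(counts) == 0) return(character())
  counts |>
    group_by(.data$event_id) |>
    summarise(min_total = min(.data$n_inclusion + .data$n_exclusion)) |>
    filter(.data$min_total >= threshold) |>
    pull("event_id")
}

#' Divergence decision from replicate-wise Bayes factors and PSI deltas
#'
#' An event is divergent when the Bayes factor exceeds `bf_min` in **every**
#' replicate and the absolute value of the **average** signed PSI difference
#' exceeds `delta_min` (both strict). Averaging signed deltas penalises
#' sign-inconsistent replicates; set `mean_of = "absolute"` to average
#' `|dPSI|` instead.
#'
#' @param bf_values,delta_values Equal-length vectors, one entry per
#'   replicate pair.
#' @param bf_min,delta_min Thresholds. Defaults 5 and 0.1.
#' @param mean_of `"signed"` (default) or `"absolute"`.
#' @return Logical flag.
#' @export
call_divergent <- function(bf_values, delta_values, bf_min = 5,
                           delta_min = 0.1, mean_of = c("signed", "absolute")) {
  mean_of <- match.arg(mean_of)
  if (length(bf_values) != length(delta_values)) {
    abort("bf_values and delta_values must have equal length")
  }
  if (length(bf_values) < 2) abort("need at least two replicates")
  md <- if (mean_of == "signed") abs(mean(delta_values)) else mean(abs(delta_values))
  all(bf_values > bf_min) && md > delta_min
}

#' Replicate-wise divergence statistics for a two-sample comparison
#'
#' Pairs replicate i of `sample1` with replicate i of `sample2` (index
#' pairing, the reproducible default; `pairing = "pooled"` instead pools
#' replicates into a single record pair), computes the Bayes factor and the
#' posterior-mean PSI difference for each pair, and applies the divergence
#' rule.
#'
#' @param counts Count tibble covering both samples. For allelic
#'   comparisons pass the hybrid records and name the samples by `allele`
#'   via `by = "allele"`.
#' @param sample1,sample2 Sample labels; `delta = sample1 - sample2`.
#' @param by Column distinguishing the two sides: `"sample"` (default) or
#'   `"allele"`.
#' @param events Optional catalog for informativeness constants.
#' @param bf_min,delta_min,mean_of Passed to the divergence rule.
#' @param pairing `"replicate"` (default) or `"pooled"`.
#' @return List: `replicates` (per event and replicate: `bf`, `psi1`,
#'   `psi2`, `delta_psi`) and `calls` (per event: `min_bf`,
#'   `mean_delta_psi`, `divergent`).
#' @export
divergence_calls <- function(counts, sample1, sample2, by = "sample",
                             events = NULL, bf_min = 5, delta_min = 0.1,
                             mean_of = "signed", pairing = c("replicate", "pooled")) {
  pairing <- match.arg(pairing)
  side <- counts[[by]]
  c1 <- counts[side == sample1, ]
  c2 <- counts[side == sample2, ]
  if (nrow(c1) == 0 || nrow(c2) == 0) {
    abort(sprintf("no records for one of '%s', '%s'", sample1, sample2))
  }
  if (pairing == "pooled") {
    c1 <- c1 |>
      group_by(.data$event_id) |>
      summarise(n_inclusion = sum(.data$n_inclusion),
                n_exclusion = sum(.data$n_exclusion)) |>
      mutate(replicate = 1L)
    c2 <- c2 |>
      group_by(.data$event_id) |>
      summarise(n_inclusion = sum(.data$n_inclusion),
                n_exclusion = sum(.data$n_exclusion)) |>
      mutate(replicate = 1L)
  }
  j <- inner_join(
    c1 |> select("event_id", "replicate", k1 = "n_inclusion", l1 = "n_exclusion"),
    c2 |> select("event_id", "replicate", k2 = "n_inclusion", l2 = "n_exclusion"),
    by = c("event_id", "replicate")
  )
  if (!is.null(events)) {
    idx <- match(j$event_id, events$event_id)
    ci <- events$c_inclusion[idx] %||% 1
    ce <- events$c_exclusion[idx] %||% 1
    ci[is.na(ci)] <- 1
    ce[is.na(ce)] <- 1
  } else {
    ci <- 1
    ce <- 1
  }
  eq <- all(ci == ce)
  post <- function(k, l, cc_i, cc_e) {
    if (eq) (k + 1) / (k + l + 2)
    else {
      mapply(function(kk, ll, a, b) psi_posterior_quadrature(kk, ll, a, b)$mean,
             k, l, cc_i, cc_e)
    }
  }
  repl <- j |>
    mutate(
      bf = bayes_factor(.data$k1, .data$l1, .data$k2, .data$l2, ci, ce),
      psi1 = post(.data$k1, .data$l1, ci, ce),
      psi2 = post(.data$k2, .data$l2, ci, ce),
      delta_psi = .data$psi1 - .data$psi2
    )
  calls <- repl |>
    group_by(.data$event_id) |>
    summarise(
      n_replicates = n(),
      min_bf = min(.data$bf),
      mean_delta_psi = mean(.data$delta_psi),
      mean_abs_delta_psi = mean(abs(.data$delta_psi)),
      .groups = "drop"
    ) |>
    mutate(
      divergent = .data$min_bf > bf_min &
        (if (mean_of == "signed") abs(.data$mean_delta_psi)
         else .data$mean_abs_delta_psi) > delta_min
    )
  list(replicates = repl, calls = calls,
       thresholds = list(bf_min = bf_min, delta_min = delta_min,
                         mean_of = mean_of))
}

#' Permutation-based FDR of the joint divergence threshold
#'
#' For each `|dPSI|` cutoff on a grid, estimates the false discovery rate of
#' the rule (BF > `bf_min` in all replicates, `|mean dPSI|` > cutoff) by
#' bootstrapped label permutation: each of `n_permutations` pseudo-datasets
#' resamples events with replacement and swaps the sample labels of
#' replicates 2..k between the two samples. Because the Bayes factor is
#' symmetric in its two records, a label swap leaves each replicate's BF
#' unchanged and flips the sign of its dPSI, so the null statistic is
#' `|mean(d1, -d2, ..., -dk)|`. FDR(x) is the mean over permutations of
#' (false positives) / (real events passing), the denominator counting both
#' true and false positives.
#'
#' @param replicates Per-replicate table from [divergence_calls()]
#'   (columns `event_id`, `replicate`, `bf`, `delta_psi`).
#' @param cutoffs `|dPSI|` cutoff grid. Default `seq(0.01, 0.20, 0.01)`.
#' @param bf_min BF threshold. Default 5.
#' @param n_permutations Default 100.
#' @param seed Integer seed.
#' @return Tibble: `cutoff`, `n_real`, `fdr_mean`, `fdr_sd` (`NA` where no
#'   real event passes), plus the permutation false-positive count summary
#'   `fp_mean` and its central 95% band (`fp_lo`, `fp_hi`).
#' @export
permutation_fdr <- function(replicates, cutoffs = seq(0.01, 0.20, by = 0.01),
                            bf_min = 5, n_permutations = 100, seed = 1L) {
  wide <- replicates |>
    arrange(.data$event_id, .data$replicate) |>
    group_by(.data$event_id) |>
    summarise(
      all_bf_pass = all(.data$bf > bf_min),
      mean_d = mean(.data$delta_psi),
      null_d = mean(.data$delta_psi *
                      c(1, rep(-1, dplyr::n() - 1))[seq_len(dplyr::n())]),
      .groups = "drop"
    )
  n_ev <- nrow(wide)
  n_real <- vapply(cutoffs, function(x) {
    sum(wide$all_bf_pass & abs(wide$mean_d) > x)
  }, numeric(1))
  fp <- matrix(0, n_permutations, length(cutoffs))
  with_seed(derive_seed(seed, "permfdr"), {
    for (b in seq_len(n_permutations)) {
      idx <- sample.int(n_ev, n_ev, replace = TRUE)
      pass <- wide$all_bf_pass[idx]
      nd <- abs(wide$null_d[idx])
      fp[b, ] <- vapply(cutoffs, function(x) sum(pass & nd > x), numeric(1))
    }
  })
  fdr <- sweep(fp, 2, n_real, "/")
  fdr[, n_real == 0] <- NA_real_
  tibble(
    cutoff = cutoffs,
    n_real = n_real,
    fdr_mean = colMeans(fdr),
    fdr_sd = apply(fdr, 2, sd),
    fp_mean = colMeans(fp),
    fp_lo = apply(fp, 2, quantile, probs = 0.025),
    fp_hi = apply(fp, 2, quantile, probs = 0.975)
  )
}

#' Select non-divergent control events
#'
#' Controls are well-expressed events with no evidence of divergence:
#' BF < 1 in every replicate, PSI strictly inside (`psi_low`, `psi_high`)
#' in every replicate of both samples, and `|mean dPSI|` below `delta_max`.
#'
#' @param replicates Per-replicate table from [divergence_calls()].
#' @param psi_low,psi_high Per-replicate PSI bounds. Defaults 0.05, 0.95.
#' @param bf_max Per-replicate BF bound. Default 1.
#' @param delta_max Bound on `|mean dPSI|`. Default 0.05.
#' @return Character vector of control `event_id`s.
#' @export
select_controls <- function(replicates, psi_low = 0.05, psi_high = 0.95,
                            bf_max = 1, delta_max = 0.05) {
  replicates |>
    group_by(.data$event_id) |>
    summarise(
      ok = all(.data$bf < bf_max) &
        all(.data$psi1 > psi_low & .data$psi1 < psi_high) &
        all(.data$psi2 > psi_low & .data$psi2 < psi_high) &
        abs(mean(.data$delta_psi)) < delta_max
    ) |>
    filter(.data$ok) |>
    pull("event_id")
}
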