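#' Coverage filter on mock allelic counts
#'
#' Drops events supported by fewer than `threshold` allelic reads in the
#' mock hybrid: such events have too few assignable reads for a reliable
#' allelic PSI.
#'
#' @param mock_counts Mock allelic count tibble (from [build_mock_f1()]).
#' @param threshold Minimum allelic reads (inclusion + exclusion) required
#'   in every mock record of the event. Default 20.
#' @return Character vector of dropped `event_id`s.
#' @export
mock_coverage_filter <- function(mock_counts, threshold = 20) {
  mock_counts |>
    group_by(.data$event_id) |>
    summarise(min_total = min(.data$n_inclusion + .data$n_exclusion)) |>
    filter(.data$min_total < threshold) |>
    pull("event_id")
}

#' Coverage-dependent local standard deviation of PSI deltas
#'
#' Estimates, as a function of read coverage, the pure-sampling spread of a
#' PSI difference. Records are sorted by coverage; each record's raw sigma
#' is the sample SD of the deltas inside a centered window holding
#' `window_frac` of all records (at least `min_window`, truncated at the
#' ends); the raw values are then smoothed against coverage rank by loess
#' and floored at `floor`.
#'
#' @param deltas Data frame with columns `delta` (PSI difference) and
#'   `coverage` (reads supporting the estimate); typically the
#'   full-vs-downsampled parental contrast, which isolates sampling noise.
#' @param window_frac Window size as a fraction of records. Default 0.01.
#' @param min_window Minimum window size in records. Default 20.
#' @param span,degree Loess smoothing parameters. Defaults 0.75, 2.
#' @param floor Lower bound for the smoothed sigma. Default 1e-4.
#' @return Input tibble, sorted by coverage, with `sigma_raw` and
#'   `sigma_local` appended.
#' @export
local_sd <- function(deltas, window_frac = 0.01, min_window = 20,
                     span = 0.75, degree = 2, floor = 1e-4) {
  d <- as_tibble(deltas)
  if (nrow(d) < 2) abort("need at least two records to estimate a local SD")
  d <- arrange(d, .data$coverage)
  n <- nrow(d)
  if (n < min_window) {
    warn("fewer records than the minimum window; using a single global SD")
    d$sigma_raw <- sd(d$delta)
    d$sigma_local <- pmax(d$sigma_raw, floor)
    return(d)
  }
  w <- max(min_window, ceiling(window_frac * n))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(lo + w - 1, n)
  lo <- pmax(hi - w + 1, 1)
  cs <- cumsum(c(0, d$delta))
  cs2 <- cumsum(c(0, d$delta^2))
  m <- hi - lo + 1
  s1 <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  v <- pmax((s2 - s1^2 / m) / (m - 1), 0)
  d$sigma_raw <- sqrt(v)
  fit <- stats::loess(sigma_raw ~ rank, data = tibble(sigma_raw = d$sigma_raw,
                                                      rank = seq_len(n)),
                      span = span, degree = degree)
  d$sigma_local <- pmax(stats::predict(fit), floor)
  d
}

# Interpolate the smoothed sigma(coverage) curve at new coverages.
sigma_lookup <- function(sigma_table, coverage) {
  stats::approx(sigma_table$coverage, sigma_table$sigma_local, xout = coverage,
                rule = 2, ties = mean)$y
}

#' Z filter for parental-vs-mock PSI inconsistency
#'
#' Standardises each parental-vs-mock PSI difference by the local standard
#' deviation at its coverage, converts to a two-sided normal p-value,
#' adjusts across all (event, allele) records by Benjamini-Hochberg, and
#' drops events significant on either allele: their allelic quantification
#' is biased by non-random read assignability.
#'
#' @param deltas Data frame with columns `event_id`, `allele`, `delta`
#'   (parental minus mock PSI) and `coverage`.
#' @param sigma_table Output of [local_sd()] on the downsampling contrast.
#' @param fdr Benjamini-Hochberg FDR for the drop decision. Default 0.05.
#' @return Tibble with `sigma_local`, `z_value`, `p_value`, `p_adjusted`
#'   and per-event `verdict` (`keep` / `drop_inconsistent`) appended.
#' @export
mock_z_filter <- function(deltas, sigma_table, fdr = 0.05) {
  d <- as_tibble(deltas)
  d$sigma_local <- sigma_lookup(sigma_table, d$coverage)
  d$z_value <- d$delta / d$sigma_local
  d$p_value <- 2 * pnorm(-abs(d$z_value))
  d$p_adjusted <- p.adjust(d$p_value, method = "BH")
  bad <- unique(d$event_id[d$p_adjusted < fdr])
  d$verdict <- if_else(d$event_id %in% bad, "drop_inconsistent", "keep")
  d
}

#' Run the full mock-hybrid filter
#'
#' Combines the coverage filter and the local-SD Z filter. Pooled (across
#' replicates) posterior PSI means are compared: each parent against the
#' matching mock allele. The local SD is calibrated on the full-vs-
#' downsampled parental contrast, which contains only sampling noise, and
#' applied at each event's mock coverage. The filter is a pure function of
#' the mock and downsampling datasets; real-hybrid data never enter it.
#'
#' @param parental_counts,mock_counts,downsampled_counts Count tibbles:
#'   parental records, mock allelic records from [build_mock_f1()], and
#'   downsampled parental records from [downsample_parental()].
#' @param coverage_threshold Minimum mock allelic reads. Default 20.
#' @param fdr BH FDR for the inconsistency drop. Default 0.05.
#' @param window_frac,span Local-SD window fraction and loess span.
#' @return List: `result` (per event-allele tibble with z, p, adjusted p),
#'   `verdicts` (per event: `keep`, `drop_low_coverage` or
#'   `drop_inconsistent`), `sigma_table`, and `kept` (event ids).
#' @export
run_mock_filter <- function(parental_counts, mock_counts, downsampled_counts,
                            coverage_threshold = 20, fdr = 0.05,
                            window_frac = 0.01, span = 0.75) {
  pooled_psi <- function(counts) {
    counts |>
      group_by(.data$event_id, .data$sample, .data$allele) |>
      summarise(n_inclusion = sum(.data$n_inclusion),
                n_exclusion = sum(.data$n_exclusion), .groups = "drop") |>
      psi_posterior()
  }
  low_cov <- mock_coverage_filter(mock_counts, coverage_threshold)

  par_psi <- pooled_psi(parental_counts) |>
    mutate(allele = if_else(.data$sample == "parent_B", "B", "S"))
  ds_psi <- pooled_psi(downsampled_counts) |>
    mutate(allele = if_else(.data$sample == "parent_B", "B", "S"))
  ds_contrast <- inner_join(
    par_psi |> select("event_id", "allele", psi_full = "psi_mean"),
    ds_psi |> select("event_id", "allele", psi_down = "psi_mean",
                     coverage = "n_total"),
    by = c("event_id", "allele")
  ) |>
    mutate(delta = .data$psi_full - .data$psi_down)
  sigma_table <- local_sd(ds_contrast, window_frac = window_frac, span = span)

  mock_psi <- pooled_psi(mock_counts)
  contrast <- inner_join(
    par_psi |> select("event_id", "allele", psi_parental = "psi_mean"),
    mock_psi |> select("event_id", "allele", psi_mock = "psi_mean",
                       coverage = "n_total"),
    by = c("event_id", "allele")
  ) |>
    filter(!.data$event_id %in% low_cov) |>
    mutate(delta = .data$psi_parental - .data$psi_mock)
  result <- mock_z_filter(contrast, sigma_table, fdr = fdr)

  verdicts <- bind_rows(
    tibble(event_id = low_cov, verdict = "drop_low_coverage"),
    result |> distinct(.data$event_id, .data$verdict)
  ) |>
    distinct(.data$event_id, .keep_all = TRUE)
  list(
    result = result,
    verdicts = verdicts,
    sigma_table = sigma_table,
    kept = verdicts$event_id[verdicts$verdict == "keep"]
  )
}
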