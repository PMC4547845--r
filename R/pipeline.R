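#' Simulate a complete synthetic dataset
#'
#' Runs the generator chain — catalog, ground-truth architectures, count
#' tables, variants, optionally haplotypes and reads — under a single seed.
#'
#' @param config A [sim_config()].
#' @param reads Also emit haplotype sequences and reads. Default `FALSE`
#'   (the count-level pipeline does not need sequence data).
#' @return List of class `sim_dataset`: `config`, `catalog`, `truth`,
#'   `counts`, `variants`, and (optionally) `sequences`.
#' @export
simulate_dataset <- function(config, reads = FALSE) {
  catalog <- generate_catalog(config)
  truth <- generate_truth(catalog, config)
  counts <- sample_counts(truth, config, catalog)
  variants <- generate_variants(catalog, truth, config)
  out <- list(config = config, catalog = catalog, truth = truth,
              counts = counts, variants = variants)
  if (reads) out$sequences <- emit_reads(catalog, truth, variants, config)
  structure(out, class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>", nrow(x$catalog), "events,",
      nrow(x$counts), "count records,", nrow(x$variants), "variants\n")
  invisible(x)
}

#' Run the cis/trans dissection pipeline
#'
#' Executes the full analysis on a dataset: mock-hybrid construction,
#' coverage filtering, mock-bias filtering, replicate-wise divergence
#' calling for the parental and allelic comparisons, permutation-FDR
#' estimation, the parental-vs-allelic ratio interaction test with Storey
#' q-values, and the final per-event category. Ground truth, when present
#' in the dataset, is carried through for evaluation but never read by any
#' inference stage.
#'
#' @param dataset A `sim_dataset`, or a list with elements `catalog`,
#'   `counts` (and optionally `truth`, `variants`).
#' @param coverage_threshold Minimum reads per record. Default 20.
#' @param bf_min,delta_min Divergence thresholds. Defaults 5, 0.1.
#' @param mock_fdr BH FDR of the mock Z filter. Default 0.05.
#' @param n_permutations Label permutations per cutoff. Default 100.
#' @param trans_cutoff `"matched"` (default) sets the trans q-value cutoff
#'   to the permutation-estimated FDR of the divergence threshold on this
#'   dataset; `"absolute"` uses `trans_q`.
#' @param trans_q Absolute q cutoff (also the fallback when the matched
#'   estimate is unavailable). Default 0.05.
#' @param assignability Mock thinning probability; defaults to the
#'   simulation config's value when available.
#' @param verbose Log stage progress to standard error. Default `FALSE`.
#' @return Object of class `cistrans_result`; see [tidy.cistrans_result()]
#'   and [glance.cistrans_result()].
#' @export
run_pipeline <- function(dataset,
                         coverage_threshold = 20,
                         bf_min = 5,
                         delta_min = 0.1,
                         mock_fdr = 0.05,
                         n_permutations = 100,
                         trans_cutoff = c("matched", "absolute"),
                         trans_q = 0.05,
                         assignability = NULL,
                         verbose = FALSE) {
  trans_cutoff <- match.arg(trans_cutoff)
  say <- function(...) if (verbose) message(sprintf(...))
  counts <- dataset$counts
  catalog <- dataset$catalog
  seed <- dataset$config$seed %||% 1L
  assignability <- assignability %||% dataset$config$assignability %||% 0.6

  parental <- counts |> filter(.data$sample %in% c("parent_B", "parent_S"))
  hybrid <- counts |> filter(.data$sample == "hybrid")
  if (nrow(parental) == 0) abort("stage counts: no parental records")

  expressed <- coverage_filter(parental, coverage_threshold)
  say("coverage filter: %d of %d events expressed", length(expressed),
      dplyr::n_distinct(parental$event_id))

  mock <- build_mock_f1(parental, assignability = assignability, seed = seed)
  mock_totals <- mock |>
    mutate(sample = if_else(.data$allele == "B", "parent_B", "parent_S"),
           target = .data$n_inclusion + .data$n_exclusion) |>
    select("event_id", "sample", "replicate", "target")
  downsampled <- downsample_parental(parental, mock_totals, seed = seed)
  mf <- run_mock_filter(
    parental |> filter(.data$event_id %in% expressed),
    mock |> filter(.data$event_id %in% expressed),
    downsampled |> filter(.data$event_id %in% expressed),
    coverage_threshold = coverage_threshold, fdr = mock_fdr
  )
  say("mock filter: %d kept, %d dropped", length(mf$kept),
      length(expressed) - length(mf$kept))

  hybrid_ok <- coverage_filter(hybrid, coverage_threshold)
  retained <- intersect(intersect(expressed, mf$kept), hybrid_ok)
  say("retained for allelic analysis: %d events", length(retained))
  if (length(retained) == 0) abort("stage mock_filter: no events retained")

  par_kept <- parental |> filter(.data$event_id %in% retained)
  hyb_kept <- hybrid |> filter(.data$event_id %in% retained)

  dp <- divergence_calls(par_kept, "parent_B", "parent_S", by = "sample",
                         events = catalog, bf_min = bf_min,
                         delta_min = delta_min)
  da <- divergence_calls(hyb_kept, "B", "S", by = "allele",
                         events = catalog, bf_min = bf_min,
                         delta_min = delta_min)
  say("divergent: %d parental, %d allelic", sum(dp$calls$divergent),
      sum(da$calls$divergent))

  fdr_grid <- permutation_fdr(dp$replicates, bf_min = bf_min,
                              n_permutations = n_permutations, seed = seed)
  q_cut <- if (trans_cutoff == "matched") {
    est <- fdr_grid$fdr_mean[which.min(abs(fdr_grid$cutoff - delta_min))]
    if (is.na(est)) trans_q else est
  } else {
    trans_q
  }

  rp <- ratio_and_se(par_kept, "parent_B", "parent_S", by = "sample",
                     events = catalog)
  ra <- ratio_and_se(hyb_kept, "B", "S", by = "allele", events = catalog)
  tz <- trans_z_test(rp, ra)
  classification <- classify_cis_trans(dp$calls, da$calls, tz,
                                       trans_fdr_cutoff = q_cut)
  classification <- classification |>
    left_join(catalog |> select("event_id", "as_type"), by = "event_id")

  res <- structure(list(
    config = dataset$config,
    catalog = catalog,
    truth = dataset$truth,
    expressed = expressed,
    mock_filter = mf,
    retained = retained,
    calls_parental = dp,
    calls_allelic = da,
    fdr_grid = fdr_grid,
    trans_q_cutoff = q_cut,
    trans_test = tz,
    classification = classification,
    thresholds = list(coverage = coverage_threshold, bf_min = bf_min,
                      delta_min = delta_min, mock_fdr = mock_fdr)
  ), class = "cistrans_result")
  res
}

#' @export
print.cistrans_result <- function(x, ...) {
  g <- glance(x)
  cat("<cistrans_result>\n")
  cat(sprintf("  expressed events: %d; retained after filters: %d\n",
              g$n_expressed, g$n_retained))
  cat(sprintf("  parental divergent: %d (%.1f%%); allelic divergent: %d\n",
              g$n_parental_divergent, g$pct_parental_divergent,
              g$n_allelic_divergent))
  cat(sprintf("  cis_only %d | cis_and_trans %d | trans_only %d | unexplained %d\n",
              g$n_cis_only, g$n_cis_and_trans, g$n_trans_only, g$n_unexplained))
  invisible(x)
}

#' Tidy the per-event classification
#'
#' @param x A `cistrans_result`.
#' @param ... Unused.
#' @return Per-event tibble with flags, trans-test statistics and category.
#' @export
tidy.cistrans_result <- function(x, ...) {
  x$classification
}

#' One-row pipeline summary
#'
#' @param x A `cistrans_result`.
#' @param ... Unused.
#' @return One-row tibble of headline counts and percentages.
#' @export
glance.cistrans_result <- function(x, ...) {
  cl <- x$classification
  n_div <- sum(cl$parental_divergent)
  tibble(
    n_expressed = length(x$expressed),
    n_retained = length(x$retained),
    n_parental_divergent = n_div,
    pct_parental_divergent = round(100 * n_div / length(x$expressed), 1),
    n_allelic_divergent = sum(cl$allelic_divergent),
    n_cis_only = sum(cl$category == "cis_only"),
    n_cis_and_trans = sum(cl$category == "cis_and_trans"),
    n_trans_only = sum(cl$category == "trans_only"),
    n_unexplained = sum(cl$category == "unexplained"),
    trans_q_cutoff = x$trans_q_cutoff
  )
}

#' Human-readable summary report
#'
#' Emits the per-type divergence breakdown (counts and one-decimal
#' percentages of expressed events), the effect-class enrichment among
#' divergent events, and the cis/trans category percentages per AS type.
#'
#' @param result A `cistrans_result`.
#' @return List of tibbles: `overall`, `by_type`, `by_effect`,
#'   `cis_trans_by_type`, printed nicely via `print()`.
#' @export
report_summary <- function(result) {
  cl <- result$classification
  cat_types <- result$catalog |>
    filter(.data$event_id %in% result$expressed) |>
    select("event_id", "as_type")
  div_ids <- cl$event_id[cl$parental_divergent]

  overall <- tibble(
    n_expressed = length(result$expressed),
    n_divergent = length(div_ids),
    pct_divergent = round(100 * length(div_ids) / length(result$expressed), 1)
  )
  by_type <- cat_types |>
    group_by(.data$as_type) |>
    summarise(n_expressed = n(),
              n_divergent = sum(.data$event_id %in% div_ids)) |>
    mutate(pct_divergent = round(100 * .data$n_divergent / .data$n_expressed, 1))

  eff <- classify_event_effect(result$catalog |>
                                 filter(.data$event_id %in% result$expressed))
  eff$divergent <- eff$event_id %in% div_ids
  region <- eff |>
    group_by(class = .data$region_class) |>
    summarise(n_expressed = n(), n_divergent = sum(.data$divergent)) |>
    mutate(pct_divergent = round(100 * .data$n_divergent / .data$n_expressed, 1))
  frame <- eff |>
    filter(.data$frame_class != "not-applicable") |>
    group_by(class = .data$frame_class) |>
    summarise(n_expressed = n(), n_divergent = sum(.data$divergent)) |>
    mutate(pct_divergent = round(100 * .data$n_divergent / .data$n_expressed, 1))
  by_effect <- bind_rows(region, frame)

  cis_trans_by_type <- cl |>
    filter(.data$parental_divergent) |>
    group_by(.data$as_type) |>
    summarise(
      n_divergent = n(),
      n_cis = sum(.data$category %in% c("cis_only", "cis_and_trans")),
      n_trans = sum(.data$category %in% c("trans_only", "cis_and_trans"))
    ) |>
    mutate(pct_cis = round(100 * .data$n_cis / .data$n_divergent, 1),
           pct_trans = round(100 * .data$n_trans / .data$n_divergent, 1))

  structure(list(overall = overall, by_type = by_type, by_effect = by_effect,
                 cis_trans_by_type = cis_trans_by_type),
            class = "cistrans_report")
}

#' @export
print.cistrans_report <- function(x, ...) {
  cat("== Splicing divergence summary ==\n")
  print(as.data.frame(x$overall), row.names = FALSE)
  cat("\n-- by AS type --\n")
  print(as.data.frame(x$by_type), row.names = FALSE)
  cat("\n-- by event effect --\n")
  print(as.data.frame(x$by_effect), row.names = FALSE)
  cat("\n-- cis/trans among divergent --\n")
  print(as.data.frame(x$cis_trans_by_type), row.names = FALSE)
  invisible(x)
}

#' Write pipeline outputs as TSV files
#'
#' One file per stage: classification, parental and allelic calls, FDR
#' grid, trans test, mock-filter result.
#'
#' @param result A `cistrans_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_pipeline_tsvs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(result$classification, file.path(dir, "classification.tsv"))
  readr::write_tsv(result$calls_parental$calls, file.path(dir, "calls_parental.tsv"))
  readr::write_tsv(result$calls_allelic$calls, file.path(dir, "calls_allelic.tsv"))
  readr::write_tsv(result$fdr_grid, file.path(dir, "fdr_grid.tsv"))
  readr::write_tsv(result$trans_test, file.path(dir, "trans_test.tsv"))
  readr::write_tsv(result$mock_filter$result, file.path(dir, "mock_filter.tsv"))
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may contain a `simulation:` block (fields of [sim_config()])
#' and a `thresholds:` block (arguments of [run_pipeline()]).
#'
#' @param path YAML file.
#' @return List with `sim` (a `sim_config`) and `thresholds`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  if (!is.null(sim_args$type_mix)) sim_args$type_mix <- unlist(sim_args$type_mix)
  list(
    sim = do.call(sim_config, sim_args),
    thresholds = y$thresholds %||% list()
  )
}
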