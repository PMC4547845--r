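#' Assign ground-truth cis/trans architectures and PSI values
#'
#' Gives each catalog event an architecture (conserved, cis, trans, or
#' cis+trans) with the configured proportions, then constructs true PSI
#' values for the four quantification contexts. Effects are additive on the
#' PSI scale and split symmetrically around the event's base PSI: the cis
#' effect separates the two alleles inside the F1 hybrid (shared trans
#' environment), while the parental contrast carries cis and trans effects
#' jointly:
#' \deqn{\psi_{alleleB} - \psi_{alleleS} = \delta_{cis}, \qquad
#'       \psi_{parentB} - \psi_{parentS} = \delta_{cis} + \delta_{trans}}
#' (both pre-clipping). All PSI values are clipped to `[0.01, 0.99]` to keep
#' events informative.
#'
#' @param catalog Event catalog from [generate_catalog()].
#' @param config A [sim_config()].
#' @return Tibble: `event_id`, `architecture`, `psi_base`, `delta_cis`,
#'   `delta_trans`, and true PSI columns `psi_parent_B`, `psi_parent_S`,
#'   `psi_allele_B`, `psi_allele_S`.
#' @export
generate_truth <- function(catalog, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(catalog) == 0) abort("catalog is empty")
  with_seed(derive_seed(config$seed, "truth"), {
    n <- nrow(catalog)
    arch <- sample(
      c("cis", "trans", "cis+trans", "conserved"), n, replace = TRUE,
      prob = c(config$frac_cis, config$frac_trans, config$frac_both,
               1 - config$frac_cis - config$frac_trans - config$frac_both)
    )
    psi_base <- runif(n, 0.05, 0.95)
    r <- config$effect_size_range
    mag <- function(m) runif(m, r[1], r[2]) * sample(c(-1, 1), m, replace = TRUE)
    delta_cis <- ifelse(arch %in% c("cis", "cis+trans"), mag(n), 0)
    delta_trans <- ifelse(arch %in% c("trans", "cis+trans"), mag(n), 0)
    clip <- function(x) pmin(pmax(x, 0.01), 0.99)
    tibble(
      event_id = catalog$event_id,
      architecture = arch,
      psi_base = psi_base,
      delta_cis = delta_cis,
      delta_trans = delta_trans,
      psi_parent_B = clip(psi_base + (delta_cis + delta_trans) / 2),
      psi_parent_S = clip(psi_base - (delta_cis + delta_trans) / 2),
      psi_allele_B = clip(psi_base + delta_cis / 2),
      psi_allele_S = clip(psi_base - delta_cis / 2)
    )
  })
}

#' Sample allele-specific read counts from a ground truth
#'
#' Draws, per event and replicate, a negative-binomial total read depth and
#' binomial inclusion counts at the informativeness-corrected inclusion
#' probability of the context's true PSI. Parental samples yield unsplit
#' records (`allele = "pooled"`); the hybrid sample's depth is first thinned
#' by the allele-assignability probability, the surviving reads split
#' equally between the two alleles, giving one record per allele.
#'
#' @param truth Tibble from [generate_truth()].
#' @param config A [sim_config()].
#' @param catalog Optional catalog carrying per-event informativeness
#'   constants; default `NULL` uses constants of 1.
#' @return Tibble of count records: `event_id`, `sample` (`parent_B`,
#'   `parent_S`, `hybrid`), `replicate`, `allele` (`pooled`, `B`, `S`),
#'   `n_inclusion`, `n_exclusion`.
#' @export
sample_counts <- function(truth, config, catalog = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth_mean <= 0) abort("depth_mean must be positive")
  if (!is.null(catalog)) {
    idx <- match(truth$event_id, catalog$event_id)
    c_inc <- catalog$c_inclusion[idx]
    c_exc <- catalog$c_exclusion[idx]
  } else {
    c_inc <- rep(1, nrow(truth))
    c_exc <- rep(1, nrow(truth))
  }
  with_seed(derive_seed(config$seed, "counts"), {
    n <- nrow(truth)
    reps <- config$n_replicates
    draw_parent <- function(sample_name, psi) {
      q <- inclusion_probability(psi, c_inc, c_exc)
      purrr::map_dfr(seq_len(reps), function(r) {
        tot <- rnbinom(n, mu = config$depth_mean, size = config$depth_dispersion)
        k <- rbinom(n, tot, q)
        tibble(event_id = truth$event_id, sample = sample_name,
               replicate = r, allele = "pooled",
               n_inclusion = k, n_exclusion = tot - k)
      })
    }
    draw_hybrid <- function() {
      qB <- inclusion_probability(truth$psi_allele_B, c_inc, c_exc)
      qS <- inclusion_probability(truth$psi_allele_S, c_inc, c_exc)
      purrr::map_dfr(seq_len(reps), function(r) {
        tot <- rnbinom(n, mu = config$depth_mean, size = config$depth_dispersion)
        assignable <- rbinom(n, tot, config$assignability)
        totB <- rbinom(n, assignable, 0.5)
        totS <- assignable - totB
        kB <- rbinom(n, totB, qB)
        kS <- rbinom(n, totS, qS)
        bind_rows(
          tibble(event_id = truth$event_id, sample = "hybrid", replicate = r,
                 allele = "B", n_inclusion = kB, n_exclusion = totB - kB),
          tibble(event_id = truth$event_id, sample = "hybrid", replicate = r,
                 allele = "S", n_inclusion = kS, n_exclusion = totS - kS)
        )
      })
    }
    bind_rows(
      draw_parent("parent_B", truth$psi_parent_B),
      draw_parent("parent_S", truth$psi_parent_S),
      draw_hybrid()
    ) |>
      arrange(.data$event_id, .data$sample, .data$replicate, .data$allele)
  })
}
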