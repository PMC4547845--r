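#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults describe
#' a realistic bulk RNA-seq contrast between two diverged inbred strains and
#' their F1 hybrid: the alternative-splicing type mix follows the observed
#' proportions among expressed events in such data (roughly 48% SE, 15% RI,
#' 6% MXE, 19% A3SS, 13% A5SS), read depth per event is negative-binomial
#' overdispersed around 200, and 60% of hybrid reads are allele-assignable
#' (a highly diverged strain pair; use `assignability = 0.3` for a closer
#' pair with shorter reads).
#'
#' @param n_events Total number of events to simulate.
#' @param type_mix Named proportions over `c("SE","RI","MXE","A3SS","A5SS")`;
#'   must sum to 1 (tolerance 1e-9).
#' @param depth_mean,depth_dispersion Mean and size (shape) parameter of the
#'   negative-binomial per-event, per-replicate total read depth.
#' @param n_replicates Replicates per sample. Default 3.
#' @param frac_cis,frac_trans,frac_both Proportions of events with a pure
#'   cis, pure trans, or joint cis+trans architecture; the remainder is
#'   conserved. Must sum to at most 1.
#' @param effect_size_range Range (min, max) of the uniform distribution of
#'   effect magnitudes `|delta_cis|`, `|delta_trans|` in PSI units.
#' @param variant_rate_background,variant_rate_cis_flank Variants per nt
#'   genome-wide and within the flanking regions of cis-architecture events
#'   (the latter must be >= the background).
#' @param splice_site_variant_frac Fraction of cis-architecture events that
#'   receive one variant inside a splice-site window.
#' @param assignability Probability that a hybrid read can be assigned to an
#'   allele, in (0, 1].
#' @param read_length Read length in nt for read-level simulation.
#' @param error_rate Per-base uniform substitution rate for simulated reads.
#'   Default 0: the assignment rule, not sequencing error, is under study.
#' @param exon_length_range,intron_length_range,alt_shift_range Segment
#'   length ranges (nt) for exons, introns, and alternative-splice-site
#'   shifts.
#' @param coding_frac Fraction of events placed in annotated coding sequence.
#' @param seed Integer seed; every generator output is deterministic in it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_events = 1000,
                       type_mix = c(SE = 0.475, RI = 0.150, MXE = 0.059,
                                    A3SS = 0.189, A5SS = 0.127),
                       depth_mean = 200,
                       depth_dispersion = 5,
                       n_replicates = 3,
                       frac_cis = 0.15,
                       frac_trans = 0.05,
                       frac_both = 0.02,
                       effect_size_range = c(0.1, 0.6),
                       variant_rate_background = 0.01,
                       variant_rate_cis_flank = 0.03,
                       splice_site_variant_frac = 0.3,
                       assignability = 0.6,
                       read_length = 50,
                       error_rate = 0,
                       exon_length_range = c(60, 250),
                       intron_length_range = c(150, 1500),
                       alt_shift_range = c(9, 120),
                       coding_frac = 0.71,
                       seed = 1L) {
  cfg <- list(
    n_events = n_events, type_mix = type_mix,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    n_replicates = n_replicates,
    frac_cis = frac_cis, frac_trans = frac_trans, frac_both = frac_both,
    effect_size_range = effect_size_range,
    variant_rate_background = variant_rate_background,
    variant_rate_cis_flank = variant_rate_cis_flank,
    splice_site_variant_frac = splice_site_variant_frac,
    assignability = assignability,
    read_length = read_length, error_rate = error_rate,
    exon_length_range = exon_length_range,
    intron_length_range = intron_length_range,
    alt_shift_range = alt_shift_range,
    coding_frac = coding_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  as_types <- c("SE", "RI", "MXE", "A3SS", "A5SS")
  if (!setequal(names(cfg$type_mix), as_types)) {
    abort("type_mix must be named over SE, RI, MXE, A3SS, A5SS")
  }
  cfg$type_mix <- cfg$type_mix[as_types]
  if (abs(sum(cfg$type_mix) - 1) > 1e-9) abort("type_mix must sum to 1")
  if (any(cfg$type_mix < 0)) abort("type_mix proportions must be >= 0")
  fr <- cfg$frac_cis + cfg$frac_trans + cfg$frac_both
  if (cfg$frac_cis < 0 || cfg$frac_trans < 0 || cfg$frac_both < 0 || fr > 1 + 1e-9) {
    abort("architecture fractions must be >= 0 and sum to at most 1")
  }
  if (cfg$depth_mean <= 0) abort("depth_mean must be positive")
  if (cfg$depth_dispersion <= 0) abort("depth_dispersion must be positive")
  if (cfg$variant_rate_background < 0 || cfg$variant_rate_cis_flank < 0) {
    abort("variant rates must be >= 0")
  }
  if (cfg$variant_rate_background >= 1 || cfg$variant_rate_cis_flank >= 1) {
    abort("variant rates must stay below 1 per nt")
  }
  if (cfg$variant_rate_cis_flank < cfg$variant_rate_background) {
    abort("variant_rate_cis_flank must be >= variant_rate_background")
  }
  if (cfg$assignability <= 0 || cfg$assignability > 1) {
    abort("assignability must lie in (0, 1]")
  }
  if (cfg$error_rate < 0 || cfg$error_rate > 1) abort("error_rate must be in [0, 1]")
  if (cfg$n_replicates < 1) abort("need at least one replicate")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  events:", x$n_events, " replicates:", x$n_replicates, "\n")
  cat("  type mix:", paste(sprintf("%s=%.3f", names(x$type_mix), x$type_mix),
                           collapse = " "), "\n")
  cat(sprintf("  depth NB(mean=%g, size=%g); assignability %.2f\n",
              x$depth_mean, x$depth_dispersion, x$assignability))
  cat(sprintf("  architectures: cis %.2f, trans %.2f, both %.2f; |delta| ~ U(%.2f, %.2f)\n",
              x$frac_cis, x$frac_trans, x$frac_both,
              x$effect_size_range[1], x$effect_size_range[2]))
  cat(sprintf("  variants/nt: background %g, cis flank %g; seed %d\n",
              x$variant_rate_background, x$variant_rate_cis_flank, x$seed))
  invisible(x)
}
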