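#' Generate a synthetic alternative-splicing event catalog
#'
#' Lays out non-overlapping two-isoform events of the five major types
#' (SE, RI, MXE, A3SS, A5SS) on a set of toy chromosomes. Coordinates are
#' 0-based half-open internally; [write_catalog_gff3()] converts to 1-based
#' closed on output. Each event records its constitutive (upstream /
#' downstream) segments, its alternative segment(s), informativeness
#' constants, and a CDS interval for events placed in coding sequence.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per event: `event_id`, `as_type`, `chrom`,
#'   `strand`, segment coordinates (`up_*`, `alt_*`, `alt2_*` for MXE,
#'   `down_*`), `c_inclusion`, `c_exclusion`, `cds_start`, `cds_end`.
#'   Chromosome sizes are attached as attribute `chrom_sizes`.
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_events == 0) {
    warn("zero events requested; returning empty catalog")
    out <- tibble(
      event_id = character(), as_type = character(), chrom = character(),
      strand = character(), up_start = integer(), up_end = integer(),
      alt_start = integer(), alt_end = integer(), alt2_start = integer(),
      alt2_end = integer(), down_start = integer(), down_end = integer(),
      c_inclusion = double(), c_exclusion = double(),
      cds_start = integer(), cds_end = integer()
    )
    attr(out, "chrom_sizes") <- integer()
    return(out)
  }
  with_seed(derive_seed(config$seed, "catalog"), {
    n <- config$n_events
    as_type <- sample(names(config$type_mix), n, replace = TRUE,
                      prob = config$type_mix)
    rexon <- function(m) sample(config$exon_length_range[1]:config$exon_length_range[2],
                                m, replace = TRUE)
    rintr <- function(m) sample(config$intron_length_range[1]:config$intron_length_range[2],
                                m, replace = TRUE)
    rshift <- function(m) sample(config$alt_shift_range[1]:config$alt_shift_range[2],
                                 m, replace = TRUE)
    gap <- 500L

    # per-event segment lengths; columns: up, i1, alt, i2, alt2, i3, down
    len <- matrix(0L, n, 7)
    se <- as_type == "SE"
    len[se, ] <- cbind(rexon(sum(se)), rintr(sum(se)), rexon(sum(se)),
                       rintr(sum(se)), 0L, 0L, rexon(sum(se)))
    ri <- as_type == "RI"
    len[ri, ] <- cbind(rexon(sum(ri)), 0L, rintr(sum(ri)), 0L, 0L, 0L, rexon(sum(ri)))
    mx <- as_type == "MXE"
    len[mx, ] <- cbind(rexon(sum(mx)), rintr(sum(mx)), rexon(sum(mx)),
                       rintr(sum(mx)), rexon(sum(mx)), rintr(sum(mx)), rexon(sum(mx)))
    a3 <- as_type == "A3SS"
    len[a3, ] <- cbind(rexon(sum(a3)), rintr(sum(a3)), rshift(sum(a3)),
                       0L, 0L, 0L, rexon(sum(a3)))
    a5 <- as_type == "A5SS"
    len[a5, ] <- cbind(rexon(sum(a5)), 0L, rshift(sum(a5)),
                       rintr(sum(a5)), 0L, 0L, rexon(sum(a5)))

    span <- rowSums(len) + gap
    per_chrom <- 500L
    chrom_idx <- (seq_len(n) - 1L) %/% per_chrom + 1L
    chrom <- sprintf("chrT%d", chrom_idx)
    offset <- unlist(lapply(split(span, chrom_idx), function(s) {
      cumsum(c(gap, utils::head(s, -1)))
    }), use.names = FALSE)

    s0 <- offset
    up_start <- s0
    up_end <- s0 + len[, 1]
    alt_start <- up_end + len[, 2]
    alt_end <- alt_start + len[, 3]
    alt2_start <- ifelse(mx, alt_end + len[, 4], NA_integer_)
    alt2_end <- ifelse(mx, alt2_start + len[, 5], NA_integer_)
    down_start <- ifelse(mx, alt2_end + len[, 6], alt_end + len[, 4])
    # A3SS: alternative region abuts the downstream core exon; A5SS: it
    # abuts the upstream core, with the intron between alt end and down.
    down_start[a3] <- alt_end[a3]
    down_end <- down_start + len[, 7]

    coding <- runif(n) < config$coding_frac
    cds_start <- ifelse(coding, up_start, NA_integer_)
    cds_end <- ifelse(coding, down_end, NA_integer_)

    out <- tibble(
      event_id = sprintf("ev%05d", seq_len(n)),
      as_type = as_type,
      chrom = chrom,
      strand = sample(c("+", "-"), n, replace = TRUE),
      up_start = as.integer(up_start), up_end = as.integer(up_end),
      alt_start = as.integer(alt_start), alt_end = as.integer(alt_end),
      alt2_start = as.integer(alt2_start), alt2_end = as.integer(alt2_end),
      down_start = as.integer(down_start), down_end = as.integer(down_end),
      c_inclusion = 1, c_exclusion = 1,
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)
    )
    sizes <- vapply(split(out$down_end, out$chrom), function(e) max(e) + gap,
                    numeric(1))
    attr(out, "chrom_sizes") <- sizes[unique(out$chrom)]
    out
  })
}

# Length of the alternative region(s) of each event, nt. For MXE this is
# the pair (len A, len B) reduced by `reduce`.
alt_region_length <- function(events, reduce = `+`) {
  la <- events$alt_end - events$alt_start
  lb <- ifelse(is.na(events$alt2_start), 0L, events$alt2_end - events$alt2_start)
  ifelse(events$as_type == "MXE", reduce(la, lb), la)
}
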