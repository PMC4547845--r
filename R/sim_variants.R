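#' Generate haplotype sequence variants
#'
#' Places SNVs and short indels between the two haplotypes: uniformly at the
#' background rate genome-wide, at the (higher) cis-flank rate within the
#' flanking regions of cis-architecture events, and — for a configurable
#' fraction of cis events — one SNV inside a splice-site window of the
#' alternative segment, emulating site-disrupting regulatory variants.
#' Variants are thinned to a minimum spacing of 4 nt so that indels never
#' overlap a neighbouring variant.
#'
#' @param catalog Event catalog from [generate_catalog()].
#' @param truth Ground truth from [generate_truth()].
#' @param config A [sim_config()].
#' @param flank Flank width (nt) used for the elevated-rate regions.
#' @return Tibble: `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `class` (`SNV`/`insertion`/`deletion`), `event_id` (flank owner or
#'   `NA`), `splice_site` flag. Writable with [write_variants_vcf()].
#' @export
generate_variants <- function(catalog, truth, config, flank = 100) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- attr(catalog, "chrom_sizes")
  if (is.null(sizes)) abort("catalog lacks chrom_sizes attribute")
  with_seed(derive_seed(config$seed, "variants"), {
    bases <- c("A", "C", "G", "T")
    rate_bg <- config$variant_rate_background
    rate_cis <- config$variant_rate_cis_flank

    bg <- purrr::imap_dfr(as.list(sizes), function(L, chr) {
      m <- rbinom(1, L, rate_bg)
      if (m == 0) return(tibble(chrom = character(), pos = integer()))
      tibble(chrom = chr, pos = sort(sample.int(L, m) - 1L))
    })
    bg$event_id <- NA_character_

    cis_ids <- truth$event_id[truth$architecture %in% c("cis", "cis+trans")]
    extra <- tibble(chrom = character(), pos = integer(), event_id = character())
    if (length(cis_ids) > 0 && rate_cis > rate_bg) {
      regions <- flanking_regions(catalog[catalog$event_id %in% cis_ids, , drop = FALSE],
                                  flank = flank)
      m <- rbinom(nrow(regions), regions$end - regions$start, rate_cis - rate_bg)
      extra <- regions[rep(seq_len(nrow(regions)), m), c("chrom", "start", "end", "event_id")]
      if (nrow(extra) > 0) {
        extra$pos <- as.integer(extra$start +
          floor(runif(nrow(extra)) * (extra$end - extra$start)))
      } else {
        extra$pos <- integer()
      }
      extra <- extra[, c("chrom", "pos", "event_id")]
    }

    ss <- tibble(chrom = character(), pos = integer(), event_id = character())
    if (length(cis_ids) > 0 && config$splice_site_variant_frac > 0) {
      pick <- cis_ids[runif(length(cis_ids)) < config$splice_site_variant_frac]
      if (length(pick) > 0) {
        ev <- catalog[match(pick, catalog$event_id), ]
        # first intronic base just past the alternative segment: inside the
        # donor window on the plus strand, acceptor window on the minus.
        ss <- tibble(chrom = ev$chrom, pos = ev$alt_end, event_id = ev$event_id)
      }
    }

    vars <- bind_rows(bg, extra, ss)
    vars$splice_site <- c(rep(FALSE, nrow(bg) + nrow(extra)),
                          rep(TRUE, nrow(ss)))
    if (nrow(vars) == 0) {
      return(tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), class = character(),
                    event_id = character(), splice_site = logical()))
    }
    vars <- vars |>
      arrange(.data$chrom, .data$pos, dplyr::desc(.data$splice_site)) |>
      distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
      group_by(.data$chrom) |>
      filter(is.na(dplyr::lag(.data$pos)) | .data$pos - dplyr::lag(.data$pos) >= 4) |>
      ungroup()

    n <- nrow(vars)
    cls <- sample(c("SNV", "insertion", "deletion"), n, replace = TRUE,
                  prob = c(0.9, 0.05, 0.05))
    cls[vars$splice_site] <- "SNV"
    ref <- character(n)
    alt <- character(n)
    for (i in seq_len(n)) {
      anchor <- sample(bases, 1)
      if (cls[i] == "SNV") {
        ref[i] <- anchor
        alt[i] <- sample(setdiff(bases, anchor), 1)
      } else if (cls[i] == "insertion") {
        ref[i] <- anchor
        alt[i] <- paste0(anchor, paste(sample(bases, sample(1:6, 1), replace = TRUE),
                                       collapse = ""))
      } else {
        ref[i] <- paste0(anchor, paste(sample(bases, sample(1:3, 1), replace = TRUE),
                                       collapse = ""))
        alt[i] <- anchor
      }
    }
    vars$ref <- ref
    vars$alt <- alt
    vars$class <- cls
    vars[, c("chrom", "pos", "ref", "alt", "class", "event_id", "splice_site")]
  })
}
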