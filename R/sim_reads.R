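# Read-level simulation: toy genome, two haplotypes differing exactly at
# the variant table, isoform sequences per allele, and error-free (or
# uniformly perturbed) reads labeled with their true allele.

random_chrom_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Overwrite reference bases so the genome agrees with the variant table's
# ref alleles (the genome is synthetic, so the table is authoritative).
stamp_ref_alleles <- function(seqs, variants) {
  for (chr in unique(variants$chrom)) {
    v <- variants[variants$chrom == chr, ]
    s <- seqs[[chr]]
    if (any(v$pos + nchar(v$ref) > nchar(s))) {
      abort(sprintf("variant outside sequence bounds on %s", chr))
    }
    # same-length substitution: splice the ref strings into their spans
    seqs[[chr]] <- apply_variants_to_seq(s, v$pos, v$ref, v$ref)
  }
  seqs
}

# Apply variants (0-based positions, ascending) to a sequence, piecewise.
apply_variants_to_seq <- function(seq, pos, ref, alt) {
  if (length(pos) == 0) return(seq)
  o <- order(pos)
  pos <- pos[o]; ref <- ref[o]; alt <- alt[o]
  pieces <- character(2 * length(pos) + 1)
  cur <- 0L
  for (i in seq_along(pos)) {
    pieces[2 * i - 1] <- substr(seq, cur + 1, pos[i])
    pieces[2 * i] <- alt[i]
    cur <- pos[i] + nchar(ref[i])
  }
  pieces[2 * length(pos) + 1] <- substr(seq, cur + 1, nchar(seq))
  paste(pieces, collapse = "")
}

# Exonic segments (B coordinates) making up each isoform of an event.
isoform_segments <- function(event, isoform) {
  with(event, switch(
    as_type,
    SE = if (isoform == "inclusion") {
      list(c(up_start, up_end), c(alt_start, alt_end), c(down_start, down_end))
    } else {
      list(c(up_start, up_end), c(down_start, down_end))
    },
    RI = if (isoform == "inclusion") {
      list(c(up_start, down_end))
    } else {
      list(c(up_start, up_end), c(down_start, down_end))
    },
    MXE = if (isoform == "inclusion") {
      list(c(up_start, up_end), c(alt_start, alt_end), c(down_start, down_end))
    } else {
      list(c(up_start, up_end), c(alt2_start, alt2_end), c(down_start, down_end))
    },
    A3SS = if (isoform == "inclusion") {
      list(c(up_start, up_end), c(alt_start, down_end))
    } else {
      list(c(up_start, up_end), c(down_start, down_end))
    },
    A5SS = if (isoform == "inclusion") {
      list(c(up_start, alt_end), c(down_start, down_end))
    } else {
      list(c(up_start, up_end), c(down_start, down_end))
    },
    abort(sprintf("unknown AS type '%s'", as_type))
  ))
}

# Build one isoform's B sequence, S sequence, and the B->S offset map.
build_isoform <- function(chrom_seq, segs, variants_chr) {
  seq_b <- paste(vapply(segs, function(se) substr(chrom_seq, se[1] + 1, se[2]),
                        character(1)), collapse = "")
  offs <- cumsum(c(0L, vapply(segs, function(se) se[2] - se[1], integer(1))))
  vs <- list(pos = integer(), ref = character(), alt = character())
  if (nrow(variants_chr) > 0) {
    for (i in seq_along(segs)) {
      se <- segs[[i]]
      hit <- variants_chr$pos >= se[1] &
        (variants_chr$pos + nchar(variants_chr$ref)) <= se[2]
      if (any(hit)) {
        vs$pos <- c(vs$pos, variants_chr$pos[hit] - se[1] + offs[i])
        vs$ref <- c(vs$ref, variants_chr$ref[hit])
        vs$alt <- c(vs$alt, variants_chr$alt[hit])
      }
    }
  }
  seq_s <- apply_variants_to_seq(seq_b, vs$pos, vs$ref, vs$alt)
  o <- order(vs$pos)
  list(
    seq_b = seq_b, seq_s = seq_s,
    var_pos = vs$pos[o],
    var_ref_len = nchar(vs$ref)[o],
    var_alt_len = nchar(vs$alt)[o]
  )
}

# Map a position in B-isoform coordinates to S-isoform coordinates (and the
# reverse). Positions inside a variant's ref span map to its start.
map_b_to_s <- function(pos, iso) {
  if (length(iso$var_pos) == 0) return(pos)
  shift <- cumsum(iso$var_alt_len - iso$var_ref_len)
  idx <- findInterval(pos, iso$var_pos + iso$var_ref_len)
  pos + ifelse(idx == 0, 0L, shift[pmax(idx, 1)])
}

map_s_to_b <- function(pos, iso) {
  if (length(iso$var_pos) == 0) return(pos)
  shift <- cumsum(iso$var_alt_len - iso$var_ref_len)
  pos_s_end <- map_b_to_s(iso$var_pos + iso$var_ref_len, iso)
  idx <- findInterval(pos, pos_s_end)
  pos - ifelse(idx == 0, 0L, shift[pmax(idx, 1)])
}

#' Emit haplotype sequences and allele-labeled reads
#'
#' Constructs a toy genome consistent with the variant table, derives the
#' two haplotypes (B = reference, S = variants applied), builds per-allele
#' isoform sequences for every event, and samples fixed-length reads from
#' the isoform of the generating allele. Reads are error-free by default
#' (an optional uniform substitution rate is available through the config)
#' and carry their true allele, isoform and origin position for oracle
#' checks.
#'
#' @param catalog Event catalog from [generate_catalog()].
#' @param truth Ground truth from [generate_truth()] (supplies per-allele
#'   true PSI, hence isoform choice probabilities).
#' @param variants Variant table from [generate_variants()] (may be empty).
#' @param config A [sim_config()]; `read_length` and `error_rate` are used,
#'   and per-allele read depth is negative-binomial with the configured
#'   depth parameters.
#' @return List with `haplotype_b`, `haplotype_s` (named chromosome
#'   sequences), `isoforms` (tibble of per-event per-isoform sequences for
#'   both alleles), and `reads` (tibble: `read_id`, `event_id`, `allele`,
#'   `isoform`, `start_b` 0-based in B-isoform coordinates, `seq`,
#'   `n_var_overlap` = number of haplotype-differing positions the read
#'   spans).
#' @export
emit_reads <- function(catalog, truth, variants, config) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- attr(catalog, "chrom_sizes")
  if (is.null(sizes)) abort("catalog lacks chrom_sizes attribute")
  L <- config$read_length
  with_seed(derive_seed(config$seed, "reads"), {
    genome <- lapply(as.list(sizes), random_chrom_seq)
    if (nrow(variants) > 0) genome <- stamp_ref_alleles(genome, variants)
    hap_s <- genome
    for (chr in names(genome)) {
      v <- variants[variants$chrom == chr, ]
      hap_s[[chr]] <- apply_variants_to_seq(genome[[chr]], v$pos, v$ref, v$alt)
    }

    iso_rows <- list()
    read_rows <- list()
    for (i in seq_len(nrow(catalog))) {
      ev <- catalog[i, ]
      tr <- truth[truth$event_id == ev$event_id, ]
      vchr <- variants[variants$chrom == ev$chrom, , drop = FALSE]
      isos <- lapply(c(inclusion = "inclusion", exclusion = "exclusion"),
                     function(iso) {
                       build_isoform(genome[[ev$chrom]], isoform_segments(ev, iso), vchr)
                     })
      min_len <- min(vapply(isos, function(x) nchar(x$seq_b), numeric(1)),
                     vapply(isos, function(x) nchar(x$seq_s), numeric(1)))
      if (L >= min_len) {
        abort(sprintf("read_length %d is not shorter than isoform length %d (%s)",
                      L, min_len, ev$event_id))
      }
      iso_rows[[i]] <- tibble(
        event_id = ev$event_id,
        isoform = c("inclusion", "exclusion"),
        seq_B = vapply(isos, function(x) x$seq_b, character(1)),
        seq_S = vapply(isos, function(x) x$seq_s, character(1)),
        map = unname(lapply(isos, function(x) {
          tibble(pos = x$var_pos, ref_len = x$var_ref_len, alt_len = x$var_alt_len)
        }))
      )
      for (allele in c("B", "S")) {
        psi <- if (allele == "B") tr$psi_allele_B else tr$psi_allele_S
        q <- inclusion_probability(psi, ev$c_inclusion, ev$c_exclusion)
        n_reads <- rnbinom(1, mu = config$depth_mean, size = config$depth_dispersion)
        if (n_reads == 0) next
        incl <- runif(n_reads) < q
        for (iso_name in c("inclusion", "exclusion")) {
          m <- sum(if (iso_name == "inclusion") incl else !incl)
          if (m == 0) next
          iso <- isos[[iso_name]]
          own_seq <- if (allele == "B") iso$seq_b else iso$seq_s
          own_len <- nchar(own_seq)
          start_own <- sample.int(own_len - L, m, replace = TRUE) - 1L
          seqs <- substring(own_seq, start_own + 1, start_own + L)
          if (config$error_rate > 0) {
            seqs <- vapply(seqs, perturb_read, character(1),
                           rate = config$error_rate, USE.NAMES = FALSE)
          }
          start_b <- if (allele == "B") start_own else map_s_to_b(start_own, iso)
          n_ov <- count_variant_overlaps(start_own, L, iso, allele)
          read_rows[[length(read_rows) + 1]] <- tibble(
            event_id = ev$event_id, allele = allele, isoform = iso_name,
            start_b = as.integer(start_b), seq = seqs, n_var_overlap = n_ov
          )
        }
      }
    }
    reads <- bind_rows(read_rows)
    if (nrow(reads) > 0) {
      reads <- reads |>
        mutate(read_id = sprintf("r%07d", row_number())) |>
        select("read_id", dplyr::everything())
    }
    list(
      haplotype_b = unlist(genome),
      haplotype_s = unlist(hap_s),
      isoforms = bind_rows(iso_rows),
      reads = reads
    )
  })
}

perturb_read <- function(seq, rate) {
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (j in hit) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
  paste(ch, collapse = "")
}

# Number of haplotype-differing sites a read spans, in its own allele's
# isoform coordinates. SNVs count when the site is covered; indels when the
# read extends past the anchor base (covers the length-changing junction).
count_variant_overlaps <- function(start_own, L, iso, allele) {
  if (length(iso$var_pos) == 0) return(rep(0L, length(start_own)))
  pos_own <- if (allele == "B") iso$var_pos else map_b_to_s(iso$var_pos, iso)
  span_own <- if (allele == "B") iso$var_ref_len else iso$var_alt_len
  vapply(start_own, function(s) {
    covered <- pos_own < s + L & (pos_own + span_own) > s
    junction <- span_own > 1 | iso$var_alt_len != iso$var_ref_len
    # indel junction requires covering anchor and the base after it
    detect <- covered & (!junction | (pos_own + 1 < s + L & pos_own >= s - span_own))
    sum(detect)
  }, integer(1))
}
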