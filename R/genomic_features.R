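#' Flanking regions of alternative-splicing events
#'
#' Regions where cis-acting variants are expected to act: for SE, the
#' alternative exon plus `flank` nt of intron on each side; for RI, the
#' retained intron plus `flank` nt of exon on each side; for A3SS/A5SS, the
#' alternative exon region plus its `flank` nt exon/intron neighbours; for
#' MXE, both alternative exons each with `flank` nt intron flanks.
#' Intervals are 0-based half-open and clipped at 0.
#'
#' @param events Event catalog tibble (one or more rows).
#' @param flank Flank width in nt. Default 100.
#' @return Tibble: `event_id`, `chrom`, `start`, `end` (one row per
#'   interval; intervals of one event never overlap).
#' @export
flanking_regions <- function(events, flank = 100) {
  bad <- setdiff(unique(events$as_type), c("SE", "RI", "MXE", "A3SS", "A5SS"))
  if (length(bad) > 0) abort(sprintf("unknown AS type '%s'", bad[1]))
  one <- function(id, chrom, s, e) {
    tibble(event_id = id, chrom = chrom,
           start = as.integer(pmax(s - flank, 0)),
           end = as.integer(e + flank))
  }
  main <- one(events$event_id, events$chrom, events$alt_start, events$alt_end)
  mx <- events[events$as_type == "MXE", , drop = FALSE]
  second <- if (nrow(mx) > 0) {
    one(mx$event_id, mx$chrom, mx$alt2_start, mx$alt2_end)
  } else {
    NULL
  }
  bind_rows(main, second) |>
    arrange(.data$event_id, .data$start)
}

# Count variants per region set using sorted-position binary search.
count_variants_in_regions <- function(regions, variants) {
  if (nrow(regions) == 0) abort("zero-length region set")
  counts <- integer(nrow(regions))
  for (chr in unique(regions$chrom)) {
    rid <- which(regions$chrom == chr)
    pos <- sort(variants$pos[variants$chrom == chr])
    if (length(pos) == 0) next
    counts[rid] <- findInterval(regions$end[rid] - 0.5, pos) -
      findInterval(regions$start[rid] - 0.5, pos)
  }
  counts
}

#' Variant density over a region set
#'
#' Number of variants whose anchor position falls inside the union of the
#' regions, divided by the total region length in nt. Indels count once at
#' their anchor. Computed per event when the region set covers several.
#'
#' @param regions Region tibble from [flanking_regions()].
#' @param variants Variant tibble (`chrom`, `pos` 0-based).
#' @return Tibble: `event_id`, `n_variants`, `length_nt`, `density`
#'   (variants per nt).
#' @export
variant_density <- function(regions, variants) {
  if (nrow(regions) == 0 || any(regions$end <= regions$start)) {
    abort("regions must be non-empty with positive length")
  }
  regions$n <- count_variants_in_regions(regions, variants)
  regions |>
    group_by(.data$event_id) |>
    summarise(n_variants = sum(.data$n),
              length_nt = sum(.data$end - .data$start)) |>
    mutate(density = .data$n_variants / .data$length_nt)
}

# Donor/acceptor windows around the boundaries of the alternative
# segment(s). Window coordinates follow the standard splice-site
# convention: positions upstream of the junction in transcript direction
# are negative, so a donor [-3, +6] spans 3 exonic and 6 intronic nt and
# an acceptor [-20, +3] spans 20 intronic and 3 exonic nt. Strand-aware;
# RI junction roles are swapped because the alternative segment is
# intronic.
splice_site_windows <- function(events, donor_window = c(-3, 6),
                                acceptor_window = c(-20, 3)) {
  rows <- list()
  win <- function(id, chrom, boundary, kind, plus) {
    w <- if (kind == "donor") donor_window else acceptor_window
    if (plus) {
      tibble(event_id = id, chrom = chrom,
             start = boundary + w[1], end = boundary + w[2])
    } else {
      tibble(event_id = id, chrom = chrom,
             start = boundary - w[2], end = boundary - w[1])
    }
  }
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    segs <- list(c(ev$alt_start, ev$alt_end))
    if (ev$as_type == "MXE") segs <- c(segs, list(c(ev$alt2_start, ev$alt2_end)))
    exonic <- ev$as_type != "RI"
    plus <- ev$strand == "+"
    # junction role at the genomic-left boundary of the segment: for an
    # exonic segment it is the acceptor on +, donor on -; inverted for RI.
    start_kind <- if (xor(plus, !exonic)) "acceptor" else "donor"
    end_kind <- if (start_kind == "acceptor") "donor" else "acceptor"
    for (sg in segs) {
      rows[[length(rows) + 1]] <- win(ev$event_id, ev$chrom, sg[1],
                                      start_kind, plus)
      rows[[length(rows) + 1]] <- win(ev$event_id, ev$chrom, sg[2],
                                      end_kind, plus)
    }
  }
  bind_rows(rows) |>
    mutate(start = pmax(.data$start, 0L))
}

#' Splice-site variant overlap
#'
#' Flags events with at least one variant inside a donor or acceptor window
#' of their alternative junctions — candidate site-disrupting cis variants.
#'
#' @param events Event catalog tibble.
#' @param variants Variant tibble.
#' @param donor_window,acceptor_window Windows relative to the exon/intron
#'   boundary, exon-negative convention. Defaults `c(-3, 6)` and
#'   `c(-20, 3)`.
#' @return Tibble: `event_id`, `splice_site_variant` (logical).
#' @export
splice_site_variant_overlap <- function(events, variants,
                                        donor_window = c(-3, 6),
                                        acceptor_window = c(-20, 3)) {
  wins <- splice_site_windows(events, donor_window, acceptor_window)
  wins$n <- if (nrow(variants) == 0) 0L else count_variants_in_regions(wins, variants)
  hit <- wins |>
    group_by(.data$event_id) |>
    summarise(splice_site_variant = any(.data$n > 0))
  tibble(event_id = events$event_id) |>
    left_join(hit, by = "event_id") |>
    mutate(splice_site_variant = !is.na(.data$splice_site_variant) &
             .data$splice_site_variant)
}

#' Coding-region and reading-frame classification
#'
#' An event is coding when its alternative region overlaps annotated CDS.
#' For coding events the frame class is frame-neutral when the nt-length
#' difference between the two isoforms is divisible by 3 (SE/RI/A3SS/A5SS:
#' the alternative region length; MXE: the absolute difference of the two
#' exon lengths), else frame-shifting; non-coding events are
#' not-applicable.
#'
#' @param events Event catalog tibble with `cds_start`/`cds_end` columns
#'   (NA for events without annotation; these classify as non-coding with
#'   a warning).
#' @return Tibble: `event_id`, `region_class` (`coding`/`non-coding`),
#'   `frame_class` (`frame-neutral`/`frame-shifting`/`not-applicable`).
#' @export
classify_event_effect <- function(events) {
  if (!all(c("cds_start", "cds_end") %in% names(events))) {
    warn("no CDS annotation; classifying all events as non-coding")
    events$cds_start <- NA_integer_
    events$cds_end <- NA_integer_
  }
  coding <- !is.na(events$cds_start) & !is.na(events$cds_end) &
    events$alt_start < events$cds_end & events$alt_end > events$cds_start
  len_diff <- alt_region_length(events, reduce = function(a, b) abs(a - b))
  tibble(
    event_id = events$event_id,
    region_class = if_else(coding, "coding", "non-coding"),
    frame_class = dplyr::case_when(
      !coding ~ "not-applicable",
      len_diff %% 3 == 0 ~ "frame-neutral",
      TRUE ~ "frame-shifting"
    )
  )
}

#' Mann-Whitney comparison of two groups
#'
#' Two-sided Mann-Whitney U test, e.g. of flanking-region variant densities
#' between cis-divergent and control events. The exact U distribution is
#' used when the smaller group has at most `exact_max` values and there are
#' no ties; otherwise the normal approximation with tie correction.
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @param exact_max Largest small-group size for the exact test. Default 8.
#' @return Two-sided p-value.
#' @export
compare_groups <- function(values_a, values_b, exact_max = 8) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- min(length(values_a), length(values_b)) <= exact_max && !ties
  suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = FALSE)$p.value
  )
}

#' Enrichment percentages and Fisher test for a 2x2 classification
#'
#' Given counts of a property in two groups (k of n), reports the
#' percentages rounded to one decimal and the two-sided Fisher exact
#' p-value of the 2x2 table `(k1, n1 - k1; k2, n2 - k2)`.
#'
#' @param k1,n1,k2,n2 Hits and totals for the two groups (`k <= n`).
#' @return Tibble: `pct1`, `pct2`, `p_value`.
#' @export
enrichment_table_test <- function(k1, n1, k2, n2) {
  if (n1 == 0 || n2 == 0) abort("group totals must be positive")
  if (k1 > n1 || k2 > n2) abort("k must not exceed n")
  tibble(
    pct1 = round(100 * k1 / n1, 1),
    pct2 = round(100 * k2 / n2, 1),
    p_value = fisher_divergence_test(k1, n1 - k1, k2, n2 - k2)
  )
}

#' Position-weight-matrix splice-site score
#'
#' Log-odds score in bits of a sequence window against a base-frequency
#' matrix: sum over positions of `log2(max(f, 1e-4) / 0.25)` with a uniform
#' background (the pseudo-frequency floor keeps zero-frequency bases
#' finite). Positions with base `N` are skipped with a warning.
#'
#' @param sequence Character string; its length must match `ncol(pwm)`.
#' @param pwm Numeric matrix with rownames A, C, G, T; columns sum to 1.
#' @return Score in bits.
#' @export
score_splice_site <- function(sequence, pwm) {
  stopifnot(is.matrix(pwm), all(c("A", "C", "G", "T") %in% rownames(pwm)))
  if (any(abs(colSums(pwm[c("A", "C", "G", "T"), , drop = FALSE]) - 1) > 1e-6)) {
    abort("pwm columns must sum to 1")
  }
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (length(ch) != ncol(pwm)) {
    abort(sprintf("window length %d does not match matrix width %d",
                  length(ch), ncol(pwm)))
  }
  score <- 0
  for (j in seq_along(ch)) {
    if (ch[j] == "N") {
      warn(sprintf("base N at position %d skipped", j))
      next
    }
    score <- score + log2(max(unname(pwm[ch[j], j]), 1e-4) / 0.25)
  }
  score
}

#' Canonical donor-site weight matrix
#'
#' Base frequencies for the 9-nt donor window (3 exonic, 6 intronic nt,
#' positions -3..+6) of mammalian U2-type introns, with the near-invariant
#' GT at intron positions +1/+2. Frequencies follow the classical splice
#' site consensus profiles.
#'
#' @return 4 x 9 frequency matrix.
#' @export
donor_pwm <- function() {
  m <- matrix(c(
    # -3    -2    -1    +1    +2    +3    +4    +5    +6
    0.33, 0.60, 0.08, 0.00, 0.00, 0.49, 0.71, 0.06, 0.15,
    0.37, 0.13, 0.04, 0.00, 0.00, 0.03, 0.08, 0.05, 0.19,
    0.18, 0.14, 0.81, 0.99, 0.01, 0.45, 0.12, 0.84, 0.20,
    0.12, 0.13, 0.07, 0.01, 0.99, 0.03, 0.09, 0.05, 0.46
  ), nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(m, 2, colSums(m), "/")
}

#' Canonical acceptor-site weight matrix
#'
#' Base frequencies for the 23-nt acceptor window (20 intronic including
#' the polypyrimidine tract and the near-invariant AG, 3 exonic nt).
#'
#' @return 4 x 23 frequency matrix.
#' @export
acceptor_pwm <- function() {
  py <- c(A = 0.10, C = 0.31, G = 0.10, T = 0.49)
  m <- matrix(rep(py, 15), nrow = 4)
  branch <- matrix(c(
    # -5    -4    -3    AG... +1    +2    +3
    0.25, 0.05, 0.26, 1.00, 0.00, 0.24, 0.25, 0.20,
    0.25, 0.66, 0.14, 0.00, 0.00, 0.16, 0.20, 0.24,
    0.22, 0.01, 0.50, 0.00, 1.00, 0.49, 0.28, 0.30,
    0.28, 0.28, 0.10, 0.00, 0.00, 0.11, 0.27, 0.26
  ), nrow = 4, byrow = TRUE)
  m <- cbind(m, branch)
  dimnames(m) <- list(c("A", "C", "G", "T"), NULL)
  sweep(m, 2, colSums(m), "/")
}
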