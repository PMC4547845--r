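#' Semi-global edit distance of a read against a locus
#'
#' Levenshtein distance (substitutions, insertions, deletions each cost 1)
#' of the full read against the best-matching window of the locus: gaps at
#' the locus ends are free, so an exact substring scores 0. `N` matches
#' nothing (always a mismatch). This is the distance used to assign hybrid
#' reads to parental alleles.
#'
#' @param read Read sequence (single string over A, C, G, T, N).
#' @param locus Locus sequence to align against.
#' @return Non-negative integer edit distance.
#' @export
read_edit_distance <- function(read, locus) {
  if (nchar(read) == 0) abort("empty read")
  if (nchar(locus) == 0) return(nchar(read))
  r <- strsplit(toupper(read), "", fixed = TRUE)[[1]]
  l <- strsplit(toupper(locus), "", fixed = TRUE)[[1]]
  m <- length(l)
  prev <- rep(0L, m + 1)            # free leading gap in the locus
  idx <- 0:m
  for (i in seq_along(r)) {
    sub_cost <- as.integer(l != r[i] | l == "N" | r[i] == "N")
    cand <- pmin(prev[1:m] + sub_cost, prev[2:(m + 1)] + 1L)
    cand <- c(prev[1] + 1L, cand)
    # left-to-right insertion relaxation: cur[j] = min_i<=j cand[i] + (j - i)
    cur <- idx + cummin(cand - idx)
    prev <- cur
  }
  min(prev)                          # free trailing gap in the locus
}

#' Assign a read to a parental allele by edit distance
#'
#' Computes the semi-global Levenshtein distance of the read against the
#' corresponding locus of each haplotype and assigns the read to the
#' strictly closer allele; reads equidistant to both haplotypes are
#' unassigned (discarded from allele-specific counting).
#'
#' @param read Read sequence.
#' @param locus_b,locus_s Locus sequences of haplotypes B and S.
#' @return One-row tibble: `allele` (`"B"`, `"S"` or `"unassigned"`),
#'   `edit_distance_B`, `edit_distance_S`.
#' @export
assign_read <- function(read, locus_b, locus_s) {
  db <- read_edit_distance(read, locus_b)
  ds <- read_edit_distance(read, locus_s)
  tibble(
    allele = if (db < ds) "B" else if (ds < db) "S" else "unassigned",
    edit_distance_B = db,
    edit_distance_S = ds
  )
}

#' Assign simulated reads to alleles
#'
#' Vectorised assignment for reads produced by [emit_reads()]. The locus of
#' each haplotype is retrieved from the read's origin interval on its
#' isoform, widened by `slop` nt on each side (indel offsets between the
#' haplotypes are absorbed by the slop); no re-alignment is performed.
#'
#' @param reads Read tibble from [emit_reads()].
#' @param isoforms Isoform tibble from [emit_reads()].
#' @param slop Extra locus nt on each side of the origin interval.
#' @return `reads` with `assigned_allele`, `edit_distance_B`,
#'   `edit_distance_S` appended.
#' @export
assign_reads <- function(reads, isoforms, slop = 20) {
  key <- paste(isoforms$event_id, isoforms$isoform)
  iso_idx <- match(paste(reads$event_id, reads$isoform), key)
  if (anyNA(iso_idx)) abort("reads reference isoforms missing from the table")
  L <- nchar(reads$seq)
  out <- purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    iso <- isoforms[iso_idx[i], ]
    map <- iso$map[[1]]
    iso_obj <- list(var_pos = map$pos, var_ref_len = map$ref_len,
                    var_alt_len = map$alt_len)
    sb <- reads$start_b[i]
    ss <- map_b_to_s(sb, iso_obj)
    locus_b <- substr(iso$seq_B, max(sb - slop, 0) + 1, sb + L[i] + slop)
    locus_s <- substr(iso$seq_S, max(ss - slop, 0) + 1, ss + L[i] + slop)
    assign_read(reads$seq[i], locus_b, locus_s)
  })
  reads |>
    mutate(assigned_allele = out$allele,
           edit_distance_B = out$edit_distance_B,
           edit_distance_S = out$edit_distance_S)
}

#' Build a mock F1 hybrid
#'
#' A mock hybrid is a computational mixture of the two parental samples,
#' processed like a real hybrid, used to detect allele-assignment bias.
#' Two input levels are supported:
#'
#' * **Count level** (default path, a data frame input): each parental count
#'   record is binomially thinned by the event's assignability — the
#'   fraction of its reads an assignment step would recover — yielding mock
#'   allelic records (`sample = "mock"`, `allele` = `B`/`S`). With
#'   assignability 1 the mock counts reproduce the parental counts exactly.
#' * **Read level** (two read tibbles): equal amounts are taken from each
#'   parent (the larger side is downsampled to the smaller), and the mixture
#'   is returned for assignment with [assign_reads()].
#'
#' @param parental Either a count tibble with parental records
#'   (`sample` in `parent_B`/`parent_S`) or a read tibble of parent B.
#' @param parental_s Read tibble of parent S (read-level path only).
#' @param assignability Scalar in (0, 1], or a data frame
#'   (`event_id`, `assignability`) for per-event values (count level).
#' @param seed Integer seed for the thinning / downsampling draws.
#' @return Mock count records, or the mixed read tibble.
#' @export
build_mock_f1 <- function(parental, parental_s = NULL, assignability = 0.6,
                          seed = 1L) {
  if (!is.null(parental_s)) {
    n_b <- nrow(parental)
    n_s <- nrow(parental_s)
    if (n_b == 0 || n_s == 0) abort("both parental read sets must be non-empty")
    n <- min(n_b, n_s)
    return(with_seed(derive_seed(seed, "mockreads"), {
      bind_rows(
        parental[sample.int(n_b, n), ],
        parental_s[sample.int(n_s, n), ]
      )
    }))
  }
  counts <- as_tibble(parental)
  if (!all(counts$sample %in% c("parent_B", "parent_S"))) {
    abort("count-level mock construction expects parental records only")
  }
  if (is.data.frame(assignability)) {
    a <- assignability$assignability[match(counts$event_id, assignability$event_id)]
    if (anyNA(a)) abort("assignability missing for some events")
  } else {
    a <- rep(assignability, nrow(counts))
  }
  if (any(a <= 0 | a > 1)) abort("assignability must lie in (0, 1]")
  with_seed(derive_seed(seed, "mockcounts"), {
    counts |>
      mutate(
        n_inclusion = rbinom(n(), .data$n_inclusion, a),
        n_exclusion = rbinom(n(), .data$n_exclusion, a),
        allele = if_else(.data$sample == "parent_B", "B", "S"),
        sample = "mock"
      )
  })
}

#' Downsample parental counts to mock allelic coverage
#'
#' Hypergeometric subsampling without replacement of each parental
#' (inclusion, exclusion) record to a target total — the coverage of the
#' matching allele in the mock hybrid. The full-vs-downsampled PSI contrast
#' isolates pure sampling variance and calibrates the local standard
#' deviation of the mock filter.
#'
#' @param counts Parental count tibble.
#' @param targets Data frame (`event_id`, `sample`, `replicate`, `target`)
#'   or a vector matching `counts` rows, giving the target totals.
#' @param seed Integer seed.
#' @return `counts` with records subsampled to the targets. A target of 0
#'   yields a (0, 0) record, left to the coverage filter.
#' @export
downsample_parental <- function(counts, targets, seed = 1L) {
  counts <- as_tibble(counts)
  if (is.data.frame(targets)) {
    key <- function(d) paste(d$event_id, d$sample, d$replicate)
    t <- targets$target[match(key(counts), key(targets))]
    if (anyNA(t)) abort("targets missing for some count records")
  } else {
    t <- rep_len(targets, nrow(counts))
  }
  tot <- counts$n_inclusion + counts$n_exclusion
  if (any(t > tot)) {
    bad <- counts$event_id[which(t > tot)[1]]
    abort(sprintf("target coverage exceeds parental coverage (first: %s)", bad))
  }
  with_seed(derive_seed(seed, "downsample"), {
    k <- rhyper(nrow(counts), counts$n_inclusion, counts$n_exclusion, t)
    counts |>
      mutate(n_inclusion = k, n_exclusion = t - k)
  })
}
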