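# Readers/writers for the on-disk stage formats. Counts, truth and result
# tables travel as TSV; the event catalog as GFF3 (1-based closed on
# output); variants as VCF 4.2; haplotypes as FASTA.

#' Write / read a count table
#'
#' Columns: `event_id`, `sample`, `replicate`, `allele`, `n_inclusion`,
#' `n_exclusion`.
#'
#' @param counts Count tibble.
#' @param path File path.
#' @return `read_counts_tsv()` returns the tibble; writers return the path
#'   invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    event_id = readr::col_character(),
    sample = readr::col_character(),
    replicate = readr::col_integer(),
    allele = readr::col_character(),
    n_inclusion = readr::col_integer(),
    n_exclusion = readr::col_integer()
  ))
}

#' Write the event catalog as GFF3
#'
#' Each event becomes a parent feature with one child feature per segment
#' (upstream/alternative/downstream exons, second alternative exon for
#' MXE). Internal 0-based half-open coordinates are converted to GFF's
#' 1-based closed intervals.
#'
#' @param catalog Event catalog tibble.
#' @param path Output path.
#' @export
write_catalog_gff3 <- function(catalog, path) {
  if (!requireNamespace("GenomicRanges", quietly = TRUE) ||
        !requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("GFF3 output needs the GenomicRanges and rtracklayer packages")
  }
  seg_rows <- purrr::map_dfr(seq_len(nrow(catalog)), function(i) {
    ev <- catalog[i, ]
    segs <- tibble(
      name = c("upstream", "alternative",
               if (ev$as_type == "MXE") "alternative2" else NULL, "downstream"),
      start = c(ev$up_start, ev$alt_start,
                if (ev$as_type == "MXE") ev$alt2_start else NULL, ev$down_start),
      end = c(ev$up_end, ev$alt_end,
              if (ev$as_type == "MXE") ev$alt2_end else NULL, ev$down_end)
    )
    bind_rows(
      tibble(name = "event", start = ev$up_start, end = ev$down_end),
      segs
    ) |>
      mutate(event_id = ev$event_id, chrom = ev$chrom, strand = ev$strand,
             as_type = ev$as_type)
  })
  gr <- GenomicRanges::GRanges(
    seqnames = seg_rows$chrom,
    ranges = IRanges::IRanges(start = seg_rows$start + 1, end = seg_rows$end),
    strand = seg_rows$strand,
    type = ifelse(seg_rows$name == "event", "splicing_event", "segment"),
    ID = ifelse(seg_rows$name == "event", seg_rows$event_id,
                paste(seg_rows$event_id, seg_rows$name, sep = ":")),
    Parent = ifelse(seg_rows$name == "event", NA_character_, seg_rows$event_id),
    as_type = seg_rows$as_type
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a variant table as VCF 4.2
#'
#' @param variants Variant tibble (`chrom`, 0-based `pos`, `ref`, `alt`).
#' @param path Output path.
#' @export
write_variants_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=splicecistrans",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(variants) == 0) character() else {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
            variants$chrom, variants$pos + 1L, variants$ref, variants$alt)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into the internal variant table
#'
#' @param path VCF path.
#' @return Tibble: `chrom`, `pos` (0-based), `ref`, `alt`, `class`.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF input needs the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), class = character()))
  }
  tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF,
    alt = fix$ALT
  ) |>
    mutate(class = dplyr::case_when(
      nchar(.data$ref) == nchar(.data$alt) ~ "SNV",
      nchar(.data$ref) < nchar(.data$alt) ~ "insertion",
      TRUE ~ "deletion"
    ))
}

#' Write haplotype sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("FASTA output needs the Biostrings package")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read FASTA into a named character vector
#'
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("FASTA input needs the Biostrings package")
  }
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
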