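mk_event <- function(as_type = "SE", strand = "+", alt = c(1000L, 1100L),
                     alt2 = c(NA_integer_, NA_integer_),
                     cds = c(NA_integer_, NA_integer_)) {
  tibble::tibble(
    event_id = "ev1", as_type = as_type, chrom = "chrT1", strand = strand,
    up_start = 500L, up_end = 700L,
    alt_start = alt[1], alt_end = alt[2],
    alt2_start = alt2[1], alt2_end = alt2[2],
    down_start = 1500L, down_end = 1700L,
    c_inclusion = 1, c_exclusion = 1,
    cds_start = cds[1], cds_end = cds[2]
  )
}

test_that("flanking regions follow the per-type composition rules", {
  se <- flanking_regions(mk_event("SE"))
  expect_equal(se$start, 900L)
  expect_equal(se$end, 1200L)
  expect_equal(sum(se$end - se$start), 300L)

  mxe <- flanking_regions(mk_event("MXE", alt = c(1000L, 1120L),
                                   alt2 = c(1300L, 1390L)))
  expect_equal(sum(mxe$end - mxe$start), 120L + 90L + 4L * 100L)

  zero <- flanking_regions(mk_event("RI"), flank = 0)
  expect_equal(zero$start, 1000L)
  expect_equal(zero$end, 1100L)

  expect_error(flanking_regions(dplyr::mutate(mk_event(), as_type = "XX")),
               "unknown AS type")

  # closed-form total-length property on a generated catalog
  cat <- generate_catalog(sim_config(n_events = 300, seed = 71))
  fr <- flanking_regions(cat)
  tot <- as.numeric(tapply(fr$end - fr$start, fr$event_id, sum)[cat$event_id])
  la <- cat$alt_end - cat$alt_start
  lb <- ifelse(is.na(cat$alt2_start), 0L, cat$alt2_end - cat$alt2_start)
  expected <- ifelse(cat$as_type == "MXE", la + lb + 400L, la + 200L)
  expect_equal(tot, as.numeric(expected))
})

test_that("variant density counts anchors in half-open regions", {
  regions <- flanking_regions(mk_event("SE"))  # union [900, 1200)
  v <- tibble::tibble(chrom = "chrT1", pos = c(900L, 1000L, 1199L))
  d <- variant_density(regions, v)
  expect_equal(d$density, 3 / 300)
  # half-open end is excluded, start included
  v2 <- tibble::tibble(chrom = "chrT1", pos = c(1200L, 899L))
  expect_equal(variant_density(regions, v2)$density, 0)
  expect_equal(variant_density(regions, v[0, ])$density, 0)
  expect_error(variant_density(regions[0, ], v), "non-empty")
})

test_that("splice-site windows catch junction variants strand-awarely", {
  ev <- mk_event("SE")
  # first intronic base past the alternative exon (the G of GT on +)
  donor_plus1 <- tibble::tibble(chrom = "chrT1", pos = 1100L)
  expect_true(splice_site_variant_overlap(ev, donor_plus1)$splice_site_variant)
  # deep intronic variant is outside every window
  deep <- tibble::tibble(chrom = "chrT1", pos = 1150L)
  expect_false(splice_site_variant_overlap(ev, deep)$splice_site_variant)
  expect_false(splice_site_variant_overlap(ev, deep[0, ])$splice_site_variant)
  # acceptor side of the alternative exon, 10 nt into the intron
  acc <- tibble::tibble(chrom = "chrT1", pos = 990L)
  expect_true(splice_site_variant_overlap(ev, acc)$splice_site_variant)
  # on the minus strand the same boundary holds an acceptor window instead
  ev_m <- mk_event("SE", strand = "-")
  # on the minus strand 1100 is the acceptor junction: 1104 sits in its
  # 20-nt intronic stretch, while the donor window at 1000 is only 6 nt deep
  expect_true(splice_site_variant_overlap(
    ev_m, tibble::tibble(chrom = "chrT1", pos = 1104L))$splice_site_variant)
  expect_false(splice_site_variant_overlap(
    ev_m, tibble::tibble(chrom = "chrT1", pos = 990L))$splice_site_variant)
})

test_that("event effect classification follows CDS overlap and frame rule", {
  coding_neutral <- mk_event("SE", alt = c(1000L, 1099L), cds = c(400L, 1800L))
  cl <- classify_event_effect(coding_neutral)
  expect_equal(cl$region_class, "coding")
  expect_equal(cl$frame_class, "frame-neutral")  # 99 nt

  coding_shift <- mk_event("SE", alt = c(1000L, 1100L), cds = c(400L, 1800L))
  expect_equal(classify_event_effect(coding_shift)$frame_class, "frame-shifting")

  utr <- mk_event("SE", alt = c(1000L, 1100L), cds = c(100L, 600L))
  cl3 <- classify_event_effect(utr)
  expect_equal(cl3$region_class, "non-coding")
  expect_equal(cl3$frame_class, "not-applicable")

  mxe <- mk_event("MXE", alt = c(1000L, 1120L), alt2 = c(1300L, 1387L),
                  cds = c(400L, 1800L))
  expect_equal(classify_event_effect(mxe)$frame_class, "frame-neutral")  # |120-87|=33

  noann <- dplyr::select(mk_event("SE", cds = c(400L, 1800L)),
                         -cds_start, -cds_end)
  expect_warning(cl4 <- classify_event_effect(noann), "no CDS annotation")
  expect_equal(cl4$region_class, "non-coding")
})

test_that("Mann-Whitney comparison matches rank enumeration and is rank-based", {
  expect_equal(compare_groups(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(compare_groups(c(1, 2, 3), c(4, 5, 6)),
               oracle_mann_whitney_p(c(1, 2, 3), c(4, 5, 6)))
  set.seed(72)
  for (i in 1:10) {
    x <- rnorm(sample(3:6, 1))
    y <- rnorm(sample(3:6, 1))
    expect_equal(compare_groups(x, y), oracle_mann_whitney_p(x, y),
                 tolerance = 1e-12)
    expect_equal(compare_groups(exp(x), exp(y)), compare_groups(x, y))
  }
  expect_gt(compare_groups(rep(c(1, 2), 10), rep(c(1, 2), 10)), 0.99)
  expect_error(compare_groups(numeric(), 1:3), "non-empty")
})

test_that("enrichment percentages are exact one-decimal roundings", {
  expect_warning(r <- enrichment_table_test(0, 10, 0, 10), "degenerate")
  expect_equal(c(r$pct1, r$pct2, r$p_value), c(0, 0, 1))
  r2 <- enrichment_table_test(273, 4235, 206, 4183)
  expect_equal(c(r2$pct1, r2$pct2), c(6.4, 4.9))
  expect_error(enrichment_table_test(5, 0, 1, 10), "positive")
  expect_error(enrichment_table_test(11, 10, 1, 10), "exceed")
})

test_that("PWM scoring is log-odds in bits with N skipped", {
  uni <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(score_splice_site("ACGTAC", uni), 0)
  conc <- matrix(c(0.97, 0.01, 0.01, 0.01), 4, 1,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(score_splice_site("A", conc), log2(0.97 / 0.25),
               tolerance = 1e-6)
  expect_equal(score_splice_site("A", conc), 1.956, tolerance = 1e-3)
  expect_warning(sN <- score_splice_site("NCGTAC", uni), "skipped")
  expect_equal(sN, 0)
  expect_error(score_splice_site("ACG", uni), "length")
  # disrupting the invariant G of a GT donor lowers the score
  pwm <- donor_pwm()
  donor <- "CAGGTAAGT"
  broken <- "CAGATAAGT"
  expect_lt(score_splice_site(broken, pwm), score_splice_site(donor, pwm))
})
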