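test_that("assignment follows the strict edit-distance rule", {
  locus_b <- "ACGTACGTACGTACGTACGT"
  locus_s <- sub("TACGTACG", "TACCTACG", locus_b)  # one substitution
  read <- substr(locus_b, 3, 14)
  a <- assign_read(read, locus_b, locus_s)
  expect_equal(a$allele, "B")
  expect_equal(a$edit_distance_B, 0)
  expect_equal(a$edit_distance_S, 1)
  # swapping haplotype arguments swaps the label
  a2 <- assign_read(read, locus_s, locus_b)
  expect_equal(a2$allele, "S")
  # a read overlapping no variant is equidistant, hence unassigned
  tie <- assign_read(substr(locus_b, 15, 20), locus_b, locus_s)
  expect_equal(tie$allele, "unassigned")
  expect_error(assign_read("", locus_b, locus_s), "empty read")
})

test_that("a 9-nt insertion separates the alleles by 9 edits", {
  base <- strrep("A", 60)              # homogeneous context: no partial matches
  ins <- strrep("C", 9)
  locus_s <- paste0(substr(base, 1, 30), ins, substr(base, 31, 60))
  read <- substr(locus_s, 25, 46)      # spans the insertion, drawn from S
  a <- assign_read(read, base, locus_s)
  expect_equal(a$edit_distance_S, 0)
  expect_equal(a$edit_distance_B, 9)
  expect_equal(a$edit_distance_B, oracle_semiglobal_distance(read, base))
  expect_equal(a$allele, "S")
})

test_that("the banded distance matches a full-matrix DP oracle", {
  set.seed(32)
  for (i in 1:200) {
    L <- sample(8:30, 1)
    M <- sample(10:50, 1)
    read <- paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                         prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    locus <- paste(sample(c("A", "C", "G", "T"), M, replace = TRUE), collapse = "")
    expect_equal(read_edit_distance(read, locus),
                 oracle_semiglobal_distance(read, locus))
  }
})

test_that("error-free simulated reads are never misassigned", {
  cfg <- sim_config(n_events = 12, frac_cis = 0.5, frac_trans = 0,
                    frac_both = 0, depth_mean = 30, depth_dispersion = 10,
                    variant_rate_background = 0.005,
                    variant_rate_cis_flank = 0.02, seed = 33)
  cat <- generate_catalog(cfg)
  tr <- generate_truth(cat, cfg)
  v <- generate_variants(cat, tr, cfg)
  em <- emit_reads(cat, tr, v, cfg)
  asn <- assign_reads(em$reads, em$isoforms)
  mis <- asn$assigned_allele != "unassigned" & asn$assigned_allele != asn$allele
  expect_equal(sum(mis), 0)
  # reads spanning no haplotype difference are exactly the unassigned ones
  expect_true(all(asn$assigned_allele[asn$n_var_overlap == 0] == "unassigned"))
  # SNV-only isoforms: every variant-spanning read is assigned
  iso <- em$isoforms
  snv_only <- vapply(iso$map, function(m) all(m$ref_len == 1 & m$alt_len == 1),
                     logical(1))
  keep <- paste(asn$event_id, asn$isoform) %in%
    paste(iso$event_id, iso$isoform)[snv_only]
  sub <- asn[keep & asn$n_var_overlap > 0, ]
  expect_true(all(sub$assigned_allele == sub$allele))
})

test_that("count-level mock construction thins parental counts", {
  counts <- tibble::tibble(
    event_id = rep(sprintf("ev%04d", 1:3000), each = 2),
    sample = rep(c("parent_B", "parent_S"), 3000),
    replicate = 1L, allele = "pooled",
    n_inclusion = 120L, n_exclusion = 80L
  )
  mock1 <- build_mock_f1(counts, assignability = 1)
  expect_equal(mock1$n_inclusion, counts$n_inclusion)
  expect_equal(mock1$n_exclusion, counts$n_exclusion)
  expect_setequal(unique(mock1$allele), c("B", "S"))
  expect_true(all(mock1$sample == "mock"))

  mock <- build_mock_f1(counts, assignability = 0.5, seed = 5)
  m <- mean(mock$n_inclusion)
  expect_lt(abs(m - 60), 3 * sqrt(120 * 0.25 / nrow(mock)))
  expect_error(build_mock_f1(dplyr::mutate(counts, sample = "hybrid")),
               "parental")
})

test_that("read-level mock mixes equal amounts from each parent", {
  rb <- tibble::tibble(read_id = sprintf("b%d", 1:4000), origin = "B")
  rs <- tibble::tibble(read_id = sprintf("s%d", 1:1000), origin = "S")
  mix <- build_mock_f1(rb, rs, seed = 2)
  expect_equal(nrow(mix), 2000)
  expect_equal(unname(table(mix$origin)["B"]), 1000L)
})

test_that("downsampling is hypergeometric with the right mean", {
  counts <- tibble::tibble(
    event_id = sprintf("ev%05d", 1:10000), sample = "parent_B",
    replicate = 1L, allele = "pooled",
    n_inclusion = 80L, n_exclusion = 20L
  )
  ds <- downsample_parental(counts, targets = 25L, seed = 3)
  expect_true(all(ds$n_inclusion + ds$n_exclusion == 25))
  se <- sd(ds$n_inclusion) / sqrt(nrow(ds))
  expect_lt(abs(mean(ds$n_inclusion) - 20), 3 * se)
  # identity at full coverage, (0,0) at target zero
  full <- downsample_parental(counts[1:5, ], targets = 100L)
  expect_equal(full$n_inclusion, counts$n_inclusion[1:5])
  zero <- downsample_parental(counts[1:5, ], targets = 0L)
  expect_true(all(zero$n_inclusion == 0 & zero$n_exclusion == 0))
  expect_error(downsample_parental(counts[1:5, ], targets = 101L), "ev00001")
})

test_that("mock allelic PSI reproduces parental PSI on unbiased data", {
  cfg <- sim_config(n_events = 600, depth_mean = 150, depth_dispersion = 8,
                    frac_cis = 0.2, frac_trans = 0.1, frac_both = 0, seed = 34)
  ds <- simulate_dataset(cfg)
  par <- dplyr::filter(ds$counts, sample %in% c("parent_B", "parent_S"))
  mock <- build_mock_f1(par, assignability = 0.6, seed = 7)
  keep <- coverage_filter(mock, 100)  # depth >= 100 regime
  pp <- psi_posterior(dplyr::summarise(
    dplyr::group_by(dplyr::filter(par, event_id %in% keep), event_id, sample),
    n_inclusion = sum(n_inclusion), n_exclusion = sum(n_exclusion),
    .groups = "drop"))
  mp <- psi_posterior(dplyr::summarise(
    dplyr::group_by(dplyr::filter(mock, event_id %in% keep), event_id, allele),
    n_inclusion = sum(n_inclusion), n_exclusion = sum(n_exclusion),
    .groups = "drop"))
  j <- dplyr::inner_join(
    dplyr::mutate(pp, allele = ifelse(sample == "parent_B", "B", "S")),
    mp, by = c("event_id", "allele"), suffix = c("_par", "_mock"))
  expect_gte(cor(j$psi_mean_par, j$psi_mean_mock)^2, 0.95)
})
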