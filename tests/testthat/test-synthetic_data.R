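test_that("generator output is deterministic in the seed", {
  s1 <- tiny_sim(21L)
  s2 <- tiny_sim(21L)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  l1 <- simulate_libraries(s1, d1)
  l2 <- simulate_libraries(s2, d2)
  for (i in seq_len(nrow(l1$samples))) {
    expect_identical(readLines(l1$samples$fastq[i]),
                     readLines(l2$samples$fastq[i]))
  }
  s3 <- tiny_sim(22L)
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("planted hairpins honor their ground-truth geometry", {
  sim <- tiny_sim(23L)
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    # mature and star both lie inside the precursor window
    expect_true(grepl(tr$mature_seq[i], tr$prec_seq[i], fixed = TRUE))
    expect_true(grepl(tr$star_seq[i], tr$prec_seq[i], fixed = TRUE))
    # the genome carries the precursor at the stated interval and strand
    expect_equal(extract_window(sim$genome, tr$chrom[i], tr$prec_start[i],
                                tr$prec_end[i], tr$strand[i]),
                 tr$prec_seq[i])
    expect_gte(tr$expected_tpm_control[i], 0)
  }
  # a zero-mismatch locus is completely complementary: siRNA-like fixture
  z <- tr[tr$n_mismatch == 0, ]
  if (nrow(z)) {
    ev <- evaluate_duplex(fold_hairpin(z$prec_seq[1]),
                          z$mature_off5[1], z$mature_off3[1])
    expect_equal(ev$duplex_mismatches, 0L)
    expect_true(ev$all_wc)
  }
  # location classes are consistent with the emitted features
  gr <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$mature_start,
                                                          tr$mature_end))
  expect_equal(classify_location(gr, sim$features), tr$location_class)
})

test_that("overfull genomes are rejected", {
  cfg <- sim_config(seed = 1, genome_length = 2000L, n_hairpin_loci = 40L,
                    n_genes = 0L)
  expect_error(build_genome(cfg), "cannot place")
  expect_error(sim_config(contaminant_fraction = 0.5,
                          degradation_fraction = 0.5), "sum to < 1")
  expect_error(sim_config(knockout_effect = c(L01 = 0)), "> 0")
})

test_that("count simulation follows the negative-binomial knockout model", {
  set.seed(30)
  m <- simulate_locus_counts(rep(1000, 400), rep(0.09, 400), 3L, 0.1)
  expect_equal(dim(m), c(400L, 6L))
  # mutant mean ~ baseline x effect = 90
  expect_equal(mean(m[, 4:6]), 90, tolerance = 0.05)
  expect_equal(mean(m[, 1:3]), 1000, tolerance = 0.05)
  # overdispersion: variance well above Poisson
  expect_gt(var(as.vector(m[, 1])), 2 * 1000)

  # null model: groups exchangeable in distribution
  m0 <- simulate_locus_counts(rep(500, 400), 1, 3L, 0.1)
  expect_equal(mean(m0[, 4:6]) / mean(m0[, 1:3]), 1, tolerance = 0.1)
})

test_that("contaminant_fraction 0 yields no contaminant-tier reads", {
  cfg <- sim_config(seed = 31, genome_length = 30000L, n_hairpin_loci = 4L,
                    n_genes = 2L, read_count_per_library = 1500L,
                    contaminant_fraction = 0, replicates_per_group = 2L)
  sim <- build_genome(cfg)
  d <- withr::local_tempdir()
  libs <- simulate_libraries(sim, d)
  rd <- read_fastq(libs$samples$fastq[1])
  cl <- clean_reads(rd$seq, rd$qual, cfg$adapter3, cfg$adapter5)
  tags <- collapse_tags(setNames(list(cl$insert[!is.na(cl$insert)]), "A"))
  m <- match_reference(tags$seq, sim$contaminants, 0L)
  expect_true(all(is.na(m)))
})
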