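test_that("reference matching honors the mismatch budget (brute-force oracle)", {
  set.seed(5)
  refs <- Biostrings::DNAStringSet(c(rRNA_1 = random_seq(120),
                                     tRNA_1 = random_seq(80)))
  inside <- substr(as.character(refs[[1]]), 31, 51)  # exact 21-mer
  expect_equal(match_reference(inside, refs, 0L), "rRNA_1")

  off1 <- inside
  substr(off1, 8, 8) <- if (substr(off1, 8, 8) == "A") "C" else "A"
  expect_true(is.na(match_reference(off1, refs, 0L)))
  expect_equal(match_reference(off1, refs, 2L), "rRNA_1")

  # randomized agreement with the brute-force Hamming scan
  for (i in 1:40) {
    tag <- if (i %% 2 == 0) {
      s <- substr(as.character(refs[[sample(1:2, 1)]]), 11, 30)
      for (k in sample(1:20, sample(0:3, 1))) {
        substr(s, k, k) <- sample(c("A", "C", "G", "T"), 1)
      }
      s
    } else random_seq(20)
    mm <- sample(0:2, 1)
    expect_equal(match_reference(tag, refs, mm),
                 oracle_match(tag, as.character(refs), mm), label = tag)
  }
  expect_true(is.na(match_reference(inside, Biostrings::DNAStringSet(), 0L)))
})

test_that("genome mapping agrees with a naive offset scan on both strands", {
  set.seed(6)
  gseq <- random_seq(3000)
  tag <- substr(gseq, 1001, 1021)
  g <- Biostrings::DNAStringSet(c(chr1 = gseq))
  hits <- map_to_genome(tag, g)
  expect_equal(GenomicRanges::start(hits), 1001L)
  expect_equal(as.character(GenomicRanges::strand(hits)), "+")

  rc_tag <- reverse_complement(substr(gseq, 2001, 2022))
  hits <- map_to_genome(rc_tag, g)
  expect_equal(GenomicRanges::start(hits), 2001L)
  expect_equal(as.character(GenomicRanges::strand(hits)), "-")

  expect_length(map_to_genome(strrep("ACGT", 5), g), 0L)

  # oracle equivalence over random and planted tags
  for (i in 1:15) {
    tag <- if (i <= 8) {
      s <- sample(1:2970, 1)
      t0 <- substr(gseq, s, s + 19)
      if (i %% 2 == 0) reverse_complement(t0) else t0
    } else random_seq(20)
    got <- map_to_genome(tag, g)
    want <- oracle_map(tag, gseq)
    expect_equal(length(got), length(want), label = tag)
    if (length(want)) {
      w <- do.call(rbind, want)
      ord <- order(as.integer(w[, 1]), w[, 3])
      got <- got[order(GenomicRanges::start(got),
                       as.character(GenomicRanges::strand(got)))]
      expect_equal(GenomicRanges::start(got), as.integer(w[ord, 1]))
      expect_equal(as.character(GenomicRanges::strand(got)), w[ord, 3])
    }
  }
})

test_that("location classification uses the declared priority", {
  feats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 201, 301, 351), c(200, 300, 400, 380)),
    strand = "+",
    kind = c("exon", "intron", "exon", "three_prime_UTR"))
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(150, 250, 500, 195, 360), c(170, 270, 520, 205, 370)))
  got <- classify_location(iv, feats)
  expect_equal(got, c("exon", "intron", "intergenic", "exon", "exon"))

  # exon/intron junction: forced by priority; cross-check against an
  # enumeration of all overlapping kinds
  junction <- GenomicRanges::GRanges("chr1", IRanges::IRanges(195, 205))
  all_kinds <- unique(feats$kind[IRanges::overlapsAny(
    IRanges::ranges(feats), IRanges::ranges(junction))])
  expect_true(all(c("exon", "intron") %in% all_kinds))
  pri <- c("exon", "three_prime_UTR", "intron")
  expect_equal(classify_location(junction, feats),
               pri[min(match(all_kinds, pri))])
})

test_that("annotation cascade partitions tags with contaminant dominance", {
  set.seed(8)
  gseq <- random_seq(5000)
  cont_seq <- substr(gseq, 101, 160)  # present in contaminants AND genome
  contaminants <- Biostrings::DNAStringSet(c(rRNA = cont_seq,
                                             tRNA = random_seq(70)))
  known <- Biostrings::DNAStringSet(c(miR1 = substr(gseq, 1001, 1021)))
  g <- Biostrings::DNAStringSet(c(chr1 = gseq))
  feats <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2001, 2400),
                                  strand = "+", kind = "exon")
  tags <- data.frame(
    seq = c(substr(cont_seq, 11, 31),      # contaminant (also genomic)
            substr(gseq, 1001, 1021),      # known miRNA
            substr(gseq, 2101, 2122),      # degradation-ish exon fragment
            strrep("TGCA", 6)),            # unmapped (absent by construction)
    total = c(5L, 9L, 3L, 2L))
  tags <- tags[!duplicated(tags$seq), ]
  ann <- annotate_tags(tags, contaminants, known, g, feats)
  a <- ann$annotation
  expect_equal(a$tier[1], "contaminant")      # cascade dominance
  expect_equal(a$tier[2], "known_miRNA")
  expect_equal(a$tier[3], "genome_mapped")
  expect_equal(a$tier[4], "unmapped")
  expect_equal(sort(table(a$tier))[["contaminant"]], 1L)
  expect_equal(sum(table(a$tier)), nrow(tags))  # partition
  expect_true(all(!is.na(a$matched_id[a$tier %in% c("contaminant", "known_miRNA")])))
  # the exon fragment is flagged degradation-like when not called
  fl <- flag_degradation(ann, called_tags = character())
  expect_true(fl$degradation_like[3])
  expect_false(any(fl$degradation_like[-3]))
})
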