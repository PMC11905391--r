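test_that("maximum-pair folding matches exhaustive enumeration on the worked example", {
  # 10-mer stem-loop: expected structure derived by enumerating every
  # non-crossing structure
  f <- srnamir:::fold_any("GGGAAAACCC", 3L)
  expect_equal(f$score, oracle_max_pairs("GGGAAAACCC"))
  expect_equal(f$score, 3)
  expect_equal(f$structure, "(((....)))")
  expect_equal(srnamir:::fold_any("AAAAAAAAAA")$score, 0)
})

test_that("fold output is a balanced, non-crossing pairing with legal loops", {
  set.seed(9)
  for (i in 1:60) {
    s <- random_seq(sample(10:80, 1))
    f <- srnamir:::fold_any(s)
    p <- f$pairs
    idx <- which(p > 0)
    # symmetry
    expect_true(all(p[p[idx]] == idx))
    # loop size
    expect_true(all(abs(p[idx] - idx) > 3L))
    # non-crossing
    op <- which(p > seq_along(p))
    if (length(op) > 1) {
      for (a in op) for (b in op) {
        if (a < b) expect_false(a < b & b < p[a] & p[a] < p[b])
      }
    }
    # dot-bracket is balanced
    ch <- strsplit(f$structure, "")[[1]]
    expect_equal(sum(ch == "("), sum(ch == ")"))
    depth <- cumsum((ch == "(") - (ch == ")"))
    expect_true(all(depth >= 0))
  }
})

test_that("fold pair counts equal enumeration for a random corpus (n <= 14)", {
  set.seed(10)
  for (i in 1:120) {
    s <- random_seq(sample(6:14, 1))
    expect_equal(srnamir:::fold_any(s)$score, oracle_max_pairs(s), label = s)
  }
})

test_that("fold_hairpin enforces the precursor length contract", {
  expect_error(fold_hairpin("GGGAAAACCC"), "40-400")
  expect_error(fold_hairpin(random_seq(500)), "40-400")
  f <- fold_hairpin(paste0(strrep("G", 20), strrep("A", 8), strrep("C", 20)))
  expect_equal(f$score, 20)
  expect_equal(f$score_per_base, 20 / 48)
})

test_that("candidate windows bracket the tag on either arm and clip at ends", {
  set.seed(11)
  g <- Biostrings::DNAStringSet(c(chr1 = random_seq(3000)))
  w <- extract_candidate_windows("chr1", 1000, 1020, "+", g, flank = 100)
  expect_equal(w$win_start, c(980, 900))
  expect_equal(w$win_end, c(1120, 1040))
  expect_equal(substr(w$seq[1], w$tag_off5[1], w$tag_off3[1]),
               extract_window(g, "chr1", 1000, 1020, "+"))
  # clipping near the chromosome start
  w2 <- extract_candidate_windows("chr1", 10, 30, "+", g, flank = 100)
  expect_equal(w2$win_start, c(1, 1))
  # minus-strand windows carry the reverse complement with correct offsets
  w3 <- extract_candidate_windows("chr1", 1000, 1020, "-", g, flank = 100)
  expect_equal(substr(w3$seq[1], w3$tag_off5[1], w3$tag_off3[1]),
               extract_window(g, "chr1", 1000, 1020, "-"))
})

test_that("duplex evaluation recovers the planted star with DCL overhang geometry", {
  set.seed(12)
  hp <- srnamir:::make_hairpin("TTGCATGCAACGATCGGATCA", "5p", 0L)
  f <- fold_hairpin(hp$precursor)
  ev <- evaluate_duplex(f, hp$mature_start, hp$mature_end)
  expect_true(ev$ok)
  expect_equal(ev$duplex_mismatches, 0L)
  expect_equal(ev$duplex_bulges, 0L)
  expect_equal(ev$pairing_fraction, 1)
  expect_true(ev$clean_cut)
  expect_true(ev$all_wc)
  expect_equal(ev$star_start, hp$star_start)
  expect_equal(ev$star_end, hp$star_end)
})

test_that("planted stem mismatches are counted as duplex mismatches", {
  # small hairpin so the optimal fold can be enumerated independently
  mat <- "GGCAGC"
  stem <- paste0("AA", mat, "AAAA", "GCAGCC", "AA")
  substr(stem, 15, 15) <- "A"  # break the pairing of one mature base
  f <- srnamir:::fold_any(stem)
  expect_equal(f$score, oracle_max_pairs(stem))
  ev <- evaluate_duplex(f, 3L, 8L)
  expect_true(ev$ok)
  expect_equal(ev$duplex_mismatches, 6L - sum(f$pairs[3:8] > 0))

  # cumulative mismatches planted into one fixed hairpin; the mature is
  # A/C-only so the substituted star bases cannot pair any mature base and
  # the unpaired count is exact (no register-shift rescue)
  set.seed(13)
  mature <- paste(sample(c("A", "C"), 21, TRUE), collapse = "")
  hp <- srnamir:::make_hairpin(mature, "5p", 0L)
  arm_ms <- hp$mature_start - 5L   # arm index of the mature start (pad 5)
  mut_at <- arm_ms + c(2L, 8L, 14L)  # spaced mature positions
  prec <- hp$precursor
  for (k in 0:3) {
    if (k > 0) {
      a <- mut_at[k]
      star_pos <- 5L + 40L + 12L + (40L - a + 1L)
      b <- substr(prec, 5L + a, 5L + a)
      repl <- if (b == "A") "C" else "A"  # pairs neither A nor C
      substr(prec, star_pos, star_pos) <- repl
    }
    ev <- evaluate_duplex(fold_hairpin(prec), hp$mature_start, hp$mature_end)
    expect_true(ev$ok)
    expect_equal(ev$duplex_mismatches, k)
  }
})

test_that("more planted mismatches never increase the pairing fraction", {
  set.seed(14)
  for (rep in 1:5) {
    mature <- paste(sample(c("A", "C"), 21, TRUE), collapse = "")
    hp <- srnamir:::make_hairpin(mature, "5p", 0L)
    arm_ms <- hp$mature_start - 5L
    prec <- hp$precursor
    pf <- numeric(4)
    for (k in 0:3) {
      if (k > 0) {
        a <- arm_ms + 2L * k
        star_pos <- 5L + 40L + 12L + (40L - a + 1L)
        b <- substr(prec, 5L + a, 5L + a)
        substr(prec, star_pos, star_pos) <- if (b == "A") "C" else "A"
      }
      pf[k + 1] <- evaluate_duplex(fold_hairpin(prec), hp$mature_start,
                                   hp$mature_end)$pairing_fraction
    }
    expect_true(all(diff(pf) <= 1e-9))
  }
})

test_that("a mature spanning the loop is rejected", {
  prec <- paste0(strrep("G", 25), strrep("A", 6), strrep("C", 25))
  f <- fold_hairpin(prec)
  ev <- evaluate_duplex(f, 20L, 36L)  # crosses the terminal loop
  expect_false(ev$ok)
})

test_that("novel calling finds a planted locus and rejects its shuffled twin", {
  set.seed(15)
  sim <- tiny_sim(15L)
  tr <- sim$truth[!sim$truth$known &
                    sim$truth$location_class %in% c("intergenic", "intron"), ][1, ]
  tags <- data.frame(seq = tr$mature_seq, A = 10L, total = 10L)
  ann <- annotate_tags(tags, genome = sim$genome, features = sim$features)
  rec <- call_novel_mirnas(ann, tags, sim$genome, sim$features)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$mature_seq, tr$mature_seq)
  expect_true(rec$prec_start <= tr$prec_end && rec$prec_end >= tr$prec_start)
  expect_equal(rec$name, "novel-miR01")

  # same mature in a dinucleotide-shuffled precursor context: stem destroyed
  shuf <- dinuc_shuffle(tr$prec_seq)
  g2seq <- paste0(random_seq(400), shuf, random_seq(400))
  pos <- regexpr(tr$mature_seq, g2seq, fixed = TRUE)
  if (pos < 0) {
    # mature itself was shuffled away; plant it into the shuffled background
    g2seq <- paste0(random_seq(400), tr$mature_seq, shuf, random_seq(400))
  }
  g2 <- Biostrings::DNAStringSet(c(chr1 = g2seq))
  ann2 <- annotate_tags(tags, genome = g2)
  rec2 <- call_novel_mirnas(ann2, tags, g2)
  expect_equal(nrow(rec2), 0L)

  # fold score drops on the shuffled precursor
  expect_lt(srnamir:::fold_any(shuf)$score_per_base / 1,
            fold_hairpin(tr$prec_seq)$score_per_base + 1e-9)

  # a tag below the count threshold is never called
  tags_low <- data.frame(seq = tr$mature_seq, A = 1L, total = 1L)
  ann3 <- annotate_tags(tags_low, genome = sim$genome, features = sim$features)
  expect_equal(nrow(call_novel_mirnas(ann3, tags_low, sim$genome, sim$features)), 0L)
})

test_that("re-classification follows the three stem-loop group rules", {
  set.seed(16)
  bg <- random_seq(1500)
  perfect <- srnamir:::make_hairpin("TTGAGCCGTGCCAATCAGAGC", "5p", 0L)
  broken <- srnamir:::make_hairpin("TAGACCGGTTCACTGCAAGCT", "3p", 3L)
  gseq <- paste0(bg, perfect$precursor, random_seq(300), broken$precursor,
                 random_seq(200))
  g <- Biostrings::DNAStringSet(c(chr1 = gseq))

  # rule 3: mature absent from the genome
  r1 <- reclassify_reported_mirna("TTTTTGGGGGCCCCCAAAAA", NULL, g)
  expect_equal(r1$group, "I")

  # rule 4: perfect Watson-Crick stem -> siRNA-like
  r3 <- reclassify_reported_mirna("TTGAGCCGTGCCAATCAGAGC", NULL, g)
  expect_equal(r3$group, "III")
  expect_equal(r3$record$duplex_mismatches, 0L)

  # rule 5: imperfect stem -> miRNA candidate
  r2 <- reclassify_reported_mirna("TAGACCGGTTCACTGCAAGCT", NULL, g)
  expect_equal(r2$group, "II")
  expect_gt(r2$record$duplex_mismatches, 0L)

  # rule 1: a recorded precursor that still maps leaves the record unchanged
  r0 <- reclassify_reported_mirna("TTGAGCCGTGCCAATCAGAGC",
                                  perfect$precursor, g)
  expect_true(is.na(r0$group))

  # groups are mutually exclusive and exhaustive over these fixtures
  expect_equal(sort(c(r1$group, r2$group, r3$group)), c("I", "II", "III"))

  expect_error(reclassify_reported_mirna("ACGT", NULL, g), "18-24")
})
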