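A3 <- "TGGAATTCTCGGGTGCCAAGG"
A5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

hiq <- function(n) strrep("I", n)                       # Phred 40
mk_read <- function(insert, pad = "GTCAGTACGTCCAGTTCGAA") {
  substr(paste0(insert, A3, pad), 1L, 50L)
}

test_that("an intact insert passes every filter and is trimmed back", {
  ins <- "TACGATTGCAGCATTGCAGCA"  # 21 nt
  r <- clean_read(mk_read(ins), hiq(50), A3, A5)
  expect_equal(r$insert, ins)
  expect_true(is.na(r$reason))
})

test_that("each defect class is rejected with its own reason, in order", {
  ins <- "TACGATTGCAGCATTGCAGCA"
  ok <- mk_read(ins)
  loq <- intToUtf8(rep(43L, 50L))  # Phred 10 throughout
  cases <- list(
    low_quality = list(seq = ok, qual = loq),
    contains_N = list(seq = sub("T", "N", ok), qual = hiq(50)),
    no_3p_adapter = list(seq = paste0(ins, strrep("GTCA", 8)), qual = hiq(53)),
    has_5p_adapter = list(
      seq = substr(paste0(substr(A5, 19, 26), ins, A3, "G"), 1, 50),
      qual = hiq(50)),
    short = list(seq = mk_read(substr(ins, 1, 17)), qual = hiq(50)),
    polyA = list(seq = mk_read(strrep("A", 20)), qual = hiq(50)),
    long = list(seq = mk_read(strrep("TCGA", 8)),  # 32 nt insert
                qual = hiq(50))
  )
  for (nm in names(cases)) {
    r <- clean_read(cases[[nm]]$seq, cases[[nm]]$qual, A3, A5)
    expect_equal(r$reason, nm, label = paste("reason for", nm))
    expect_true(is.na(r$insert))
  }
  # empty read rejects as short
  expect_equal(clean_read("", "", A3, A5)$reason, "short")
})

test_that("polyA rule fires on both the A-fraction and the A-run clause", {
  # 20 nt insert, 85% A but no 10-run
  frac <- "AAAAAAAAGAAAAAAAAGAA"
  expect_equal(clean_read(mk_read(frac), hiq(50), A3, A5)$reason, "polyA")
  # long A run inside an otherwise mixed insert
  run <- "TCGAAAAAAAAAAAGCGTAC"
  expect_equal(clean_read(mk_read(run), hiq(50), A3, A5)$reason, "polyA")
})

test_that("cleaning an already-clean insert rejects it (idempotence guard)", {
  ins <- "TACGATTGCAGCATTGCAGCA"
  r <- clean_read(ins, hiq(nchar(ins)), A3, A5)
  expect_equal(r$reason, "no_3p_adapter")
})

test_that("tag collapsing counts per library and ignores read order", {
  ins <- c("TACGATTGCAGCATTGCAGCA", "GGCATCGATCGTACGATCGAT")
  tags <- collapse_tags(list(A = c(ins[1], ins[1], ins[2]), B = ins[2]))
  expect_equal(nrow(tags), 2L)
  expect_equal(tags$A[tags$seq == ins[1]], 2L)
  expect_equal(tags$B[tags$seq == ins[2]], 1L)
  expect_equal(tags$A[tags$seq == ins[2]], 1L)

  set.seed(3)
  reads <- sample(rep(c(ins, random_seq(20)), times = c(5, 3, 2)))
  t1 <- collapse_tags(list(A = reads))
  t2 <- collapse_tags(list(A = rev(reads)))
  expect_identical(t1, t2)

  expect_equal(nrow(collapse_tags(list(A = character()))), 0L)
  expect_error(collapse_tags(list(Z = ins), libraries = c("A", "B")),
               "not in sample sheet")
})

test_that("cleaning conserves reads: tallies plus survivors equal input", {
  set.seed(4)
  n <- 400L
  seqs <- vapply(seq_len(n), function(i) mk_read(random_seq(21)), "")
  # corrupt a susbset with assorted defects
  seqs[1:40] <- vapply(1:40, function(i) random_seq(50), "")
  seqs[41:60] <- sub("G", "N", seqs[41:60])
  quals <- rep(hiq(50), n)
  quals[61:80] <- intToUtf8(rep(40L, 50L))  # Phred 7
  cl <- clean_reads(seqs, quals, A3, A5)
  rep_df <- cleaning_report(list(L = cl$reason))
  tallies <- sum(unlist(rep_df[grep("removed_", names(rep_df))]))
  expect_equal(tallies + rep_df$surviving, rep_df$input_reads)
  expect_equal(rep_df$surviving, sum(!is.na(cl$insert)))
})

test_that("length distribution is count-weighted and normalized", {
  tags <- data.frame(seq = c(strrep("A", 21), strrep("C", 24)),
                     A = c(10L, 0L), B = c(3L, 7L), total = c(13L, 7L))
  ld <- length_distribution(tags, c("A", "B"))
  expect_equal(ld$A[ld$length == 21], 1.0)
  expect_equal(ld$B[ld$length == 21], 0.3)
  expect_equal(colSums(ld[, c("A", "B")]), c(A = 1, B = 1))
  expect_error(length_distribution(tags[0, ]), "empty")
})
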