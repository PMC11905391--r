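#' Fold a candidate precursor by base-pair maximization
#'
#' Nussinov-style maximum base-pair folding with canonical pairs
#' (A.U, G.C and the G.U wobble, on the internal DNA alphabet) and hairpin
#' loops of at least `min_loop` unpaired bases. Traceback is deterministic:
#' ties are broken in favor of the pairing that closes at the smaller 5'
#' index. The pair count serves as the free-energy proxy (`score`), also
#' reported per base.
#'
#' @param seq Precursor sequence, 40-400 nt.
#' @param min_loop Minimum hairpin-loop size in unpaired bases.
#' @return A list of class `fold_result`: `seq`, `structure` (dot-bracket),
#'   `pairs` (1-based partner index per position, 0 = unpaired), `score`
#'   (number of base pairs) and `score_per_base`.
#' @export
fold_hairpin <- function(seq, min_loop = 3L) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  n <- nchar(seq)
  if (n < 40L || n > 400L) {
    stop("precursor length ", n, " outside the supported 40-400 nt range")
  }
  pairs <- nussinov_pairs(seq, as.integer(min_loop))
  structure(list(seq = seq,
                 structure = pairs_to_dotbracket(pairs),
                 pairs = pairs,
                 score = sum(pairs > 0L) / 2L,
                 score_per_base = sum(pairs > 0L) / 2L / n),
            class = "fold_result")
}

# Internal: unrestricted-length folding for tests and short stems.
fold_any <- function(seq, min_loop = 3L) {
  seq <- toupper(chartr("Uu", "Tt", seq))
  pairs <- nussinov_pairs(seq, as.integer(min_loop))
  structure(list(seq = seq, structure = pairs_to_dotbracket(pairs),
                 pairs = pairs, score = sum(pairs > 0L) / 2L,
                 score_per_base = sum(pairs > 0L) / 2L / max(nchar(seq), 1L)),
            class = "fold_result")
}

pairs_to_dotbracket <- function(pairs) {
  ch <- rep(".", length(pairs))
  ch[pairs > seq_along(pairs)] <- "("
  ch[pairs > 0L & pairs < seq_along(pairs)] <- ")"
  paste(ch, collapse = "")
}

#' Extract precursor candidate windows around a genomic hit
#'
#' For one tag hit, returns the two windows that position the tag on the 5'
#' arm and on the 3' arm of a putative hairpin: flanking sequence is taken
#' mostly downstream of the tag for the 5'-arm window and mostly upstream
#' for the 3'-arm window (in transcript orientation), clipped at chromosome
#' ends. Window sequences are strand-oriented (reverse-complemented for `-`
#' hits) and carry the tag's offsets inside the window.
#'
#' @param chrom,start,end,strand Genomic hit of the tag (1-based inclusive).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param flank Flanking bases on the far side of the putative loop.
#' @param near Flanking bases on the tag's outer side.
#' @return A `data.frame` with one row per window: `arm`, `win_start`,
#'   `win_end`, `seq`, `tag_off5`, `tag_off3`.
#' @export
extract_candidate_windows <- function(chrom, start, end, strand, genome,
                                      flank = 180L, near = 20L) {
  L <- setNames(Biostrings::width(genome), names(genome))[[chrom]]
  mk <- function(arm) {
    if ((arm == "5p") == (strand == "+")) {
      ws <- max(1L, start - near); we <- min(L, end + flank)
    } else {
      ws <- max(1L, start - flank); we <- min(L, end + near)
    }
    s <- extract_window(genome, chrom, ws, we, strand)
    if (strand == "+") {
      off5 <- start - ws + 1L
    } else {
      off5 <- we - end + 1L
    }
    data.frame(arm = arm, win_start = ws, win_end = we, seq = s,
               tag_off5 = off5, tag_off3 = off5 + (end - start),
               stringsAsFactors = FALSE)
  }
  rbind(mk("5p"), mk("3p"))
}

#' Evaluate the miRNA/miRNA* duplex of a folded candidate
#'
#' Given a folded window and the mature's offsets inside it, locates the
#' star segment as the positions pairing with the mature extended by the
#' 2-nt 3' overhang of the Dicer/DCL cut, and reports duplex metrics:
#' mismatches (mature bases left unpaired), bulges (asymmetric unpaired
#' stretches on the star side), the fraction of mature bases paired, and
#' whether both mature ends are paired (a clean DCL cut with the canonical
#' overhang geometry). A mature that pairs with itself (spanning the
#' terminal loop) or pairs on both sides is rejected.
#'
#' @param fold A [fold_hairpin()] result.
#' @param mature_start,mature_end 1-based offsets of the mature in
#'   `fold$seq`.
#' @param wc_only Count only Watson-Crick pairs as matched (G.U treated as a
#'   mismatch); used for the siRNA-like perfect-complement test.
#' @return A list: `ok`, `reason`, `star_start`, `star_end`,
#'   `duplex_mismatches`, `duplex_bulges`, `pairing_fraction`, `clean_cut`,
#'   `all_wc`.
#' @export
evaluate_duplex <- function(fold, mature_start, mature_end, wc_only = FALSE) {
  n <- nchar(fold$seq)
  stopifnot(mature_start >= 1L, mature_end <= n, mature_start < mature_end)
  idx <- mature_start:mature_end
  p <- fold$pairs[idx]
  fail <- function(reason) list(ok = FALSE, reason = reason,
                                star_start = NA_integer_, star_end = NA_integer_,
                                duplex_mismatches = NA_integer_,
                                duplex_bulges = NA_integer_,
                                pairing_fraction = 0, clean_cut = FALSE,
                                all_wc = FALSE)
  paired <- which(p > 0L)
  if (length(paired) == 0L) return(fail("unpaired"))
  partners <- p[paired]
  if (any(partners >= mature_start & partners <= mature_end)) {
    return(fail("mature_overlaps_loop"))
  }
  if (any(partners > mature_end) && any(partners < mature_start)) {
    return(fail("mature_pairs_both_sides"))
  }
  bases <- strsplit(fold$seq, "")[[1]]
  wc <- vapply(paired, function(k) {
    a <- bases[idx[k]]; b <- bases[p[k]]
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")
  }, TRUE)
  eff_paired <- if (wc_only) paired[wc] else paired
  mlen <- length(idx)
  mism <- mlen - length(eff_paired)
  star_lo <- min(partners); star_hi <- max(partners)
  star_start <- star_lo
  star_end <- min(star_hi + 2L, n)
  # bulges: between consecutive paired mature positions, unpaired star bases
  # in excess of the unpaired mature bases form an asymmetric stretch
  # (a symmetric internal loop is counted through the mismatches instead)
  bulges <- 0L
  if (length(paired) >= 2L) {
    for (k in seq_len(length(paired) - 1L)) {
      gap_m <- paired[k + 1L] - paired[k] - 1L
      gap_s <- abs(p[paired[k + 1L]] - p[paired[k]]) - 1L
      if (gap_s > gap_m) bulges <- bulges + 1L
    }
  }
  list(ok = TRUE, reason = NA_character_,
       star_start = star_start, star_end = star_end,
       duplex_mismatches = as.integer(mism),
       duplex_bulges = bulges,
       pairing_fraction = length(eff_paired) / mlen,
       clean_cut = p[1L] > 0L && p[mlen] > 0L,
       all_wc = all(wc))
}

#' Discovery parameters
#'
#' Thresholds of the novel-miRNA caller. A candidate window passes only if
#' the duplex has at most `max_mismatches` unpaired mature bases and
#' `max_bulges` asymmetric star bulges, at least `min_pairing_fraction` of
#' the mature paired, a fold score of at least `min_score_per_base`
#' pairs/nt over the window, mature length within `mature_len`, and a total
#' tag count of at least `min_count`. Candidates lacking the clean 2-nt
#' 3'-overhang cut geometry are kept but outranked when overlapping windows
#' are collapsed.
#'
#' @param max_mismatches,max_bulges,min_pairing_fraction,min_score_per_base
#'   Duplex and fold thresholds.
#' @param mature_len Length-2 integer window of allowed mature lengths (nt).
#' @param min_count Minimum total tag count across libraries.
#' @param flank Precursor window flank in nt (reflecting observed precursor
#'   spans of roughly 90-370 nt).
#' @param max_hits Maximum genomic hits for a novel candidate tag.
#' @param min_loop Minimum hairpin loop length for folding.
#' @param wc_only_for_sirna Require pure Watson-Crick complementarity for
#'   the siRNA-like (group III) perfect-duplex call.
#' @return A list of class `discovery_params`.
#' @export
discovery_params <- function(max_mismatches = 4L, max_bulges = 2L,
                             min_pairing_fraction = 0.6,
                             min_score_per_base = 0.25,
                             mature_len = c(18L, 24L),
                             min_count = 3L, flank = 180L, max_hits = 10L,
                             min_loop = 3L, wc_only_for_sirna = TRUE) {
  p <- list(max_mismatches = as.integer(max_mismatches),
            max_bulges = as.integer(max_bulges),
            min_pairing_fraction = min_pairing_fraction,
            min_score_per_base = min_score_per_base,
            mature_len = as.integer(mature_len),
            min_count = as.integer(min_count), flank = as.integer(flank),
            max_hits = as.integer(max_hits), min_loop = as.integer(min_loop),
            wc_only_for_sirna = isTRUE(wc_only_for_sirna))
  stopifnot(p$flank > 0, p$min_count >= 1, length(p$mature_len) == 2L)
  class(p) <- "discovery_params"
  p
}

# Evaluate all candidate windows for one genomic hit of one tag; returns the
# passing candidates as data.frame rows (possibly none).
evaluate_hit <- function(tag, chrom, start, end, strand, genome, params) {
  wins <- extract_candidate_windows(chrom, start, end, strand, genome,
                                    flank = params$flank)
  rows <- list()
  for (k in seq_len(nrow(wins))) {
    w <- wins[k, ]
    if (nchar(w$seq) < 40L || nchar(w$seq) > 400L) next
    fold <- fold_hairpin(w$seq, params$min_loop)
    ev <- evaluate_duplex(fold, w$tag_off5, w$tag_off3)
    if (!ev$ok) next
    if (ev$duplex_mismatches > params$max_mismatches) next
    if (ev$duplex_bulges > params$max_bulges) next
    if (ev$pairing_fraction < params$min_pairing_fraction) next
    if (fold$score_per_base < params$min_score_per_base) next
    # precursor span: duplex plus a 10-nt margin, in window coordinates
    lo <- max(1L, min(w$tag_off5, ev$star_start) - 10L)
    hi <- min(nchar(w$seq), max(w$tag_off3, ev$star_end) + 10L)
    # back to genomic coordinates
    if (strand == "+") {
      ps <- w$win_start + lo - 1L; pe <- w$win_start + hi - 1L
    } else {
      ps <- w$win_end - hi + 1L; pe <- w$win_end - lo + 1L
    }
    arm <- if (ev$star_start > w$tag_off3) "5p" else "3p"
    rows[[length(rows) + 1L]] <- data.frame(
      tag = tag, chrom = chrom, strand = strand,
      mature_start = start, mature_end = end,
      prec_start = ps, prec_end = pe, arm = arm,
      duplex_mismatches = ev$duplex_mismatches,
      duplex_bulges = ev$duplex_bulges,
      pairing_fraction = ev$pairing_fraction,
      score_per_base = fold$score_per_base,
      clean_cut = ev$clean_cut, all_wc = ev$all_wc,
      stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Call novel miRNAs from annotated tags
#'
#' Runs hairpin evaluation on every genome-mapped, unannotated tag with
#' enough reads: each genomic hit yields 5'-arm and 3'-arm candidate
#' windows, which are folded and duplex-evaluated against the thresholds in
#' `params`. Overlapping passing windows collapse to the best-scoring one
#' (highest total count, then clean-cut duplexes first, then fold score).
#' Calls are named `novel-miRNN` in rank order of total count.
#'
#' @param annot A [annotate_tags()] result.
#' @param tags The tag table the annotation was computed from (count
#'   columns are used for ranking and thresholds).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param features Optional feature [GenomicRanges::GRanges] for location
#'   classes.
#' @param params A [discovery_params()].
#' @return A `data.frame` of miRNA records (`origin = "novel"`), one row per
#'   collapsed locus, with duplex metrics; zero rows when nothing passes.
#' @export
call_novel_mirnas <- function(annot, tags, genome, features = NULL,
                              params = discovery_params()) {
  ann <- annot$annotation
  total <- tags$total[match(ann$seq, tags$seq)]
  use <- ann$tier == "genome_mapped" &
    ann$n_hits >= 1L & ann$n_hits <= params$max_hits &
    !is.na(total) & total >= params$min_count &
    nchar(ann$seq) >= params$mature_len[1] &
    nchar(ann$seq) <= params$mature_len[2]
  cand_seqs <- ann$seq[use]
  empty <- mirna_record_frame()
  if (length(cand_seqs) == 0L || is.null(annot$hits)) return(empty)
  hits <- annot$hits[annot$hits$tag %in% cand_seqs]
  # degradation guard: hits in exon/3'UTR sequence are likely mRNA
  # fragments and never seed novel loci (exonic miRNA loci are reachable
  # through the known-miRNA reference instead)
  if (!is.null(hits$location)) {
    hits <- hits[!(hits$location %in% c("exon", "three_prime_UTR"))]
  }
  if (length(hits) == 0L) return(empty)

  passing <- list()
  hd <- data.frame(tag = hits$tag,
                   chrom = as.character(GenomicRanges::seqnames(hits)),
                   start = GenomicRanges::start(hits),
                   end = GenomicRanges::end(hits),
                   strand = as.character(GenomicRanges::strand(hits)),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(hd))) {
    r <- evaluate_hit(hd$tag[i], hd$chrom[i], hd$start[i], hd$end[i],
                      hd$strand[i], genome, params)
    if (!is.null(r)) passing[[length(passing) + 1L]] <- r
  }
  if (length(passing) == 0L) return(empty)
  cand <- do.call(rbind, passing)
  cand$total <- tags$total[match(cand$tag, tags$seq)]

  # collapse overlapping candidate precursors to the best-scoring one
  gr <- GenomicRanges::GRanges(cand$chrom,
                               IRanges::IRanges(cand$prec_start, cand$prec_end))
  cl <- GenomicRanges::findOverlaps(
    gr, GenomicRanges::reduce(gr, ignore.strand = TRUE),
    ignore.strand = TRUE)
  cand$cluster <- S4Vectors::subjectHits(cl)
  ord <- order(-cand$total, -cand$clean_cut, -cand$score_per_base,
               cand$duplex_mismatches, cand$tag)
  cand <- cand[ord, , drop = FALSE]
  best <- cand[!duplicated(cand$cluster), , drop = FALSE]
  best <- best[order(-best$total, best$tag), , drop = FALSE]

  rec <- data.frame(
    name = sprintf("novel-miR%02d", seq_len(nrow(best))),
    mature_seq = best$tag,
    length = nchar(best$tag),
    arm = best$arm,
    chrom = best$chrom,
    prec_start = best$prec_start, prec_end = best$prec_end,
    mature_start = best$mature_start, mature_end = best$mature_end,
    strand = best$strand,
    origin = "novel",
    stem_loop_group = NA_character_,
    total_count = best$total,
    duplex_mismatches = best$duplex_mismatches,
    duplex_bulges = best$duplex_bulges,
    pairing_fraction = best$pairing_fraction,
    score_per_base = best$score_per_base,
    clean_cut = best$clean_cut,
    stringsAsFactors = FALSE)
  rec$location_class <- if (!is.null(features)) {
    classify_location(GenomicRanges::GRanges(
      rec$chrom, IRanges::IRanges(rec$prec_start, rec$prec_end)), features)
  } else rep("intergenic", nrow(rec))
  rec
}

mirna_record_frame <- function() {
  data.frame(name = character(), mature_seq = character(),
             length = integer(), arm = character(), chrom = character(),
             prec_start = integer(), prec_end = integer(),
             mature_start = integer(), mature_end = integer(),
             strand = character(), origin = character(),
             stem_loop_group = character(), total_count = numeric(),
             duplex_mismatches = integer(), duplex_bulges = integer(),
             pairing_fraction = numeric(), score_per_base = numeric(),
             clean_cut = logical(), location_class = character(),
             stringsAsFactors = FALSE)
}

#' Re-classify a previously reported miRNA by precursor re-prediction
#'
#' Implements the stem-loop class assignment for miRBase-style entries
#' whose recorded precursor no longer matches the genome:
#' \enumerate{
#'   \item if the recorded precursor maps exactly to the genome, the record
#'     is kept unchanged (group `NA`);
#'   \item otherwise the mature is mapped and precursor re-prediction is
#'     attempted at every hit (window extraction, folding, duplex
#'     evaluation);
#'   \item no passing precursor at any hit: group I (non-miRNA);
#'   \item a passing precursor whose mature is completely complementary to
#'     its star over the full mature length (no mismatches, no bulges,
#'     Watson-Crick only by default): group III (siRNA-like);
#'   \item otherwise: group II (miRNA candidate), with the re-predicted
#'     interval, strand and location class.
#' }
#'
#' @param mature Mature sequence (18-24 nt; RNA accepted).
#' @param precursor Recorded precursor sequence, or `NULL` when the entry
#'   has none.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param features Optional feature [GenomicRanges::GRanges].
#' @param params A [discovery_params()].
#' @return A list with `group` (`"I"`, `"II"`, `"III"`, or `NA` when the
#'   recorded precursor still maps) and `record` (a one-row miRNA record
#'   data.frame for groups II/III, else `NULL`).
#' @export
reclassify_reported_mirna <- function(mature, precursor = NULL, genome,
                                      features = NULL,
                                      params = discovery_params()) {
  mature <- toupper(chartr("Uu", "Tt", mature))
  if (nchar(mature) < 18L || nchar(mature) > 24L) {
    stop("mature length outside the 18-24 nt miRNA definition")
  }
  if (!is.null(precursor)) {
    precursor <- toupper(chartr("Uu", "Tt", precursor))
    ph <- map_tags_table(precursor, genome)
    if (nrow(ph) > 0L) {
      return(list(group = NA_character_, record = NULL,
                  reason = "recorded precursor maps to the genome"))
    }
  }
  hits <- map_tags_table(mature, genome)
  if (nrow(hits) == 0L) {
    return(list(group = "I", record = NULL, reason = "mature unmappable"))
  }
  cands <- list()
  for (i in seq_len(nrow(hits))) {
    wins <- extract_candidate_windows(hits$chrom[i], hits$start[i],
                                      hits$end[i], hits$strand[i], genome,
                                      flank = params$flank)
    for (k in seq_len(nrow(wins))) {
      w <- wins[k, ]
      if (nchar(w$seq) < 40L || nchar(w$seq) > 400L) next
      fold <- fold_hairpin(w$seq, params$min_loop)
      ev <- evaluate_duplex(fold, w$tag_off5, w$tag_off3)
      if (!ev$ok) next
      if (ev$duplex_mismatches > params$max_mismatches) next
      if (ev$duplex_bulges > params$max_bulges) next
      if (ev$pairing_fraction < params$min_pairing_fraction) next
      if (fold$score_per_base < params$min_score_per_base) next
      lo <- max(1L, min(w$tag_off5, ev$star_start) - 10L)
      hi <- min(nchar(w$seq), max(w$tag_off3, ev$star_end) + 10L)
      if (hits$strand[i] == "+") {
        ps <- w$win_start + lo - 1L; pe <- w$win_start + hi - 1L
      } else {
        ps <- w$win_end - hi + 1L; pe <- w$win_end - lo + 1L
      }
      perfect <- ev$duplex_mismatches == 0L && ev$duplex_bulges == 0L &&
        ev$pairing_fraction == 1 &&
        (!params$wc_only_for_sirna || ev$all_wc)
      cands[[length(cands) + 1L]] <- data.frame(
        chrom = hits$chrom[i], strand = hits$strand[i],
        mature_start = hits$start[i], mature_end = hits$end[i],
        prec_start = ps, prec_end = pe,
        arm = if (ev$star_start > w$tag_off3) "5p" else "3p",
        duplex_mismatches = ev$duplex_mismatches,
        duplex_bulges = ev$duplex_bulges,
        pairing_fraction = ev$pairing_fraction,
        score_per_base = fold$score_per_base,
        clean_cut = ev$clean_cut, perfect = perfect,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cands) == 0L) {
    return(list(group = "I", record = NULL,
                reason = "no passing precursor at any hit"))
  }
  cand <- do.call(rbind, cands)
  cand <- cand[order(cand$duplex_mismatches, cand$duplex_bulges,
                     -cand$score_per_base), , drop = FALSE]
  top <- cand[1L, , drop = FALSE]
  group <- if (top$perfect) "III" else "II"
  rec <- data.frame(
    name = NA_character_, mature_seq = mature, length = nchar(mature),
    arm = top$arm, chrom = top$chrom,
    prec_start = top$prec_start, prec_end = top$prec_end,
    mature_start = top$mature_start, mature_end = top$mature_end,
    strand = top$strand, origin = "known", stem_loop_group = group,
    total_count = NA_real_,
    duplex_mismatches = top$duplex_mismatches,
    duplex_bulges = top$duplex_bulges,
    pairing_fraction = top$pairing_fraction,
    score_per_base = top$score_per_base, clean_cut = top$clean_cut,
    stringsAsFactors = FALSE)
  rec$location_class <- if (!is.null(features)) {
    classify_location(GenomicRanges::GRanges(
      rec$chrom, IRanges::IRanges(rec$prec_start, rec$prec_end)), features)
  } else "intergenic"
  list(group = group, record = rec, reason = NA_character_)
}
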