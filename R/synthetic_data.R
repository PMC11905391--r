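#' Simulation configuration
#'
#' Parameters of the synthetic small-RNA study: a toy genome with planted
#' stem-loop (hairpin) miRNA loci and gene models, plus two sample groups
#' (control and Dicer-like knockout) of three replicates each. Defaults
#' emulate the design the pipeline targets: 18-30 nt inserts ligated to a
#' 3' adapter, a library size of 200,000 reads, negative-binomial replicate
#' noise, a 10:1 mature:star read ratio, and knockout fold-reductions on a
#' subset of loci spanning the strongly down-regulated regime
#' (log2 fold changes of roughly -4.6 to -2).
#'
#' @param seed Integer RNG seed; all generator output is deterministic in it.
#' @param genome_length Chromosome length in bases.
#' @param n_hairpin_loci Number of planted miRNA hairpin loci.
#' @param n_genes Number of gene models (3 exons, 2 introns, one 3'UTR each).
#' @param adapter3,adapter5 Adapter sequences; the 3' adapter is ligated to
#'   every intact read, and its first 8 bases are masked out of the genome
#'   background so it stays non-genomic.
#' @param read_length Sequencing read length.
#' @param read_count_per_library Reads per simulated library.
#' @param mature_star_ratio Mature reads per star read.
#' @param contaminant_fraction Fraction of reads drawn from the contaminant
#'   ncRNA set (rRNA/tRNA/snoRNA/snRNA stand-ins). Small-RNA libraries are
#'   dominated by such fragments; together with `degradation_fraction` the
#'   default leaves about a third of each library as miRNA/star reads, so
#'   the clean-tag TPM denominator is not hostage to a few dominant miRNA
#'   loci (the published quantifications imply the same minority share).
#' @param degradation_fraction Fraction of reads that are random mRNA (exonic)
#'   fragments.
#' @param defect_fraction Fraction of reads planted as defective, split evenly
#'   over the six cleaning-filter classes (low quality, N, missing 3' adapter,
#'   embedded 5' adapter, short insert, polyA insert).
#' @param knockout_effect Named numeric vector mapping locus ids to the
#'   multiplicative fold-reduction applied in the mutant group (e.g. 0.09 is
#'   a log2 fold change near -3.5). `NULL` assigns the default effect profile
#'   `c(0.04, 0.07, 0.09, 0.12, 0.15, 0.20, 0.25, 0.25)` to eight loci and
#'   1 (no effect) elsewhere.
#' @param replicates_per_group Biological replicates per group.
#' @param dispersion Negative-binomial overdispersion of replicate counts
#'   (variance = mu + dispersion * mu^2).
#' @param jitter_fraction Fraction of mature reads carrying a +/-1 nt ragged
#'   end, mimicking imprecise DCL cleavage.
#' @param n_known Number of loci whose mature sequence is emitted into the
#'   known-miRNA reference (the rest are left for novel discovery).
#' @param five_prime_U_prob Probability that a planted mature starts with U.
#' @param arm_length,loop_length,pad_length Precursor geometry in nt; the
#'   precursor is pad + arm + loop + reverse-complemented arm + pad.
#' @param abundance_log10_range Range of log10 locus abundance weights
#'   (log-uniform), controlling the spread of baseline expression.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_hairpin_loci = 20L,
                       n_genes = 8L,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                       read_length = 50L,
                       read_count_per_library = 200000L,
                       mature_star_ratio = 10,
                       contaminant_fraction = 0.50,
                       degradation_fraction = 0.15,
                       defect_fraction = 0.03,
                       knockout_effect = NULL,
                       replicates_per_group = 3L,
                       dispersion = 0.1,
                       jitter_fraction = 0.1,
                       n_known = 4L,
                       five_prime_U_prob = 0.7,
                       arm_length = 40L,
                       loop_length = 12L,
                       pad_length = 5L,
                       abundance_log10_range = c(-2.5, 1.5)) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              n_hairpin_loci = as.integer(n_hairpin_loci),
              n_genes = as.integer(n_genes),
              adapter3 = toupper(adapter3), adapter5 = toupper(adapter5),
              read_length = as.integer(read_length),
              read_count_per_library = as.integer(read_count_per_library),
              mature_star_ratio = mature_star_ratio,
              contaminant_fraction = contaminant_fraction,
              degradation_fraction = degradation_fraction,
              defect_fraction = defect_fraction,
              knockout_effect = knockout_effect,
              replicates_per_group = as.integer(replicates_per_group),
              dispersion = dispersion,
              jitter_fraction = jitter_fraction,
              n_known = as.integer(n_known),
              five_prime_U_prob = five_prime_U_prob,
              arm_length = as.integer(arm_length),
              loop_length = as.integer(loop_length),
              pad_length = as.integer(pad_length),
              abundance_log10_range = abundance_log10_range)
  stopifnot(cfg$genome_length > 0, cfg$n_hairpin_loci > 0,
            cfg$read_count_per_library > 0, cfg$replicates_per_group >= 2,
            cfg$mature_star_ratio > 0, cfg$dispersion >= 0)
  fr <- cfg$contaminant_fraction + cfg$degradation_fraction + cfg$defect_fraction
  if (fr >= 1) stop("contaminant + degradation + defect fractions must sum to < 1")
  if (!is.null(cfg$knockout_effect) && any(cfg$knockout_effect <= 0)) {
    stop("knockout_effect values must be > 0")
  }
  class(cfg) <- "sim_config"
  cfg
}

DNA_BASES <- c("A", "C", "G", "T")
# pairing partners under WC + G.U wobble, used to plant duplex mismatches
PAIRS_WITH <- list(A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))

random_dna <- function(len, gc = 0.55) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
}

# One planted stem-loop precursor in transcript (5'->3') orientation.
# Returns the precursor string plus 1-based offsets of the mature and star
# segments and the star's 2-nt 3' overhang geometry.
make_hairpin <- function(mature, arm = c("5p", "3p"), n_mismatch = 0L,
                         arm_length = 40L, loop_length = 12L, pad_length = 5L) {
  arm <- match.arg(arm)
  mlen <- nchar(mature)
  if (mlen > arm_length - 4L) stop("mature longer than the stem arm allows")
  La <- arm_length; Lp <- pad_length; Ll <- loop_length
  ms <- sample(3:(La - mlen - 1L), 1L)
  me <- ms + mlen - 1L
  host <- strsplit(random_dna(La), "")[[1]]
  host[ms:me] <- strsplit(mature, "")[[1]]
  other <- rev(vapply(host, function(b) {
    c(A = "T", C = "G", G = "C", T = "A")[[b]]
  }, ""))
  # plant mismatches at positions pairing the mature
  if (n_mismatch > 0L) {
    mm_host_idx <- sort(sample(ms:me, n_mismatch))
    for (a in mm_host_idx) {
      o <- La - a + 1L
      b <- host[a]
      other[o] <- sample(setdiff(DNA_BASES, PAIRS_WITH[[b]]), 1L)
    }
  }
  if (arm == "5p") {
    armA <- paste(host, collapse = ""); armB <- paste(other, collapse = "")
    p_ms <- Lp + ms; p_me <- Lp + me
    star_lo <- Lp + La + Ll + (La - me + 1L)
    star_hi <- Lp + La + Ll + (La - ms + 1L) + 2L
  } else {
    armB <- paste(host, collapse = ""); armA <- paste(other, collapse = "")
    p_ms <- Lp + La + Ll + ms; p_me <- Lp + La + Ll + me
    star_lo <- Lp + (La - me + 1L)
    star_hi <- Lp + (La - ms + 1L) + 2L
  }
  prec <- paste0(random_dna(Lp), armA, random_dna(Ll), armB, random_dna(Lp))
  star_hi <- min(star_hi, nchar(prec))
  list(precursor = prec, mature_start = p_ms, mature_end = p_me,
       star_start = star_lo, star_end = star_hi,
       star_seq = substr(prec, star_lo, star_hi),
       n_mismatch = n_mismatch, arm = arm)
}

# Replace every occurrence of `motif` in `g` outside protected intervals
# with freshly sampled bases.
mask_motif <- function(g, motif, protected) {
  repeat {
    pos <- gregexpr(motif, g, fixed = TRUE)[[1]]
    pos <- pos[pos > 0]
    if (length(protected)) {
      inprot <- vapply(pos, function(p) {
        any(p <= protected$end & (p + nchar(motif) - 1L) >= protected$start)
      }, TRUE)
      pos <- pos[!inprot]
    }
    if (length(pos) == 0L) return(g)
    for (p in pos) {
      substr(g, p, p + nchar(motif) - 1L) <- random_dna(nchar(motif))
    }
  }
}

#' Build a synthetic genome with planted miRNA hairpin loci
#'
#' Generates a random background chromosome, places gene models
#' (exon/intron/3'UTR structure), plants `n_hairpin_loci` stem-loop
#' precursors across location classes (intergenic, intron, exon, 3'UTR,
#' roughly in 10:5:3:2 proportions with an intergenic plurality), builds a
#' contaminant ncRNA reference and a known-miRNA reference, and returns a
#' ground-truth table for parameter-recovery tests. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` (DNAStringSet), `features`
#'   (GRanges with `kind`), `truth` (data.frame), `contaminants`
#'   (DNAStringSet), `known_mature` and `known_precursors` (DNAStringSets)
#'   and `config`.
#' @export
build_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  n <- config$n_hairpin_loci
  prec_len <- 2L * config$arm_length + config$loop_length + 2L * config$pad_length

  g <- random_dna(L)

  ## ---- gene models ----
  ng <- config$n_genes
  utr_len <- 150L
  genes <- vector("list", ng)
  feat_rows <- list()
  if (ng > 0L) {
    slot <- floor(L / (ng + 1L))
    for (i in seq_len(ng)) {
      ex_len <- sample(250:400, 3L, replace = TRUE)
      in_len <- sample(400:600, 2L, replace = TRUE)
      glen <- sum(ex_len) + sum(in_len) + utr_len
      if (glen + 400L > slot) {
        stop("genome too small to place ", ng, " gene models without overlap")
      }
      gs <- (i - 1L) * slot + slot %/% 4L
      strand <- sample(c("+", "-"), 1L)
      cur <- gs
      ex <- matrix(0L, 3L, 2L)
      for (k in 1:3) {
        ex[k, ] <- c(cur, cur + ex_len[k] - 1L)
        cur <- cur + ex_len[k]
        if (k < 3L) cur <- cur + in_len[k]
      }
      utr <- c(cur, cur + utr_len - 1L)
      genes[[i]] <- list(id = sprintf("gene%02d", i), start = gs,
                         end = utr[2], strand = strand, exons = ex,
                         introns = matrix(c(ex[1, 2] + 1L, ex[2, 1] - 1L,
                                            ex[2, 2] + 1L, ex[3, 1] - 1L),
                                          2L, 2L, byrow = TRUE),
                         utr = utr)
    }
  }

  ## ---- assign hairpin loci to location classes ----
  n_intron_slots <- if (ng > 0L) 2L * ng else 0L
  n_exon_slots <- if (ng > 0L) 3L * ng else 0L
  n_utr_slots <- ng
  want <- c(intergenic = 0L, intron = round(0.3 * n),
            exon = round(0.1 * n), three_prime_UTR = round(0.1 * n))
  want["intron"] <- min(want[["intron"]], n_intron_slots)
  want["exon"] <- min(want[["exon"]], n_exon_slots)
  want["three_prime_UTR"] <- min(want[["three_prime_UTR"]], n_utr_slots)
  want["intergenic"] <- n - sum(want[2:4])
  classes <- rep(names(want), times = want)

  gene_iv <- if (ng > 0L) {
    data.frame(start = vapply(genes, function(x) as.numeric(x$start), 0),
               end = vapply(genes, function(x) as.numeric(x$end), 0))
  } else data.frame(start = integer(), end = integer())

  placed <- data.frame(start = integer(), end = integer())
  overlaps_any <- function(s, e, iv, margin = 50L) {
    nrow(iv) > 0L && any(s <= iv$end + margin & e >= iv$start - margin)
  }

  intron_slots <- if (ng > 0L) {
    do.call(rbind, lapply(genes, function(gn) {
      data.frame(start = gn$introns[, 1], end = gn$introns[, 2])
    }))
  } else data.frame()
  exon_slots <- if (ng > 0L) {
    do.call(rbind, lapply(genes, function(gn) {
      data.frame(start = gn$exons[, 1], end = gn$exons[, 2])
    }))
  } else data.frame()
  utr_slots <- if (ng > 0L) {
    do.call(rbind, lapply(genes, function(gn) {
      data.frame(start = gn$utr[1], end = gn$utr[2])
    }))
  } else data.frame()
  slot_used <- list(intron = rep(FALSE, nrow(intron_slots)),
                    exon = rep(FALSE, nrow(exon_slots)),
                    three_prime_UTR = rep(FALSE, nrow(utr_slots)))

  ## abundance weights drawn before length assignment so the mature-length
  ## spectrum can be made consistent with the intended 21-nt count mode
  w <- 10^runif(n, config$abundance_log10_range[1], config$abundance_log10_range[2])
  mlens <- NULL
  for (try in seq_len(200L)) {
    cand <- sample(c(20L, 21L, 22L, 23L), n, replace = TRUE,
                   prob = c(0.2, 0.5, 0.15, 0.15))
    mass <- tapply(w, factor(cand, levels = 20:23), sum, default = 0)
    if (which.max(mass) == 2L) { mlens <- cand; break }
  }
  if (is.null(mlens)) {
    mlens <- rep(21L, n)
  }

  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- classes[i]
    mlen <- mlens[i]
    first <- if (runif(1) < config$five_prime_U_prob) "T" else sample(DNA_BASES, 1L)
    mature <- paste0(first, random_dna(mlen - 1L, gc = 0.5))
    arm <- sample(c("5p", "3p"), 1L)
    nmm <- sample(0:3, 1L, prob = c(0.25, 0.35, 0.25, 0.15))
    hp <- make_hairpin(mature, arm, nmm, config$arm_length,
                       config$loop_length, config$pad_length)
    if (cls == "intergenic") {
      ok <- FALSE
      for (try in seq_len(500L)) {
        s <- sample.int(L - prec_len - 10L, 1L)
        e <- s + prec_len - 1L
        if (!overlaps_any(s, e, gene_iv, 200L) && !overlaps_any(s, e, placed)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("cannot place hairpin locus ", i,
                    " without overlap; genome too small or too many loci")
    } else {
      slots <- switch(cls, intron = intron_slots, exon = exon_slots,
                      three_prime_UTR = utr_slots)
      free <- which(!slot_used[[cls]] & (slots$end - slots$start + 1L) >= prec_len)
      if (length(free) == 0L) stop("no free ", cls,
                                   " slot for hairpin locus ", i)
      si <- free[sample.int(length(free), 1L)]
      slot_used[[cls]][si] <- TRUE
      s <- slots$start[si] +
        sample.int(slots$end[si] - slots$start[si] - prec_len + 2L, 1L) - 1L
      e <- s + prec_len - 1L
    }
    strand <- sample(c("+", "-"), 1L)
    planted <- if (strand == "+") hp$precursor else reverse_complement(hp$precursor)
    substr(g, s, e) <- planted
    placed <- rbind(placed, data.frame(start = s, end = e))
    to_genomic <- function(p1, p2) {
      if (strand == "+") c(s + p1 - 1L, s + p2 - 1L) else c(e - p2 + 1L, e - p1 + 1L)
    }
    miv <- to_genomic(hp$mature_start, hp$mature_end)
    truth[[i]] <- data.frame(
      locus = sprintf("L%02d", i), chrom = "chr1",
      prec_start = s, prec_end = e, strand = strand,
      mature_seq = substr(hp$precursor, hp$mature_start, hp$mature_end),
      mature_len = mlen, arm = arm,
      mature_start = miv[1], mature_end = miv[2],
      star_seq = hp$star_seq, n_mismatch = nmm,
      location_class = cls,
      prec_seq = hp$precursor,
      mature_off5 = hp$mature_start, mature_off3 = hp$mature_end,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)

  ## ---- abundance, knockout effects, known subset ----
  mirna_fraction <- 1 - config$contaminant_fraction -
    config$degradation_fraction - config$defect_fraction
  truth$baseline_count <- mirna_fraction * config$read_count_per_library * w / sum(w)
  truth$baseline_tpm <- truth$baseline_count / config$read_count_per_library * 1e6
  eff <- rep(1, n); names(eff) <- truth$locus
  if (is.null(config$knockout_effect)) {
    profile <- c(0.04, 0.07, 0.09, 0.12, 0.15, 0.20, 0.25, 0.25)
    hit <- sample(n, min(length(profile), n))
    eff[hit] <- profile[seq_along(hit)]
  } else {
    eff[names(config$knockout_effect)] <- config$knockout_effect
  }
  truth$effect <- unname(eff)
  truth$expected_tpm_control <- truth$baseline_tpm
  truth$expected_tpm_mutant <- truth$baseline_tpm * truth$effect
  # exon/UTR-hosted loci are emitted as previously reported (known) miRNAs:
  # tags overlapping coding sequence are removed as degradation-like before
  # novel prediction, so only known-reference matches identify such loci
  exonic <- which(truth$location_class %in% c("exon", "three_prime_UTR"))
  nk <- min(config$n_known, n)
  known_idx <- exonic[seq_len(min(length(exonic), nk))]
  pool <- setdiff(seq_len(n), known_idx)
  if (length(known_idx) < nk) {
    known_idx <- c(known_idx, sample(pool, nk - length(known_idx)))
  }
  truth$known <- seq_len(n) %in% known_idx
  truth$name <- ifelse(truth$known,
                       sprintf("cre-miR-sim%02d", seq_len(n)), truth$locus)

  ## ---- adapter masking (adapter seeds stay non-genomic) ----
  seed3 <- substr(config$adapter3, 1L, 8L)
  seed5 <- substr(config$adapter5, nchar(config$adapter5) - 7L,
                  nchar(config$adapter5))
  for (motif in unique(c(seed3, reverse_complement(seed3),
                         seed5, reverse_complement(seed5)))) {
    g <- mask_motif(g, motif, placed)
  }

  genome <- Biostrings::DNAStringSet(setNames(g, "chr1"))

  ## ---- feature GRanges ----
  feats <- list()
  for (gn in genes) {
    mrna_id <- paste0(gn$id, ".t1")
    feats[[length(feats) + 1L]] <- data.frame(
      start = gn$start, end = gn$end, strand = gn$strand,
      kind = "gene", id = gn$id, parent = NA_character_)
    for (k in 1:3) feats[[length(feats) + 1L]] <- data.frame(
      start = gn$exons[k, 1], end = gn$exons[k, 2], strand = gn$strand,
      kind = "exon", id = sprintf("%s.e%d", gn$id, k), parent = mrna_id)
    for (k in 1:2) feats[[length(feats) + 1L]] <- data.frame(
      start = gn$introns[k, 1], end = gn$introns[k, 2], strand = gn$strand,
      kind = "intron", id = sprintf("%s.i%d", gn$id, k), parent = mrna_id)
    feats[[length(feats) + 1L]] <- data.frame(
      start = gn$utr[1], end = gn$utr[2], strand = gn$strand,
      kind = "three_prime_UTR", id = paste0(gn$id, ".utr3"), parent = mrna_id)
  }
  features <- if (length(feats)) {
    fd <- do.call(rbind, feats)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(fd$start, fd$end),
                           strand = fd$strand, kind = fd$kind,
                           id = fd$id, parent = fd$parent)
  } else {
    GenomicRanges::GRanges(kind = character(), id = character(),
                           parent = character())
  }
  GenomeInfoDb::seqlengths(features) <- c(chr1 = L)

  ## ---- contaminant ncRNA reference (non-genomic random stand-ins) ----
  cont_names <- c("rRNA_LSU", "rRNA_SSU", "rRNA_5S", "tRNA_Ala", "tRNA_Gly",
                  "snoRNA_U3", "snRNA_U4", "snRNA_U6")
  cont_len <- c(1500L, 900L, 120L, 76L, 74L, 210L, 140L, 110L)
  cont_seqs <- vapply(cont_len, random_dna, "")
  for (motif in unique(c(seed3, reverse_complement(seed3),
                         seed5, reverse_complement(seed5)))) {
    cont_seqs <- vapply(cont_seqs, mask_motif, "", motif,
                        data.frame(start = integer(), end = integer()))
  }
  contaminants <- Biostrings::DNAStringSet(setNames(unname(cont_seqs),
                                                    cont_names))

  known <- truth[truth$known, , drop = FALSE]
  known_mature <- Biostrings::DNAStringSet(
    setNames(known$mature_seq, known$name))
  known_precursors <- Biostrings::DNAStringSet(
    setNames(known$prec_seq, paste0(known$name, "-precursor")))

  list(genome = genome, features = features, truth = truth,
       contaminants = contaminants, known_mature = known_mature,
       known_precursors = known_precursors, config = config)
}

#' Simulate per-locus replicate counts under the generative model
#'
#' Draws negative-binomial read counts for each locus and replicate, with
#' mutant-group means multiplied by the locus knockout effect. This is the
#' count layer of the full read simulator, exposed for statistical
#' calibration studies (e.g. type-I error under the null where all effects
#' are 1).
#'
#' @param baseline_counts Numeric vector of per-library mean mature counts.
#' @param effects Multiplicative knockout effects, recycled to match.
#' @param replicates_per_group Replicates in each of the two groups.
#' @param dispersion NB overdispersion (variance = mu + dispersion * mu^2).
#' @return A matrix (loci x 2*replicates) with control replicates first;
#'   column names encode group and replicate.
#' @export
simulate_locus_counts <- function(baseline_counts, effects = 1,
                                  replicates_per_group = 3L,
                                  dispersion = 0.1) {
  n <- length(baseline_counts)
  effects <- rep_len(effects, n)
  reps <- as.integer(replicates_per_group)
  draw <- function(mu) {
    if (dispersion <= 0) stats::rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  ctrl <- matrix(unlist(lapply(seq_len(reps), function(r) draw(baseline_counts))),
                 nrow = n)
  mut <- matrix(unlist(lapply(seq_len(reps), function(r) draw(baseline_counts * effects))),
                nrow = n)
  out <- cbind(ctrl, mut)
  colnames(out) <- c(paste0("control_", seq_len(reps)),
                     paste0("mutant_", seq_len(reps)))
  rownames(out) <- names(baseline_counts)
  out
}

# mature-variant table for one locus: exact insert plus the four +/-1 nt
# ragged-end variants, all cut from the precursor.
mature_variants <- function(prec, p_ms, p_me) {
  lims <- function(a, b) c(max(1L, a), min(nchar(prec), b))
  v <- rbind(c(p_ms, p_me), c(p_ms - 1L, p_me), c(p_ms + 1L, p_me),
             c(p_ms, p_me - 1L), c(p_ms, p_me + 1L))
  apply(v, 1L, function(x) {
    x <- lims(x[1], x[2]); substr(prec, x[1], x[2])
  })
}

#' Simulate control and knockout small-RNA libraries
#'
#' Writes one FASTQ file per replicate plus the genome, annotation,
#' contaminant, known-miRNA and truth files, and a sample sheet. Read counts
#' per locus and replicate are negative-binomial around the locus baseline
#' (times the knockout effect in mutant replicates); mature reads dominate
#' star reads at the configured ratio and a `jitter_fraction` of mature reads
#' carry +/-1 nt ragged ends. Contaminant and degradation reads are drawn
#' from the contaminant set and exonic sequence respectively, and a small
#' planted fraction of defective reads exercises every cleaning filter.
#'
#' @param sim Output of [build_genome()].
#' @param outdir Output directory (created if missing).
#' @return A list with the sample sheet (`samples`), file paths and the
#'   per-library planted-read tallies (`planted`).
#' @export
simulate_libraries <- function(sim, outdir) {
  config <- sim$config
  set.seed(config$seed + 1L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- sim$truth
  n <- nrow(truth)
  reps <- config$replicates_per_group
  N <- config$read_count_per_library
  rl <- config$read_length
  a3 <- config$adapter3
  a5 <- config$adapter5

  variants <- lapply(seq_len(n), function(i) {
    mature_variants(truth$prec_seq[i], truth$mature_off5[i], truth$mature_off3[i])
  })

  qpool_hi <- vapply(seq_len(500L), function(i) {
    intToUtf8(sample(61:73, rl, replace = TRUE))   # Phred 28-40
  }, "")
  qpool_lo <- vapply(seq_len(100L), function(i) {
    intToUtf8(sample(35:53, rl, replace = TRUE))   # Phred 2-20, mean ~ 11
  }, "")
  padpool <- vapply(seq_len(500L), function(i) random_dna(rl), "")

  make_reads <- function(inserts, append3 = TRUE, qual = qpool_hi) {
    k <- length(inserts)
    if (k == 0L) return(data.frame(seq = character(), qual = character()))
    body <- if (append3) paste0(inserts, a3) else inserts
    seqs <- substr(paste0(body, padpool[sample.int(length(padpool), k, TRUE)]),
                   1L, rl)
    data.frame(seq = seqs,
               qual = substr(qual[sample.int(length(qual), k, TRUE)], 1L,
                             nchar(seqs)),
               stringsAsFactors = FALSE)
  }

  cont <- as.character(sim$contaminants)
  exon_feats <- sim$features[sim$features$kind == "exon"]
  exon_seqs <- if (length(exon_feats)) {
    as.character(Biostrings::extractAt(
      sim$genome[["chr1"]], IRanges::ranges(exon_feats)))
  } else character()

  groups <- c(rep("control", reps), rep("mutant", reps))
  samples <- data.frame(
    sample = c(paste0("WT_", seq_len(reps)), paste0("KO_", seq_len(reps))),
    group = groups,
    replicate = rep(seq_len(reps), 2L),
    fastq = NA_character_, stringsAsFactors = FALSE)

  n_cont <- round(config$contaminant_fraction * N)
  n_degr <- round(config$degradation_fraction * N)
  n_def1 <- round(config$defect_fraction * N / 6)
  planted <- list()

  for (li in seq_len(nrow(samples))) {
    mutant <- samples$group[li] == "mutant"
    mu <- truth$baseline_count * (if (mutant) truth$effect else 1)
    mat_counts <- rnbinom(n, mu = mu, size = 1 / config$dispersion)
    star_counts <- round(mat_counts / config$mature_star_ratio)

    locus_of_mat <- rep(seq_len(n), mat_counts)
    vidx <- ifelse(runif(length(locus_of_mat)) < config$jitter_fraction,
                   sample(2:5, length(locus_of_mat), replace = TRUE), 1L)
    mat_ins <- vapply(seq_len(n), function(i) variants[[i]], character(5L))
    mature_inserts <- mat_ins[cbind(vidx, locus_of_mat)]
    star_inserts <- rep(truth$star_seq, star_counts)

    ci <- sample.int(length(cont), n_cont, replace = TRUE,
                     prob = nchar(cont))
    clen <- sample(18:28, n_cont, replace = TRUE)
    cst <- floor(runif(n_cont) * pmax(1L, nchar(cont)[ci] - clen)) + 1L
    cont_inserts <- substr(cont[ci], cst, cst + clen - 1L)

    degr_inserts <- character()
    if (length(exon_seqs) && n_degr > 0L) {
      ei <- sample.int(length(exon_seqs), n_degr, replace = TRUE,
                       prob = nchar(exon_seqs))
      dlen <- sample(18:28, n_degr, replace = TRUE)
      dst <- floor(runif(n_degr) * pmax(1L, nchar(exon_seqs)[ei] - dlen)) + 1L
      degr_inserts <- substr(exon_seqs[ei], dst, dst + dlen - 1L)
      flip <- runif(n_degr) < 0.5
      degr_inserts[flip] <- reverse_complement(degr_inserts[flip])
    }

    good_ins <- sample(c(mature_inserts, star_inserts), replace = FALSE)
    def_ins <- function(k) good_ins[sample.int(length(good_ins), k, TRUE)]
    def_N <- def_ins(n_def1)
    substr(def_N, 5L, 5L) <- "N"
    reads <- rbind(
      make_reads(c(mature_inserts, star_inserts, cont_inserts, degr_inserts)),
      make_reads(def_ins(n_def1), qual = qpool_lo),                  # low quality
      make_reads(def_N),                                             # contains N
      make_reads(def_ins(n_def1), append3 = FALSE),                  # no 3' adapter
      make_reads(paste0(substr(a5, nchar(a5) - 7L, nchar(a5)),
                        def_ins(n_def1))),                           # 5' adapter
      make_reads(substr(def_ins(n_def1), 1L, 17L)),                  # short insert
      make_reads(strrep("A", 20L)[rep(1L, n_def1)])                  # polyA insert
    )
    ord <- sample.int(nrow(reads))
    reads <- reads[ord, , drop = FALSE]
    reads$id <- sprintf("%s_r%07d", samples$sample[li], seq_len(nrow(reads)))
    path <- file.path(outdir, paste0(samples$sample[li], ".fastq"))
    write_fastq(reads[, c("id", "seq", "qual")], path)
    samples$fastq[li] <- path
    planted[[samples$sample[li]]] <- list(mature = mat_counts,
                                          star = star_counts,
                                          n_reads = nrow(reads))
  }

  samples$adapter3 <- a3
  samples$adapter5 <- a5
  paths <- list(
    sample_sheet = file.path(outdir, "samples.tsv"),
    genome = file.path(outdir, "genome.fa"),
    annotation = file.path(outdir, "annotation.gff3"),
    contaminants = file.path(outdir, "contaminants.fa"),
    known_mature = file.path(outdir, "known_mature.fa"),
    known_precursors = file.path(outdir, "known_precursors.fa"),
    truth = file.path(outdir, "truth.tsv"))
  write.table(samples, paths$sample_sheet, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_fasta(sim$genome, paths$genome)
  write_gff3(sim$features, paths$annotation)
  write_fasta(sim$contaminants, paths$contaminants)
  write_fasta(sim$known_mature, paths$known_mature)
  write_fasta(sim$known_precursors, paths$known_precursors)
  write.table(sim$truth[, setdiff(names(sim$truth), "prec_seq")],
              paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  list(samples = samples, paths = paths, planted = planted)
}
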