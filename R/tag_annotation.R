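#' Match a tag against a reference sequence set
#'
#' Substring search of each tag, in both orientations, against every
#' reference record, allowing up to `max_mismatches` substitutions. The
#' first matching reference in file order wins (forward orientation tried
#' before reverse complement within each record).
#'
#' @param tags Character vector of tag sequences.
#' @param reference A named [Biostrings::DNAStringSet] (e.g. a contaminant
#'   ncRNA set or a miRBase-style mature/stem-loop set).
#' @param max_mismatches Maximum substitutions tolerated (0 for contaminant
#'   matching, 2 for known-miRNA matching by default elsewhere).
#' @return Character vector of matched reference ids (`NA` where unmatched).
#' @export
match_reference <- function(tags, reference, max_mismatches = 0L) {
  stopifnot(max_mismatches >= 0L)
  if (length(reference) == 0L || length(tags) == 0L) {
    return(rep(NA_character_, length(tags)))
  }
  idx <- hamming_substring_match(tags, reverse_complement(tags),
                                 as.character(reference),
                                 as.integer(max_mismatches))
  ifelse(is.na(idx), NA_character_, names(reference)[idx])
}

#' Map tags to all exact genomic occurrences
#'
#' Finds every exact, full-length occurrence of each tag on both strands of
#' the genome. A tag equal to the reverse complement of a genomic segment is
#' reported as a `-`-strand hit at that segment's coordinates (1-based
#' inclusive).
#'
#' @param tags Character vector of tag sequences.
#' @param genome A named [Biostrings::DNAStringSet].
#' @return A [GenomicRanges::GRanges] of hits with a `tag` metadata column;
#'   zero-length when nothing maps.
#' @export
map_to_genome <- function(tags, genome) {
  hits <- map_tags_table(tags, genome)
  if (nrow(hits) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$tag <- character()
    return(gr)
  }
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start, hits$end),
                               strand = hits$strand, tag = hits$tag)
  GenomeInfoDb::seqlengths(gr) <-
    setNames(Biostrings::width(genome), names(genome))[GenomeInfoDb::seqlevels(gr)]
  gr
}

# Exact mapping by hashed window lookup: for every tag width, all genomic
# windows of that width are matched against the tag set (plus strand) and
# against the tags' reverse complements (minus strand).
map_tags_table <- function(tags, genome) {
  out <- list()
  if (length(tags) == 0L) {
    return(data.frame(tag = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  widths <- nchar(tags)
  tags_rc <- reverse_complement(tags)
  for (chrom in names(genome)) {
    g <- as.character(genome[[chrom]])
    L <- nchar(g)
    for (w in sort(unique(widths))) {
      if (w > L || w == 0L) next
      sel <- widths == w
      tset <- tags[sel]; trc <- tags_rc[sel]
      starts <- seq_len(L - w + 1L)
      win <- substring(g, starts, starts + w - 1L)
      for (strand in c("+", "-")) {
        m <- match(win, if (strand == "+") tset else trc)
        hit <- which(!is.na(m))
        if (length(hit)) {
          out[[length(out) + 1L]] <- data.frame(
            tag = tset[m[hit]], chrom = chrom,
            start = starts[hit], end = starts[hit] + w - 1L,
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(tag = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$tag, res$chrom, res$start, res$strand), , drop = FALSE]
}

#' Classify the genomic location of intervals
#'
#' Labels each interval by the highest-priority feature kind it overlaps by
#' at least one base (strand-agnostic), with priority
#' exon > 3'UTR > intron; intervals overlapping none of these are
#' `intergenic`.
#'
#' @param intervals A [GenomicRanges::GRanges].
#' @param features A feature [GenomicRanges::GRanges] with a `kind` column,
#'   e.g. from [read_gff3()].
#' @return Character vector of location classes (`exon`,
#'   `three_prime_UTR`, `intron`, `intergenic`).
#' @export
classify_location <- function(intervals, features) {
  out <- rep("intergenic", length(intervals))
  if (length(intervals) == 0L) return(character())
  for (kind in c("intron", "three_prime_UTR", "exon")) {
    f <- features[features$kind == kind]
    if (length(f) == 0L) next
    ov <- GenomicRanges::countOverlaps(intervals, f, minoverlap = 1L,
                                       ignore.strand = TRUE) > 0L
    out[ov] <- kind
  }
  out
}

#' Annotation parameters
#'
#' @param contaminant_mismatches Substitutions tolerated for contaminant
#'   matching.
#' @param known_mismatches Substitutions tolerated for known-miRNA matching.
#' @param max_hits Genomic hit count above which a tag is treated as a
#'   repeat (excluded from novel-candidate input).
#' @return A list of class `annotation_params`.
#' @export
annotation_params <- function(contaminant_mismatches = 0L,
                              known_mismatches = 2L,
                              max_hits = 10L) {
  p <- list(contaminant_mismatches = as.integer(contaminant_mismatches),
            known_mismatches = as.integer(known_mismatches),
            max_hits = as.integer(max_hits))
  class(p) <- "annotation_params"
  p
}

#' Annotate clean tags by cascade
#'
#' Applies the annotation cascade in order: contaminant ncRNA first, then
#' known miRNA, then exact genome mapping with per-hit location
#' classification; tags matching nothing are `unmapped`. Every tag receives
#' exactly one tier, so a sequence present both in the contaminant set and
#' in the genome is tiered `contaminant`.
#'
#' @param tags A tag table from [collapse_tags()] (or any data.frame with a
#'   `seq` column).
#' @param contaminants,known_mirnas [Biostrings::DNAStringSet] references
#'   (either may be empty).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param features Feature [GenomicRanges::GRanges] with `kind`, or `NULL`
#'   (all genome hits then classify as intergenic).
#' @param params An [annotation_params()].
#' @return A list of class `tag_annotation`: `annotation` (data.frame with
#'   `seq`, `tier`, `matched_id`, `n_hits`) and `hits` (GRanges of genomic
#'   hits with `tag` and `location` columns, known-miRNA tags included so
#'   their loci can be located).
#' @export
annotate_tags <- function(tags, contaminants = NULL, known_mirnas = NULL,
                          genome = NULL, features = NULL,
                          params = annotation_params()) {
  seqs <- tags$seq
  n <- length(seqs)
  tier <- rep("unmapped", n)
  matched <- rep(NA_character_, n)

  if (!is.null(contaminants) && length(contaminants)) {
    m <- match_reference(seqs, contaminants, params$contaminant_mismatches)
    tier[!is.na(m)] <- "contaminant"
    matched[!is.na(m)] <- m[!is.na(m)]
  }
  open <- tier == "unmapped"
  if (!is.null(known_mirnas) && length(known_mirnas) && any(open)) {
    m <- match_reference(seqs[open], known_mirnas, params$known_mismatches)
    hit <- which(open)[!is.na(m)]
    tier[hit] <- "known_miRNA"
    matched[hit] <- m[!is.na(m)]
  }

  hits <- NULL
  n_hits <- rep(0L, n)
  if (!is.null(genome)) {
    candidate <- tier %in% c("unmapped", "known_miRNA")
    hits <- map_to_genome(seqs[candidate], genome)
    if (length(hits)) {
      tab <- table(hits$tag)
      n_hits[match(names(tab), seqs)] <- as.integer(tab)
      hits$location <- if (!is.null(features)) {
        classify_location(hits, features)
      } else rep("intergenic", length(hits))
    }
    mapped <- tier == "unmapped" & n_hits > 0L
    tier[mapped] <- "genome_mapped"
  }

  structure(list(
    annotation = data.frame(seq = seqs, tier = tier, matched_id = matched,
                            n_hits = n_hits, stringsAsFactors = FALSE),
    hits = hits,
    params = params), class = "tag_annotation")
}

#' Flag degradation-like tags
#'
#' Genome-mapped tags whose every hit overlaps exon or 3'UTR sequence, that
#' are neither known miRNAs nor part of a surviving hairpin locus, are
#' flagged as likely mRNA-degradation fragments.
#'
#' @param annot A [annotate_tags()] result.
#' @param called_tags Character vector of mature sequences retained by
#'   hairpin evaluation (novel calls), or `NULL`.
#' @return The annotation data.frame with a logical `degradation_like`
#'   column added.
#' @export
flag_degradation <- function(annot, called_tags = NULL) {
  ann <- annot$annotation
  ann$degradation_like <- FALSE
  if (is.null(annot$hits) || length(annot$hits) == 0L) return(ann)
  hd <- data.frame(tag = annot$hits$tag, loc = annot$hits$location,
                   stringsAsFactors = FALSE)
  exonic <- tapply(hd$loc %in% c("exon", "three_prime_UTR"), hd$tag, all)
  sel <- ann$tier == "genome_mapped" &
    ann$seq %in% names(exonic)[exonic] &
    !(ann$seq %in% called_tags)
  ann$degradation_like[sel] <- TRUE
  ann
}
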