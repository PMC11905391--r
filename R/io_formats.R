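#' Read a FASTA file of DNA (or RNA) sequences
#'
#' Reads a multi-record FASTA file into a [Biostrings::DNAStringSet]. RNA
#' input is normalized to the internal DNA alphabet (`U` -> `T`) and case is
#' folded to upper, so genome, contaminant and miRBase-style mature/stem-loop
#' references all share one alphabet.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped records).
#' @return A named [Biostrings::DNAStringSet]; names are the header tokens up
#'   to the first whitespace, with the remainder kept as the `description`
#'   metadata column.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(Biostrings::DNAStringSet())
  }
  if (!startsWith(first, ">")) {
    stop("malformed FASTA at line 1 (expected '>' header): ", path)
  }
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file ", path, ": ",
                             conditionMessage(e))
  )
  if (any(Biostrings::width(raw) == 0L)) {
    bad <- which(Biostrings::width(raw) == 0L)[1L]
    stop("empty sequence for FASTA record '", names(raw)[bad], "' in ", path)
  }
  seqs <- toupper(chartr("Uu", "Tt", as.character(raw)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-DNA characters in FASTA record '", names(raw)[which(bad)[1L]],
         "' in ", path)
  }
  ids <- sub("\\s.*$", "", names(raw))
  desc <- ifelse(grepl("\\s", names(raw)),
                 sub("^\\S+\\s+", "", names(raw)), "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA record id '", ids[anyDuplicated(ids)], "' in ", path)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write sequences to a FASTA file
#'
#' @param x A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a 4-line FASTQ file (Phred+33)
#'
#' Parses the standard 4-line-per-record FASTQ dialect. Sequences are
#' upper-cased with `U` mapped to `T`; quality strings are validated to match
#' the sequence length record by record and kept Phred+33 encoded (decode
#' with [phred_scores()]).
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ file ", path, ": line count ", length(lines),
         " is not a multiple of 4")
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (!all(startsWith(hdr, "@"))) {
    stop("malformed FASTQ file ", path, ": record header without '@' near record ",
         which(!startsWith(hdr, "@"))[1L])
  }
  if (!all(startsWith(plus, "+"))) {
    stop("malformed FASTQ file ", path, ": separator line without '+' near record ",
         which(!startsWith(plus, "+"))[1L])
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  mism <- nchar(seqs) != nchar(qual)
  if (any(mism)) {
    stop("FASTQ record '", ids[which(mism)[1L]],
         "': sequence and quality lengths differ")
  }
  data.frame(id = ids,
             seq = toupper(chartr("Uu", "Tt", seqs)),
             qual = qual,
             stringsAsFactors = FALSE)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual Character vector of quality strings.
#' @return A list of integer vectors, one per input string.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (!nzchar(q)) integer() else utf8ToInt(q) - 33L
  })
}

#' Write reads to a 4-line FASTQ file
#'
#' @param reads A `data.frame` with columns `id`, `seq`, `qual` (Phred+33).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence and quality lengths differ")
  }
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), by = 4L)] <- reads$seq
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Read a GFF3 annotation into genome features
#'
#' Imports a GFF3 file (1-based inclusive coordinates) and returns the
#' feature kinds used for genomic location classification: `gene`, `exon`,
#' `three_prime_UTR`, `five_prime_UTR` and `intron`. When the file carries no
#' explicit intron features, introns are derived per transcript as the gaps
#' between consecutive exons sharing one `Parent`.
#'
#' @param path Path to a GFF3 file.
#' @return A [GenomicRanges::GRanges] with a `kind` metadata column.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body)) {
    nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
    if (any(nfield != 9L)) {
      stop("malformed GFF3 file ", path, ": line with ",
           nfield[nfield != 9L][1L], " columns (9 required)")
    }
    starts <- vapply(strsplit(body, "\t", fixed = TRUE), `[`, "", 4L)
    ends <- vapply(strsplit(body, "\t", fixed = TRUE), `[`, "", 5L)
    if (any(is.na(suppressWarnings(as.integer(starts)))) ||
        any(is.na(suppressWarnings(as.integer(ends))))) {
      stop("malformed GFF3 file ", path, ": non-numeric coordinates")
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  keep_kinds <- c("gene", "exon", "intron", "three_prime_UTR", "five_prime_UTR")
  gr <- gr[as.character(gr$type) %in% keep_kinds]
  kind <- as.character(gr$type)
  feats <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    kind = kind
  )
  parent <- if (!is.null(gr$Parent)) {
    vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1L]] else NA_character_, "")
  } else rep(NA_character_, length(gr))
  feats$parent <- parent
  if (!any(kind == "intron")) {
    feats <- c(feats, derive_introns(feats))
  }
  feats
}

# Gaps between consecutive exons of one transcript, carried over to the
# transcript's strand.
derive_introns <- function(feats) {
  ex <- feats[feats$kind == "exon" & !is.na(feats$parent)]
  if (length(ex) == 0L) return(GenomicRanges::GRanges(kind = character(), parent = character()))
  by_tx <- split(ex, ex$parent)
  introns <- lapply(names(by_tx), function(tx) {
    e <- by_tx[[tx]]
    if (length(e) < 2L) return(NULL)
    rng <- range(e)
    gaps <- GenomicRanges::setdiff(rng, e, ignore.strand = FALSE)
    if (length(gaps) == 0L) return(NULL)
    gaps$kind <- "intron"
    gaps$parent <- tx
    gaps
  })
  introns <- introns[!vapply(introns, is.null, TRUE)]
  if (length(introns) == 0L) {
    return(GenomicRanges::GRanges(kind = character(), parent = character()))
  }
  do.call(c, introns)
}

#' Write genome features to a GFF3 file
#'
#' @param feats A [GenomicRanges::GRanges] with `kind` (and optionally
#'   `ID`/`parent`) metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(feats, path) {
  gr <- feats
  gr$type <- gr$kind
  gr$kind <- NULL
  if (!is.null(gr$parent)) {
    gr$Parent <- ifelse(is.na(gr$parent), NA_character_, gr$parent)
    gr$parent <- NULL
  }
  gr$source <- "srnamir"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`.
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) {
    stop("non-DNA character in sequence (alphabet is A/C/G/T/N)")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Extract a genomic window sequence
#'
#' Returns the subsequence of the named chromosome over a 1-based inclusive
#' interval; on the `-` strand the reverse complement is returned.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return A single character string.
#' @export
extract_window <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- Biostrings::width(genome[chrom])
  if (start < 1L || end > L || start > end) {
    stop("interval ", start, "..", end, " out of bounds for ", chrom,
         " (length ", L, ")")
  }
  s <- as.character(Biostrings::subseq(genome[[chrom]], start, end))
  if (identical(strand, "-")) reverse_complement(s) else s
}
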