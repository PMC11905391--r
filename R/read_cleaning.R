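#' Cleaning parameters
#'
#' Thresholds of the raw-read filters. A read is rejected when its mean
#' Phred quality is at or below `min_quality`, when it contains `N`, when no
#' 3' adapter is found (exact match of the adapter's first `seed3_len` bases
#' at or after read position `adapter_min_pos`), when the trimmed insert
#' still carries the 5' adapter (exact match of the adapter's last
#' `seed5_len` bases anywhere in it), when the insert is shorter than `min_len` or longer than
#' `max_len`, or when the insert is polyA (at least `polyA_frac` of its bases
#' are A, or it contains a run of `polyA_run` or more A).
#'
#' @param min_quality Mean-quality rejection threshold (reject when <=).
#' @param min_len,max_len Insert length window in nt.
#' @param seed3_len 3' adapter seed length (prefix).
#' @param seed5_len 5' adapter seed length (suffix).
#' @param adapter_min_pos Earliest read position searched for the 3' adapter.
#' @param polyA_frac,polyA_run PolyA rejection rule.
#' @return A list of class `clean_params`.
#' @export
clean_params <- function(min_quality = 20, min_len = 18L, max_len = 30L,
                         seed3_len = 8L, seed5_len = 8L,
                         adapter_min_pos = 18L,
                         polyA_frac = 0.8, polyA_run = 10L) {
  p <- list(min_quality = min_quality, min_len = as.integer(min_len),
            max_len = as.integer(max_len), seed3_len = as.integer(seed3_len),
            seed5_len = as.integer(seed5_len),
            adapter_min_pos = as.integer(adapter_min_pos),
            polyA_frac = polyA_frac, polyA_run = as.integer(polyA_run))
  stopifnot(p$min_len > 0, p$max_len >= p$min_len, p$seed3_len > 0,
            p$polyA_frac > 0, p$polyA_frac <= 1, p$polyA_run > 1)
  class(p) <- "clean_params"
  p
}

REJECT_REASONS <- c("low_quality", "contains_N", "no_3p_adapter",
                    "has_5p_adapter", "short", "polyA", "long")

#' Clean a batch of reads
#'
#' Applies the raw-read filters in fixed order -- (1) low mean quality,
#' (2) unknown nucleotide N, (3) missing 3' adapter (otherwise the adapter
#' and everything after it is trimmed off), (4) 5' adapter contamination,
#' (5) insert shorter than the minimum, (6) polyA insert, (7) insert longer
#' than the maximum -- and returns the surviving insert or the first
#' rejection reason per read.
#'
#' @param seqs Character vector of read sequences.
#' @param quals Matching Phred+33 quality strings.
#' @param adapter3,adapter5 Adapter sequences.
#' @param params A [clean_params()].
#' @return A list with `insert` (character, `NA` where rejected) and
#'   `reason` (character, `NA` where kept; one of
#'   low_quality, contains_N, no_3p_adapter, has_5p_adapter, short, polyA,
#'   long).
#' @export
clean_reads <- function(seqs, quals, adapter3, adapter5 = "",
                        params = clean_params()) {
  stopifnot(length(seqs) == length(quals), nzchar(adapter3))
  n <- length(seqs)
  reason <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  if (n == 0L) return(list(insert = insert, reason = reason))

  empty <- !nzchar(seqs)
  reason[empty] <- "short"
  todo <- !empty

  mq <- phred_mean(quals)
  sel <- todo & mq <= params$min_quality
  reason[sel] <- "low_quality"; todo <- todo & !sel

  sel <- todo & grepl("N", seqs, fixed = TRUE)
  reason[sel] <- "contains_N"; todo <- todo & !sel

  seed3 <- substr(adapter3, 1L, params$seed3_len)
  tail_part <- substr(seqs, params$adapter_min_pos, nchar(seqs))
  loc <- rep(-1L, n)
  loc[todo] <- regexpr(seed3, tail_part[todo], fixed = TRUE)
  sel <- todo & loc < 0L
  reason[sel] <- "no_3p_adapter"; todo <- todo & !sel
  ins <- substr(seqs, 1L, params$adapter_min_pos - 2L + pmax(loc, 1L))

  if (nzchar(adapter5)) {
    # searched in the trimmed insert: bases at or after the 3' adapter are
    # adapter/filler sequence, not part of the ligated fragment
    seed5 <- substr(adapter5, max(1L, nchar(adapter5) - params$seed5_len + 1L),
                    nchar(adapter5))
    sel <- todo & grepl(seed5, ins, fixed = TRUE)
    reason[sel] <- "has_5p_adapter"; todo <- todo & !sel
  }

  sel <- todo & nchar(ins) < params$min_len
  reason[sel] <- "short"; todo <- todo & !sel

  nA <- nchar(ins) - nchar(gsub("A", "", ins, fixed = TRUE))
  isA <- nA / pmax(nchar(ins), 1L) >= params$polyA_frac |
    grepl(strrep("A", params$polyA_run), ins, fixed = TRUE)
  sel <- todo & isA
  reason[sel] <- "polyA"; todo <- todo & !sel

  sel <- todo & nchar(ins) > params$max_len
  reason[sel] <- "long"; todo <- todo & !sel

  insert[todo] <- ins[todo]
  list(insert = insert, reason = reason)
}

#' Clean a single read
#'
#' Scalar convenience wrapper around [clean_reads()].
#'
#' @param seq Read sequence.
#' @param qual Phred+33 quality string.
#' @inheritParams clean_reads
#' @return A list with `insert` (or `NA`) and `reason` (or `NA`).
#' @export
clean_read <- function(seq, qual, adapter3, adapter5 = "",
                       params = clean_params()) {
  r <- clean_reads(seq, qual, adapter3, adapter5, params)
  list(insert = r$insert[1L], reason = r$reason[1L])
}

#' Collapse cleaned inserts into counted clean tags
#'
#' One tag per distinct insert sequence with per-library counts, ordered by
#' descending total count and then lexicographically, so output is invariant
#' to input read order.
#'
#' @param inserts_by_library Named list of character vectors (surviving
#'   inserts per library).
#' @param libraries Library names defining the count columns (defaults to
#'   the names of `inserts_by_library`); a list name absent from this set is
#'   an error.
#' @return A `data.frame` with columns `seq`, one count column per library,
#'   and `total`.
#' @export
collapse_tags <- function(inserts_by_library,
                          libraries = names(inserts_by_library)) {
  stopifnot(is.list(inserts_by_library), !is.null(names(inserts_by_library)))
  missing_lib <- setdiff(names(inserts_by_library), libraries)
  if (length(missing_lib)) {
    stop("library not in sample sheet: ", paste(missing_lib, collapse = ", "))
  }
  dt <- rbindlist(lapply(names(inserts_by_library), function(lb) {
    x <- inserts_by_library[[lb]]
    if (length(x) == 0L) return(NULL)
    data.table(seq_ = x, lib = lb)
  }))
  empty <- data.frame(seq = character(), stringsAsFactors = FALSE)
  for (lb in libraries) empty[[lb]] <- integer()
  empty$total <- integer()
  if (is.null(dt) || nrow(dt) == 0L) return(empty)
  counts <- dt[, .N, by = .(seq_, lib)]
  wide <- dcast(counts, seq_ ~ lib, value.var = "N", fill = 0L)
  for (lb in setdiff(libraries, names(wide))) wide[[lb]] <- 0L
  wide <- wide[, c("seq_", libraries), with = FALSE]
  wide$total <- rowSums(as.matrix(wide[, libraries, with = FALSE]))
  setorder(wide, -total, seq_)
  out <- as.data.frame(wide)
  names(out)[1L] <- "seq"
  out
}

#' Per-library cleaning report
#'
#' Tallies of the rejection reasons plus survivors per library; per library
#' the tallies sum to the input read count.
#'
#' @param reasons_by_library Named list of per-read reason vectors
#'   (`NA` = kept), as returned by [clean_reads()].
#' @param unique_tags Optional named integer vector of unique tag counts.
#' @return A `data.frame` with one row per library.
#' @export
cleaning_report <- function(reasons_by_library, unique_tags = NULL) {
  rows <- lapply(names(reasons_by_library), function(lb) {
    r <- reasons_by_library[[lb]]
    tab <- table(factor(r, levels = REJECT_REASONS))
    out <- data.frame(library = lb, input_reads = length(r),
                      stringsAsFactors = FALSE)
    for (rr in REJECT_REASONS) out[[paste0("removed_", rr)]] <- as.integer(tab[[rr]])
    out$surviving <- sum(is.na(r))
    out$unique_tags <- if (!is.null(unique_tags)) unique_tags[[lb]] else NA_integer_
    out
  })
  do.call(rbind, rows)
}

#' Read-length distribution of clean tags
#'
#' Proportions of read counts (not unique tags) by insert length, per
#' library; each library column sums to 1.
#'
#' @param tags A tag table from [collapse_tags()].
#' @param libraries Count columns to tabulate (default: all between `seq`
#'   and `total`).
#' @return A `data.frame` with `length` and one proportion column per
#'   library.
#' @export
length_distribution <- function(tags, libraries = NULL) {
  if (nrow(tags) == 0L) stop("empty tag table")
  if (is.null(libraries)) {
    libraries <- setdiff(names(tags), c("seq", "total"))
  }
  len <- nchar(tags$seq)
  lens <- sort(unique(len))
  out <- data.frame(length = lens)
  for (lb in libraries) {
    tot <- sum(tags[[lb]])
    out[[lb]] <- vapply(lens, function(l) sum(tags[[lb]][len == l]) / tot, 0)
  }
  out
}
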