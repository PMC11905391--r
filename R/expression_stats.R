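#' TPM normalization
#'
#' Transcripts per million: the tag (or miRNA) count divided by the
#' library's total clean-tag count, times 10^6, so TPM over all clean tags
#' of a library sums to one million.
#'
#' @param count Non-negative count(s).
#' @param total_clean_tags Total clean tags of the library (> 0).
#' @return TPM value(s).
#' @export
tpm_normalize <- function(count, total_clean_tags) {
  if (any(total_clean_tags <= 0)) stop("total clean tags must be > 0")
  if (any(count < 0)) stop("counts must be >= 0")
  count / total_clean_tags * 1e6
}

#' Fold change and its log2
#'
#' Fold change is mutant over control mean expression; a pseudocount is
#' substituted only for a zero mean so the ratio stays defined. Both means
#' zero is undefined and flagged.
#'
#' @param mean_mutant,mean_control Group mean TPM values.
#' @param pseudocount Guard value used when a mean is exactly 0.
#' @return A list with `fc`, `log2fc` and `defined`.
#' @export
fold_change <- function(mean_mutant, mean_control, pseudocount = 0.01) {
  stopifnot(mean_mutant >= 0, mean_control >= 0, pseudocount >= 0)
  if (mean_mutant == 0 && mean_control == 0) {
    return(list(fc = NA_real_, log2fc = NA_real_, defined = FALSE))
  }
  mm <- if (mean_mutant == 0) pseudocount else mean_mutant
  mc <- if (mean_control == 0) pseudocount else mean_control
  fc <- mm / mc
  list(fc = fc, log2fc = log2(fc), defined = TRUE)
}

#' Two-group significance test on log2 TPM
#'
#' Welch's two-sided t test on `log2(TPM + pseudocount)` per replicate,
#' computed in closed form so degenerate inputs are handled exactly: zero
#' variance in both groups gives p = 1 when the means agree and p -> 0 when
#' they differ.
#'
#' @param tpm_mutant,tpm_control Replicate TPM vectors (>= 2 each).
#' @param pseudocount Added before the log transform (1 TPM by default,
#'   which keeps zero-count replicates from dominating the variance).
#' @return Two-sided p-value.
#' @export
de_test <- function(tpm_mutant, tpm_control, pseudocount = 1) {
  stopifnot(length(tpm_mutant) >= 2L, length(tpm_control) >= 2L)
  x <- log2(tpm_mutant + pseudocount)
  y <- log2(tpm_control + pseudocount)
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  d <- mean(x) - mean(y)
  if (v1 == 0 && v2 == 0) {
    return(if (d == 0) 1 else 0)
  }
  se2 <- v1 / n1 + v2 / n2
  tt <- d / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  2 * pt(-abs(tt), df)
}

#' Classify differential expression status and tier
#'
#' Down-regulated when `log2fc <= -log2(1.5)` with `p < 0.05`; up-regulated
#' when `log2fc >= log2(1.5)` with `p < 0.05`; otherwise not significant.
#' Down-regulated records split into the high tier (`log2fc <= -1`,
#' boundary inclusive) and the medium tier
#' (`-1 < log2fc <= -log2(1.5)`).
#'
#' @param log2fc Log2 fold change (mutant over control).
#' @param p_value Significance of the between-group difference.
#' @return A list with `status` (`up`/`down`/`ns`) and `tier`
#'   (`high`/`medium`/`none`).
#' @export
classify_de <- function(log2fc, p_value) {
  stopifnot(is.finite(log2fc), is.finite(p_value))
  thr <- log2(1.5)
  if (p_value < 0.05 && log2fc <= -thr) {
    list(status = "down", tier = if (log2fc <= -1) "high" else "medium")
  } else if (p_value < 0.05 && log2fc >= thr) {
    list(status = "up", tier = "none")
  } else {
    list(status = "ns", tier = "none")
  }
}

#' Relative quantification by the 2^-ddCt method
#'
#' Stem-loop RT-qPCR quantification: ddCt is the target-minus-reference Ct
#' difference in the treated condition minus the same difference in the
#' control condition; relative expression is `2^-ddCt`.
#'
#' @param ct_target_treated,ct_ref_treated Ct values in the treated
#'   condition (target and reference gene).
#' @param ct_target_control,ct_ref_control Ct values in the control
#'   condition.
#' @return A list with `ddct` and `relative_expression`.
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  stopifnot(is.finite(ct_target_treated), is.finite(ct_ref_treated),
            is.finite(ct_target_control), is.finite(ct_ref_control))
  dd <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  list(ddct = dd, relative_expression = 2^(-dd))
}

#' Count tags attributable to each miRNA
#'
#' A miRNA's count in a library is the sum of counts of tags lying within
#' its mature interval extended by the isomiR window (+/- `isomir_window`
#' nt) on the same strand, capturing ragged-end variants; known miRNAs
#' without a genomic interval fall back to their reference-matched tags.
#'
#' @param records miRNA record data.frame (from [call_novel_mirnas()] or
#'   assembled known records) with `chrom`, `mature_start`, `mature_end`,
#'   `strand`.
#' @param tags Tag table from [collapse_tags()].
#' @param annot A [annotate_tags()] result (for hits and known matches).
#' @param libraries Library count columns of `tags`.
#' @param isomir_window Allowed shift/trim in nt (0-2).
#' @return A numeric matrix, miRNA x library.
#' @export
quantify_mirnas <- function(records, tags, annot,
                            libraries = setdiff(names(tags), c("seq", "total")),
                            isomir_window = 2L) {
  counts <- matrix(0, nrow(records), length(libraries),
                   dimnames = list(records$name, libraries))
  if (nrow(records) == 0L) return(counts)
  hits <- annot$hits
  hd <- if (!is.null(hits) && length(hits)) {
    data.frame(tag = hits$tag,
               chrom = as.character(GenomicRanges::seqnames(hits)),
               start = GenomicRanges::start(hits),
               end = GenomicRanges::end(hits),
               strand = as.character(GenomicRanges::strand(hits)),
               stringsAsFactors = FALSE)
  } else NULL
  ann <- annot$annotation
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    sel_tags <- character()
    if (!is.na(r$mature_start) && !is.null(hd)) {
      in_win <- hd$chrom == r$chrom & hd$strand == r$strand &
        hd$start >= r$mature_start - isomir_window &
        hd$end <= r$mature_end + isomir_window
      sel_tags <- unique(hd$tag[in_win])
    }
    if (r$origin == "known" && !is.na(r$name)) {
      sel_tags <- union(sel_tags,
                        ann$seq[!is.na(ann$matched_id) &
                                  ann$matched_id == r$name])
    }
    if (length(sel_tags)) {
      rows <- match(sel_tags, tags$seq)
      rows <- rows[!is.na(rows)]
      if (length(rows)) {
        counts[i, ] <- colSums(as.matrix(tags[rows, libraries, drop = FALSE]))
      }
    }
  }
  counts
}

#' Build the differential-expression table
#'
#' TPM-normalizes per-miRNA counts against total clean tags, computes group
#' means, fold change, Welch p-values and DE status/tier for every miRNA.
#'
#' @param counts miRNA x library count matrix from [quantify_mirnas()].
#' @param total_clean_tags Named vector of total clean tags per library.
#' @param groups Named vector mapping library to `control`/`mutant`.
#' @param records Optional miRNA record data.frame merged into the output.
#' @param fc_pseudocount Zero-mean guard for [fold_change()].
#' @param test_pseudocount Log-transform pseudocount for [de_test()].
#' @return A `data.frame` with per-library TPM, group means, `fc`,
#'   `log2fc`, `p_value`, `status` and `tier`, ordered by `log2fc`.
#' @export
expression_table <- function(counts, total_clean_tags, groups,
                             records = NULL, fc_pseudocount = 0.01,
                             test_pseudocount = 1) {
  libs <- colnames(counts)
  stopifnot(all(libs %in% names(total_clean_tags)),
            all(libs %in% names(groups)))
  tpm <- sweep(counts, 2L, total_clean_tags[libs], "/") * 1e6
  ctrl <- libs[groups[libs] == "control"]
  mut <- libs[groups[libs] == "mutant"]
  out <- data.frame(name = rownames(counts), stringsAsFactors = FALSE)
  for (lb in libs) out[[paste0("tpm_", lb)]] <- tpm[, lb]
  out$mean_control <- rowMeans(tpm[, ctrl, drop = FALSE])
  out$mean_mutant <- rowMeans(tpm[, mut, drop = FALSE])
  fcs <- lapply(seq_len(nrow(out)), function(i) {
    fold_change(out$mean_mutant[i], out$mean_control[i], fc_pseudocount)
  })
  out$fc <- vapply(fcs, `[[`, 0, "fc")
  out$log2fc <- vapply(fcs, `[[`, 0, "log2fc")
  out$defined <- vapply(fcs, `[[`, TRUE, "defined")
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    de_test(tpm[i, mut], tpm[i, ctrl], test_pseudocount)
  }, 0)
  cls <- lapply(seq_len(nrow(out)), function(i) {
    if (!out$defined[i]) return(list(status = "ns", tier = "none"))
    classify_de(out$log2fc[i], out$p_value[i])
  })
  out$status <- vapply(cls, `[[`, "", "status")
  out$tier <- vapply(cls, `[[`, "", "tier")
  if (!is.null(records)) {
    out <- merge(records, out, by = "name", sort = FALSE)
  }
  out[order(out$log2fc, out$name), , drop = FALSE]
}
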