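#' Pipeline configuration
#'
#' Paths and thresholds for a full run. All stage parameters are validated
#' at construction, before any work is done; unknown arguments are rejected
#' by normal argument matching.
#'
#' @param sample_sheet Tab-separated sample sheet with columns `sample`,
#'   `group` (`control`/`mutant`), `replicate`, `fastq` and the adapter
#'   columns `adapter3`/`adapter5`.
#' @param genome FASTA path of the reference genome.
#' @param annotation Optional GFF3 path (location classes default to
#'   intergenic without it).
#' @param contaminants Optional FASTA of rRNA/snoRNA/snRNA/tRNA stand-ins.
#' @param known_mature Optional FASTA of known mature miRNAs.
#' @param known_precursors Optional FASTA of the recorded precursors of the
#'   known miRNAs (record names are matched by prefix against the mature
#'   names).
#' @param out_dir Output directory for the result tables.
#' @param clean A [clean_params()].
#' @param annotation_opts An [annotation_params()].
#' @param discovery A [discovery_params()].
#' @param isomir_window IsomiR counting window in nt (0-2).
#' @param fc_pseudocount,test_pseudocount Expression-stage pseudocounts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_sheet, genome, annotation = NULL,
                            contaminants = NULL, known_mature = NULL,
                            known_precursors = NULL,
                            out_dir = "srnamir_out",
                            clean = clean_params(),
                            annotation_opts = annotation_params(),
                            discovery = discovery_params(),
                            isomir_window = 2L,
                            fc_pseudocount = 0.01,
                            test_pseudocount = 1) {
  stopifnot(inherits(clean, "clean_params"),
            inherits(annotation_opts, "annotation_params"),
            inherits(discovery, "discovery_params"))
  if (!isomir_window %in% 0:2) stop("isomir_window must be 0, 1 or 2")
  for (p in c(sample_sheet, genome, annotation, contaminants, known_mature,
              known_precursors)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(sample_sheet = sample_sheet, genome = genome,
                 annotation = annotation, contaminants = contaminants,
                 known_mature = known_mature,
                 known_precursors = known_precursors, out_dir = out_dir,
                 clean = clean, annotation_opts = annotation_opts,
                 discovery = discovery,
                 isomir_window = as.integer(isomir_window),
                 fc_pseudocount = fc_pseudocount,
                 test_pseudocount = test_pseudocount),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full small-RNA analysis pipeline
#'
#' Executes clean -> annotate -> discover -> reclassify -> quantify ->
#' classify on the configured libraries and writes every result table
#' (clean tags, cleaning report, tag annotation, novel calls,
#' re-classification, expression with DE tiers, and the summary tables
#' behind the length spectrum, 5'-nucleotide frequency and location
#' breakdown) plus a run log echoing every threshold used. The run is
#' deterministic: re-running an identical configuration reproduces the
#' tables byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all in-memory tables and file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  samples <- stage("config", {
    s <- read.delim(config$sample_sheet, stringsAsFactors = FALSE)
    need <- c("sample", "group", "replicate", "fastq", "adapter3", "adapter5")
    if (!all(need %in% names(s))) {
      stop("sample sheet must have columns: ", paste(need, collapse = ", "))
    }
    s
  })
  libs <- samples$sample
  groups <- setNames(samples$group, libs)

  say("cleaning ", nrow(samples), " libraries")
  inserts <- list(); reasons <- list()
  cleaned <- stage("clean", {
    for (i in seq_len(nrow(samples))) {
      rd <- read_fastq(samples$fastq[i])
      cl <- clean_reads(rd$seq, rd$qual, samples$adapter3[i],
                        samples$adapter5[i], config$clean)
      inserts[[libs[i]]] <- cl$insert[!is.na(cl$insert)]
      reasons[[libs[i]]] <- cl$reason
    }
    list(inserts = inserts, reasons = reasons)
  })
  tags <- stage("collapse", collapse_tags(cleaned$inserts, libs))
  unique_tags <- vapply(libs, function(lb) sum(tags[[lb]] > 0L), 0L)
  report <- cleaning_report(cleaned$reasons, unique_tags)
  total_clean <- setNames(vapply(libs, function(lb) sum(tags[[lb]]), 0), libs)

  say("annotating ", nrow(tags), " clean tags")
  genome <- read_fasta(config$genome)
  features <- if (!is.null(config$annotation)) read_gff3(config$annotation)
  contaminants <- if (!is.null(config$contaminants)) read_fasta(config$contaminants)
  known_mature <- if (!is.null(config$known_mature)) read_fasta(config$known_mature)
  known_prec <- if (!is.null(config$known_precursors)) read_fasta(config$known_precursors)
  annot <- stage("annotate", annotate_tags(tags, contaminants, known_mature,
                                           genome, features,
                                           config$annotation_opts))

  say("evaluating hairpin candidates")
  novel <- stage("discover", call_novel_mirnas(annot, tags, genome, features,
                                               config$discovery))

  known_records <- stage("locate-known", {
    recs <- mirna_record_frame()
    if (!is.null(known_mature) && length(known_mature)) {
      hits <- map_tags_table(as.character(known_mature), genome)
      for (i in seq_along(known_mature)) {
        nm <- names(known_mature)[i]
        sq <- as.character(known_mature[[i]])
        h <- hits[hits$tag == sq, , drop = FALSE]
        rec <- data.frame(
          name = nm, mature_seq = sq, length = nchar(sq),
          arm = NA_character_,
          chrom = if (nrow(h)) h$chrom[1] else NA_character_,
          prec_start = if (nrow(h)) h$start[1] else NA_integer_,
          prec_end = if (nrow(h)) h$end[1] else NA_integer_,
          mature_start = if (nrow(h)) h$start[1] else NA_integer_,
          mature_end = if (nrow(h)) h$end[1] else NA_integer_,
          strand = if (nrow(h)) h$strand[1] else NA_character_,
          origin = "known", stem_loop_group = NA_character_,
          total_count = NA_real_, duplex_mismatches = NA_integer_,
          duplex_bulges = NA_integer_, pairing_fraction = NA_real_,
          score_per_base = NA_real_, clean_cut = NA,
          stringsAsFactors = FALSE)
        rec$location_class <- if (nrow(h) && !is.null(features)) {
          classify_location(GenomicRanges::GRanges(
            h$chrom[1], IRanges::IRanges(h$start[1], h$end[1])), features)
        } else if (nrow(h)) "intergenic" else NA_character_
        recs <- rbind(recs, rec)
      }
    }
    recs
  })

  reclass <- stage("reclassify", {
    rows <- list()
    if (!is.null(known_mature) && length(known_mature)) {
      for (i in seq_along(known_mature)) {
        nm <- names(known_mature)[i]
        prec <- NULL
        if (!is.null(known_prec) && length(known_prec)) {
          j <- which(startsWith(names(known_prec), nm))
          if (length(j)) prec <- as.character(known_prec[[j[1]]])
        }
        rc <- reclassify_reported_mirna(as.character(known_mature[[i]]),
                                        prec, genome, features,
                                        config$discovery)
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, group = ifelse(is.na(rc$group), "unchanged", rc$group),
          reason = ifelse(is.na(rc$reason), "", rc$reason),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(name = character(), group = character(),
                 reason = character(), stringsAsFactors = FALSE)
  })

  # drop novel calls that are the star side of a located known miRNA locus
  if (nrow(novel) && nrow(known_records)) {
    km <- known_records[!is.na(known_records$mature_start), , drop = FALSE]
    if (nrow(km)) {
      ngr <- GenomicRanges::GRanges(novel$chrom,
                                    IRanges::IRanges(novel$prec_start,
                                                     novel$prec_end))
      kgr <- GenomicRanges::GRanges(km$chrom,
                                    IRanges::IRanges(km$mature_start - 200L,
                                                     km$mature_end + 200L))
      dup <- GenomicRanges::countOverlaps(ngr, kgr, ignore.strand = TRUE) > 0L
      novel <- novel[!dup, , drop = FALSE]
      if (nrow(novel)) {
        novel$name <- sprintf("novel-miR%02d", seq_len(nrow(novel)))
      }
    }
  }
  records <- rbind(known_records, novel)

  say("quantifying ", nrow(records), " miRNAs")
  counts <- stage("quantify", quantify_mirnas(records, tags, annot, libs,
                                              config$isomir_window))
  expr <- stage("classify", expression_table(counts, total_clean, groups,
                                             records, config$fc_pseudocount,
                                             config$test_pseudocount))

  annotation_out <- flag_degradation(annot, novel$mature_seq)
  lengths_out <- length_distribution(tags, libs)
  nt_out <- summarize_first_nucleotide(records)
  loc_out <- summarize_locations(records)

  paths <- list(
    clean_tags = write_tsv(tags, file.path(config$out_dir, "clean_tags.tsv")),
    cleaning_report = write_tsv(report, file.path(config$out_dir, "cleaning_report.tsv")),
    annotation = write_tsv(annotation_out, file.path(config$out_dir, "tag_annotation.tsv")),
    novel = write_tsv(novel, file.path(config$out_dir, "novel_mirnas.tsv")),
    reclassification = write_tsv(reclass, file.path(config$out_dir, "reclassification.tsv")),
    expression = write_tsv(expr, file.path(config$out_dir, "expression.tsv")),
    length_distribution = write_tsv(lengths_out, file.path(config$out_dir, "length_distribution.tsv")),
    first_nucleotide = write_tsv(nt_out, file.path(config$out_dir, "first_nucleotide.tsv")),
    locations = write_tsv(loc_out, file.path(config$out_dir, "location_summary.tsv")))

  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c(
    paste0("srnamir ", as.character(utils::packageVersion("srnamir"))),
    paste0("libraries: ", paste(libs, collapse = ", ")),
    "parameters:",
    paste0("  clean.", names(unclass(config$clean)), " = ",
           vapply(unclass(config$clean), paste, "", collapse = ",")),
    paste0("  annotation.", names(unclass(config$annotation_opts)), " = ",
           vapply(unclass(config$annotation_opts), paste, "", collapse = ",")),
    paste0("  discovery.", names(unclass(config$discovery)), " = ",
           vapply(unclass(config$discovery), paste, "", collapse = ",")),
    paste0("  isomir_window = ", config$isomir_window),
    paste0("  fc_pseudocount = ", config$fc_pseudocount),
    paste0("  test_pseudocount = ", config$test_pseudocount))
  writeLines(log_lines, log_path)
  paths$log <- log_path

  invisible(list(tags = tags, report = report, annotation = annotation_out,
                 novel = novel, known = known_records, records = records,
                 reclassification = reclass, counts = counts,
                 total_clean_tags = total_clean, expression = expr,
                 length_distribution = lengths_out,
                 first_nucleotide = nt_out, locations = loc_out,
                 paths = paths))
}

#' 5'-nucleotide frequency of identified miRNAs by length
#'
#' For each mature length 18-24 nt, the proportion of identified miRNAs
#' starting with each base (U reported for T), summing to 1 per length with
#' at least one record.
#'
#' @param records miRNA record data.frame with `mature_seq`.
#' @return A `data.frame` with `length`, `n` and columns `A`, `C`, `G`, `U`.
#' @export
summarize_first_nucleotide <- function(records) {
  lens <- 18:24
  out <- data.frame(length = lens, n = 0L, A = 0, C = 0, G = 0, U = 0)
  if (nrow(records) == 0L) {
    warning("no miRNA records to summarize")
    return(out)
  }
  first <- substr(records$mature_seq, 1L, 1L)
  len <- nchar(records$mature_seq)
  for (i in seq_along(lens)) {
    sel <- len == lens[i]
    out$n[i] <- sum(sel)
    if (!any(sel)) next
    tab <- table(factor(first[sel], levels = c("A", "C", "G", "T")))
    out[i, c("A", "C", "G", "U")] <- as.numeric(tab) / sum(sel)
  }
  out
}

#' Genomic location breakdown of identified miRNAs
#'
#' Counts of records per location class; each record counts once (by its
#' first class when multiple).
#'
#' @param records miRNA record data.frame with `location_class`.
#' @return Named integer vector over intergenic, intron, exon and 3'UTR.
#' @export
summarize_locations <- function(records) {
  classes <- c("intergenic", "intron", "exon", "three_prime_UTR")
  if (nrow(records) == 0L) {
    warning("no miRNA records to summarize")
    return(setNames(integer(length(classes)), classes))
  }
  loc <- vapply(strsplit(records$location_class, ","), `[`, "", 1L)
  tab <- table(factor(loc, levels = classes))
  setNames(as.integer(tab), classes)
}
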