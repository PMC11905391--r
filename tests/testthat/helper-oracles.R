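# Independent oracles used to derive expected values. These deliberately use
# brute-force enumeration, not the package's dynamic-programming code paths.

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# All non-crossing structures over x[i..j] as lists of pair matrices; max
# pair count by explicit enumeration.
enumerate_structures <- function(x, i, j, min_loop = 3L) {
  if (i >= j || j - i <= min_loop) return(list(matrix(0L, 0L, 2L)))
  out <- list()
  for (s in enumerate_structures(x, i + 1L, j, min_loop)) {
    out[[length(out) + 1L]] <- s
  }
  for (k in (i + min_loop + 1L):j) {
    if (!oracle_can_pair(x[i], x[k])) next
    left <- enumerate_structures(x, i + 1L, k - 1L, min_loop)
    right <- enumerate_structures(x, k + 1L, j, min_loop)
    for (a in left) for (b in right) {
      out[[length(out) + 1L]] <- rbind(matrix(c(i, k), 1L, 2L), a, b)
    }
  }
  out
}

oracle_max_pairs <- function(seq, min_loop = 3L) {
  x <- strsplit(toupper(seq), "")[[1]]
  structs <- enumerate_structures(x, 1L, length(x), min_loop)
  max(vapply(structs, nrow, 0L))
}

# Brute-force Hamming substring scan over every offset of every reference.
oracle_match <- function(tag, refs, max_mm) {
  tag_rc <- reverse_complement(tag)
  w <- nchar(tag)
  for (r in seq_along(refs)) {
    ref <- strsplit(refs[[r]], "")[[1]]
    for (q in list(strsplit(tag, "")[[1]], strsplit(tag_rc, "")[[1]])) {
      if (length(ref) < w) next
      for (off in seq_len(length(ref) - w + 1L)) {
        if (sum(ref[off:(off + w - 1L)] != q) <= max_mm) return(names(refs)[r])
      }
    }
  }
  NA_character_
}

# Naive full scan of every genomic offset on both strands.
oracle_map <- function(tag, genome_seq) {
  w <- nchar(tag)
  L <- nchar(genome_seq)
  rc <- reverse_complement(tag)
  starts <- seq_len(L - w + 1L)
  win <- substring(genome_seq, starts, starts + w - 1L)
  hits <- list()
  for (s in starts) {
    if (win[s] == tag) hits[[length(hits) + 1L]] <- c(s, s + w - 1L, "+")
    if (win[s] == rc) hits[[length(hits) + 1L]] <- c(s, s + w - 1L, "-")
  }
  hits
}

# Permutation test on the difference of mean log2(TPM + 1) between groups.
oracle_permutation_p <- function(x, y, pseudo = 1) {
  lx <- log2(x + pseudo); ly <- log2(y + pseudo)
  obs <- abs(mean(lx) - mean(ly))
  all_v <- c(lx, ly)
  n <- length(lx)
  combs <- utils::combn(length(all_v), n)
  stats <- apply(combs, 2L, function(idx) {
    abs(mean(all_v[idx]) - mean(all_v[-idx]))
  })
  mean(stats >= obs - 1e-12)
}

# Dinucleotide-preserving shuffle by a randomized Eulerian walk over the
# dinucleotide multigraph.
dinuc_shuffle <- function(s) {
  x <- strsplit(s, "")[[1]]
  n <- length(x)
  for (attempt in seq_len(2000L)) {
    pool <- lapply(split(x[2:n], x[1:(n - 1L)]), sample)
    out <- character(n)
    out[1] <- x[1]
    cur <- x[1]
    good <- TRUE
    for (i in 2:n) {
      targs <- pool[[cur]]
      if (is.null(targs) || length(targs) == 0L) { good <- FALSE; break }
      out[i] <- targs[1]
      pool[[cur]] <- targs[-1]
      cur <- out[i]
    }
    if (good && all(lengths(pool) == 0L)) return(paste(out, collapse = ""))
  }
  stop("dinucleotide shuffle failed to converge")
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Small shared simulation for module tests (kept tiny for speed).
tiny_sim <- function(seed = 7L) {
  cfg <- sim_config(seed = seed, genome_length = 30000L, n_hairpin_loci = 6L,
                    n_genes = 3L, read_count_per_library = 3000L)
  build_genome(cfg)
}
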