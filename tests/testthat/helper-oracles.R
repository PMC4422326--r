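# Independent brute-force oracles. These deliberately share no code with
# the package internals: naive scans, full DP matrices, and a row-by-row
# Gotoh recurrence are used to cross-check the optimized implementations.

# Naive position-by-position CpG scan.
oracle_cpg_sites <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  out <- integer(0)
  for (p in seq_len(max(0L, length(chars) - 1L))) {
    if (chars[p] == "C" && chars[p + 1] == "G") out <- c(out, p - 1L)
  }
  out
}

# Exhaustive cytosine-context classification.
oracle_classify <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cpg <- top <- bottom <- integer(0)
  for (p in seq_len(n)) {
    if (chars[p] == "C") {
      nxt <- if (p < n) chars[p + 1] else ""
      if (nxt == "G") cpg <- c(cpg, p - 1L)
      else if (nxt != "N") top <- c(top, p - 1L)
    }
    if (chars[p] == "G") {
      prv <- if (p > 1) chars[p - 1] else ""
      if (prv != "C" && prv != "N") bottom <- c(bottom, p - 1L)
    }
  }
  list(cpg_sites = cpg, noncpg_c_top = top, noncpg_c_bottom = bottom)
}

# Full Levenshtein DP matrix (unit costs), no library calls.
oracle_edit_distance <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- min(d[i, j] + (ac[i] != bc[j]),
                           d[i, j + 1] + 1L, d[i + 1, j] + 1L)
  }
  d[n + 1, m + 1]
}

# Minimum edit distance of `barcode` against any prefix of `seq`:
# last row of the DP matrix holds the distance to every prefix.
oracle_prefix_distance <- function(seq, barcode) {
  ac <- strsplit(barcode, "")[[1]]; bc <- strsplit(seq, "")[[1]]
  n <- length(ac); m <- length(bc)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j] + (ac[i] != bc[j]), prev[j + 1] + 1L,
                        cur[j] + 1L)
    }
    prev <- cur
  }
  min(prev)
}

# Oracle demultiplex decision: best forward barcode over both orientations
# by prefix edit distance; ties between samples -> unassigned.
oracle_assign <- function(read, manifest, max_edits = 2L) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  d_f <- vapply(manifest$bc_fwd, function(b) oracle_prefix_distance(read, b),
                numeric(1))
  d_r <- vapply(manifest$bc_fwd, function(b) oracle_prefix_distance(rc, b),
                numeric(1))
  d <- pmin(d_f, d_r)
  if (min(d) > max_edits) return(NA_character_)
  hits <- manifest$sample_id[d == min(d)]
  if (length(unique(hits)) > 1L) return(NA_character_)
  hits[1]
}

# Semi-global Gotoh DP (pattern global, subject local, affine gaps with a
# length-L gap costing open + ext * L). Row-vectorized; returns the score.
oracle_semiglobal <- function(pattern, subject, match = 2, mismatch = -3,
                              open = 5, ext = 2) {
  pc <- strsplit(pattern, "")[[1]]; sc <- strsplit(subject, "")[[1]]
  n <- length(pc); m <- length(sc)
  H_prev <- rep(0, m + 1L)          # row i = 0: free subject prefix
  E_prev <- rep(-Inf, m + 1L)
  js <- 0:m
  for (i in seq_len(n)) {
    E <- pmax(H_prev - open - ext, E_prev - ext)
    sub_scores <- ifelse(pc[i] == sc, match, mismatch)
    H0 <- c(E[1], pmax(H_prev[1:m] + sub_scores, E[-1]))
    # gaps in the pattern (subject base vs '-') via a prefix-max scan
    g <- cummax(H0 + ext * js)
    H <- c(H0[1], pmax(H0[-1], g[1:m] - open - ext * js[-1]))
    E_prev <- E
    H_prev <- H
  }
  max(H_prev)
}

# O(n^2) all-pairs clonal grouping oracle over call vectors.
oracle_clonal_removed <- function(aligned) {
  n <- length(aligned)
  if (n == 0L) return(0L)
  same <- function(a, b) {
    identical(a$strand, b$strand) &&
      identical(unname(a$cpg_calls), unname(b$cpg_calls)) &&
      identical(unname(a$noncpg_vector), unname(b$noncpg_vector))
  }
  assigned <- rep(0L, n)
  ngroups <- 0L
  for (i in seq_len(n)) {
    if (assigned[i] > 0L) next
    ngroups <- ngroups + 1L
    assigned[i] <- ngroups
    if (i < n) for (j in seq(i + 1L, n)) {
      if (assigned[j] == 0L && same(aligned[[i]], aligned[[j]]))
        assigned[j] <- ngroups
    }
  }
  n - ngroups
}

# Random DNA string.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
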