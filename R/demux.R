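#' Read a barcode/sample manifest
#'
#' Loads the TSV manifest mapping samples to their forward/reverse barcodes
#' and universal primers. Columns: `sample_id`, `bc_fwd`, `bc_rev`,
#' `primer_fwd`, `primer_rev`. All barcodes must share one length
#' (18 bp in the standard design). The minimum pairwise Levenshtein distance
#' among all barcodes is computed at load time and attached as attribute
#' `min_barcode_dist`; a manifest whose barcodes are closer than
#' `2 * max_edits + 1` cannot guarantee unambiguous assignment.
#'
#' @param path Path to a tab-separated manifest with a header row.
#' @return A `data.frame` of class `barcode_manifest`.
#' @export
read_barcode_manifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  barcode_manifest(m)
}

#' Construct and validate a barcode manifest
#'
#' @param entries `data.frame` with columns `sample_id`, `bc_fwd`, `bc_rev`,
#'   `primer_fwd`, `primer_rev`.
#' @return The validated `data.frame` with class `barcode_manifest` and
#'   attribute `min_barcode_dist`.
#' @export
barcode_manifest <- function(entries) {
  required <- c("sample_id", "bc_fwd", "bc_rev", "primer_fwd", "primer_rev")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0L)
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  if (nrow(entries) == 0L) stop("manifest has no entries")
  if (anyDuplicated(entries$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(entries$sample_id[duplicated(entries$sample_id)]),
               collapse = ", "))
  for (col in c("bc_fwd", "bc_rev", "primer_fwd", "primer_rev"))
    lapply(entries[[col]], .dna_chars, allow_n = FALSE)
  bc_len <- unique(nchar(c(entries$bc_fwd, entries$bc_rev)))
  if (length(bc_len) != 1L)
    stop("all barcodes must have the same length; found lengths ",
         paste(bc_len, collapse = ", "))
  all_bc <- unique(c(entries$bc_fwd, entries$bc_rev))
  min_dist <- if (length(all_bc) > 1L) {
    d <- utils::adist(all_bc)
    min(d[upper.tri(d)])
  } else NA_integer_
  structure(entries, class = c("barcode_manifest", "data.frame"),
            min_barcode_dist = min_dist, barcode_length = bc_len)
}

## Best Levenshtein distance of `barcode` against any prefix of `window`
## whose length is within +/- max_edits of the barcode length (a shorter or
## longer prefix absorbs indels). Returns list(dist, end): `end` is the
## prefix length achieving the minimum (barcode trim point).
.prefix_edit <- function(window, barcode, max_edits) {
  bl <- nchar(barcode)
  ends <- seq(max(1L, bl - max_edits), min(nchar(window), bl + max_edits))
  if (length(ends) == 0L) return(list(dist = Inf, end = 0L))
  prefixes <- substring(window, 1L, ends)
  d <- as.vector(utils::adist(barcode, prefixes))
  i <- which.min(d)
  list(dist = d[i], end = ends[i])
}

#' Assign a read to a sample by its barcode
#'
#' Tests the 5' end of the read, in both orientations, against every forward
#' barcode in the manifest and returns the unique best match within the edit
#' budget. "Two mismatches" are counted as Levenshtein edit distance, so
#' insertions and deletions count alongside substitutions. The search window
#' is the first `barcode_length + max_edits` bases of the (oriented) read,
#' and the distance is minimised over candidate barcode end points so that
#' indels inside the barcode do not shift the comparison frame.
#'
#' Two distinct samples tying at the minimum distance leave the read
#' unassigned: cross-contaminating a sample is worse than dropping a read.
#'
#' @param read Read sequence (uppercase DNA string).
#' @param manifest A [barcode_manifest].
#' @param max_edits Maximum edit distance per barcode (default 2).
#' @return List with `sample_id` (`NA` if unassigned), `edits`, `orientation`
#'   (`"forward"` or `"reverse-complement"`), and `reason` when unassigned.
#' @export
assign_barcode <- function(read, manifest, max_edits = 2L) {
  stopifnot(inherits(manifest, "barcode_manifest"))
  if (nrow(manifest) == 0L) stop("empty manifest")
  bl <- attr(manifest, "barcode_length")
  if (nchar(read) < bl)
    return(list(sample_id = NA_character_, edits = NA_integer_,
                orientation = NA_character_, reason = "read_shorter_than_barcode"))
  win_len <- bl + max_edits
  oriented <- c(forward = read, `reverse-complement` = .revcomp(read))
  k <- nrow(manifest)
  dist <- numeric(0); sample <- character(0); orient <- character(0)
  for (o in names(oriented)) {
    window <- substr(oriented[[o]], 1L, win_len)
    d <- vapply(manifest$bc_fwd, function(b)
      .prefix_edit(window, b, max_edits)$dist, numeric(1))
    dist <- c(dist, d)
    sample <- c(sample, manifest$sample_id)
    orient <- c(orient, rep(o, k))
  }
  ok <- dist <= max_edits
  if (!any(ok))
    return(list(sample_id = NA_character_, edits = NA_integer_,
                orientation = NA_character_, reason = "no_barcode_match"))
  dmin <- min(dist[ok])
  hits <- which(ok & dist == dmin)
  if (length(unique(sample[hits])) > 1L)
    return(list(sample_id = NA_character_, edits = as.integer(dmin),
                orientation = NA_character_, reason = "ambiguous_barcode_tie"))
  list(sample_id = sample[hits[1]], edits = as.integer(dmin),
       orientation = orient[hits[1]], reason = NA_character_)
}

## Trim barcode (+ primer, when locatable) off the 5' end of an oriented
## sequence. Returns list(seq, cut, primer_found).
.trim_front <- function(seq, barcode, primer, max_edits, max_primer_edits) {
  bc <- .prefix_edit(substr(seq, 1L, nchar(barcode) + max_edits),
                     barcode, max_edits)
  cut <- bc$end
  rest <- substr(seq, cut + 1L, nchar(seq))
  pr <- .prefix_edit(substr(rest, 1L, nchar(primer) + max_primer_edits),
                     primer, max_primer_edits)
  primer_found <- is.finite(pr$dist) && pr$dist <= max_primer_edits
  if (primer_found) {
    cut <- cut + pr$end
    rest <- substr(rest, pr$end + 1L, nchar(rest))
  }
  list(seq = rest, cut = cut, primer_found = primer_found)
}

#' Trim barcode and universal primer from both read ends
#'
#' Orients the read so the forward barcode is at the 5' end, then removes the
#' barcode and the universal primer from the 5' end and the reverse
#' barcode/primer (reverse-complemented) from the 3' end, each at its best
#' sub-alignment within the edit budget. The interior insert is untouched.
#' If a primer cannot be located within `max_primer_edits`, only the barcode
#' is trimmed at that end and the read is flagged `primer_missing`.
#'
#' @param read Read sequence (uppercase DNA string).
#' @param sample_id Sample the read was assigned to.
#' @param orientation `"forward"` or `"reverse-complement"` from
#'   [assign_barcode].
#' @param manifest A [barcode_manifest].
#' @param max_edits Edit budget per barcode (default 2).
#' @param max_primer_edits Edit budget per primer (default 3).
#' @param quals Optional per-base quality string (trimmed in step with the
#'   sequence).
#' @return List with `trimmed_sequence`, `trimmed_quals`, `flags`
#'   (character vector, empty when clean).
#' @export
trim_read <- function(read, sample_id, orientation, manifest,
                      max_edits = 2L, max_primer_edits = 3L, quals = NULL) {
  stopifnot(inherits(manifest, "barcode_manifest"))
  if (is.na(sample_id))
    return(list(trimmed_sequence = read, trimmed_quals = quals,
                flags = "unassigned"))
  row <- manifest[manifest$sample_id == sample_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("sample_id not in manifest: ", sample_id)
  if (identical(orientation, "reverse-complement")) {
    read <- .revcomp(read)
    if (!is.null(quals))
      quals <- paste(rev(strsplit(quals, "", fixed = TRUE)[[1]]), collapse = "")
  }
  flags <- character(0)
  front <- .trim_front(read, row$bc_fwd, row$primer_fwd,
                       max_edits, max_primer_edits)
  if (!front$primer_found) flags <- c(flags, "primer_fwd_missing")
  # 3' end: reverse-complement and trim as a front, then flip back
  rc <- .revcomp(front$seq)
  back <- .trim_front(rc, row$bc_rev, row$primer_rev,
                      max_edits, max_primer_edits)
  if (!back$primer_found) flags <- c(flags, "primer_rev_missing")
  trimmed <- .revcomp(back$seq)
  if (!is.null(quals)) {
    quals <- substr(quals, front$cut + 1L, nchar(read))
    quals <- substr(quals, 1L, nchar(quals) - back$cut)
  }
  list(trimmed_sequence = trimmed, trimmed_quals = quals, flags = flags)
}

#' Minimum-length read filter
#'
#' Retains reads whose trimmed length exceeds `min_len` (strictly, by
#' default: "longer than 50 bp" is read literally; set `inclusive = TRUE`
#' for a >= comparison).
#'
#' @param lengths Integer vector of trimmed read lengths, or a character
#'   vector of sequences.
#' @param min_len Length threshold in bp (default 50).
#' @param inclusive If `TRUE`, keep reads of length exactly `min_len` too.
#' @return Logical vector: `TRUE` for retained reads. Counts in/out are
#'   attached as attribute `counts`.
#' @export
length_filter <- function(lengths, min_len = 50L, inclusive = FALSE) {
  if (is.character(lengths)) lengths <- nchar(lengths)
  keep <- if (inclusive) lengths >= min_len else lengths > min_len
  structure(keep, counts = c(n_in = length(keep), n_out = sum(keep)))
}

#' Demultiplex a FASTQ of barcoded amplicon reads
#'
#' Full demultiplexing pass: assign each read to a sample by its 5' forward
#' barcode (both orientations tested), optionally cross-check the 3' reverse
#' barcode, trim barcodes and universal primers, and apply the minimum-length
#' filter. When both end barcodes are located but point to different samples
#' the read is binned as unassigned with reason `barcode_conflict`.
#'
#' @param fastq Path to a FASTQ file (gzip-transparent), or a named character
#'   vector of read sequences (names = read ids) for in-memory use.
#' @param manifest A [barcode_manifest] or path to a manifest TSV.
#' @param max_edits Edit budget per barcode (default 2).
#' @param min_len Minimum trimmed length in bp, exclusive (default 50).
#' @param max_primer_edits Edit budget per primer (default 3).
#' @param check_rear If `TRUE` (default), demote reads whose 3' barcode
#'   contradicts the 5' assignment.
#' @param outdir Optional directory; when given, writes one FASTQ per sample,
#'   `unassigned.fastq`, and `demux_stats.tsv`.
#' @return List with `reads` (a `data.frame`: read_id, sample_id, sequence,
#'   quals, barcode_edits, orientation, flags, passed_length), and `stats`
#'   (per-sample: n_reads, median_len, mean_edits).
#' @export
demux_reads <- function(fastq, manifest, max_edits = 2L, min_len = 50L,
                        max_primer_edits = 3L, check_rear = TRUE,
                        outdir = NULL) {
  if (is.character(manifest) && length(manifest) == 1L && file.exists(manifest))
    manifest <- read_barcode_manifest(manifest)
  stopifnot(inherits(manifest, "barcode_manifest"))
  if (is.character(fastq) && length(fastq) == 1L && file.exists(fastq)) {
    ss <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                       with.qualities = TRUE)
    seqs <- as.character(ss)
    quals <- as.character(S4Vectors::mcols(ss)$qualities)
    ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  } else {
    ids <- names(fastq)
    seqs <- as.character(fastq)
    if (is.null(ids)) ids <- sprintf("read_%d", seq_along(seqs))
    quals <- rep(NA_character_, length(seqs))
  }

  n <- length(seqs)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- assign_barcode(seqs[i], manifest, max_edits = max_edits)
    sample_id <- a$sample_id
    reason <- a$reason
    if (!is.na(sample_id) && check_rear) {
      # locate the rear (reverse) barcode on the oriented read and demand
      # agreement when it is found within the same edit budget
      oriented <- if (identical(a$orientation, "reverse-complement"))
        .revcomp(seqs[i]) else seqs[i]
      tail_rc <- .revcomp(substr(oriented,
                                 max(1L, nchar(oriented) - attr(manifest, "barcode_length") - max_edits + 1L),
                                 nchar(oriented)))
      d_rear <- vapply(manifest$bc_rev, function(b)
        .prefix_edit(tail_rc, b, max_edits)$dist, numeric(1))
      if (any(d_rear <= max_edits)) {
        best_rear <- manifest$sample_id[which(d_rear == min(d_rear))]
        if (!(sample_id %in% best_rear)) {
          sample_id <- NA_character_
          reason <- "barcode_conflict"
        }
      }
    }
    q <- if (is.na(quals[i])) NULL else quals[i]
    tr <- trim_read(seqs[i], sample_id, a$orientation, manifest,
                    max_edits = max_edits, max_primer_edits = max_primer_edits,
                    quals = q)
    out[[i]] <- data.frame(
      read_id = ids[i],
      sample_id = if (is.na(sample_id)) "unassigned" else sample_id,
      sequence = tr$trimmed_sequence,
      quals = if (is.null(tr$trimmed_quals)) NA_character_ else tr$trimmed_quals,
      barcode_edits = a$edits,
      orientation = if (is.na(a$orientation)) NA_character_ else a$orientation,
      flags = paste(c(tr$flags, if (!is.na(reason)) reason), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out)
  if (is.null(reads))
    reads <- data.frame(read_id = character(0), sample_id = character(0),
                        sequence = character(0), quals = character(0),
                        barcode_edits = integer(0), orientation = character(0),
                        flags = character(0))
  assigned <- reads$sample_id != "unassigned"
  reads$passed_length <- FALSE
  reads$passed_length[assigned] <-
    as.logical(length_filter(reads$sequence[assigned], min_len = min_len))

  stats <- do.call(rbind, lapply(split(reads, reads$sample_id), function(g)
    data.frame(sample = g$sample_id[1], n_reads = nrow(g),
               median_len = stats::median(nchar(g$sequence)),
               mean_edits = mean(g$barcode_edits, na.rm = TRUE))))
  rownames(stats) <- NULL

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (s in unique(reads$sample_id)) {
      g <- reads[reads$sample_id == s &
                   (s == "unassigned" | reads$passed_length), , drop = FALSE]
      .write_fastq(g$sequence, g$read_id, g$quals,
                   file.path(outdir, paste0(s, ".fastq")))
    }
    utils::write.table(stats, file.path(outdir, "demux_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(reads = reads, stats = stats)
}

## FASTQ writer for in-memory character data (constant quality when absent).
.write_fastq <- function(seqs, ids, quals = NULL, path) {
  if (length(seqs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (is.null(quals) || all(is.na(quals)))
    quals <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}
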