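#' Alignment scoring parameters
#'
#' Scoring used by the semi-global (free end-gaps on the reference)
#' three-letter bisulfite alignment. A gap of length L costs
#' `gap_open + gap_extend * L`. The defaults are this package's own choice
#' for CCS-accuracy amplicon reads; all are exposed here.
#'
#' @param match Match score (default +2).
#' @param mismatch Mismatch score (default -3).
#' @param gap_open Gap opening penalty, positive (default 5).
#' @param gap_extend Per-base gap extension penalty, positive (default 2).
#' @param min_identity Minimum identity in converted space for a read to be
#'   reported as aligned (default 0.7). Identity is matches divided by
#'   alignment columns (matches + mismatches + gapped columns).
#' @return List of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = 5,
                         gap_extend = 2, min_identity = 0.7) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            min_identity >= 0, min_identity <= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity),
            class = "align_params")
}

CALL_LEVELS <- c("METH", "UNMETH", "AMBIG", "UNCOVERED")
CONV_LEVELS <- c("CONVERTED", "RETAINED", "AMBIG", "UNCOVERED")

## Collapse a read into three-letter space for the given strand.
.collapse_read <- function(seqs, strand) {
  if (strand == "top") chartr("C", "T", seqs) else chartr("G", "A", seqs)
}

## Column walk of a gapped alignment: returns 0-based reference positions
## covered and the original read base over each (NA at deletions), plus the
## covered span [start, end) in 0-based reference coordinates.
.walk_alignment <- function(pattern_gapped, subject_gapped, subject_start,
                            oriented_read) {
  pc <- strsplit(pattern_gapped, "", fixed = TRUE)[[1]]
  sc <- strsplit(subject_gapped, "", fixed = TRUE)[[1]]
  if (length(pc) != length(sc))
    stop("gapped pattern and subject have different lengths")
  scol <- sc != "-"
  pcol <- pc != "-"
  ref_pos0 <- cumsum(scol) + subject_start - 2L   # 0-based where scol TRUE
  read_pos0 <- cumsum(pcol) - 1L                  # 0-based where pcol TRUE
  idx <- which(scol)
  rchars <- strsplit(oriented_read, "", fixed = TRUE)[[1]]
  base <- rep(NA_character_, length(idx))
  has_base <- pcol[idx]
  base[has_base] <- rchars[read_pos0[idx][has_base] + 1L]
  span_start <- subject_start - 1L
  span_end <- span_start + sum(scol)
  list(ref_pos0 = ref_pos0[idx], base = base,
       span = c(span_start, span_end),
       n_columns = length(pc), n_gap_cols = sum(!scol) + sum(!pcol))
}

#' Extract per-cytosine methylation evidence from an alignment
#'
#' Reads the original (uncollapsed) base over every reference cytosine of
#' the aligned strand and classifies it. On the top strand a CpG cytosine
#' read as `C` is METH and as `T` is UNMETH; on the bottom strand the
#' informative base is the guanine paired with the CpG cytosine (forward
#' coordinate `p + 1`), read as `G` (METH) or `A` (UNMETH). Non-CpG
#' cytosines are classified RETAINED/CONVERTED the same way and feed the
#' per-read conversion rate. Any other base, or a deletion over the
#' position, is AMBIG; positions outside the aligned span are UNCOVERED.
#' Insertions in the read contribute no evidence (no reference coordinate).
#'
#' CpG calls are always keyed by the forward-strand C position, whichever
#' strand the read covers, so both strands report the same biological site.
#'
#' @param alignment List describing a gapped alignment: `pattern` and
#'   `subject` (equal-length gapped strings, `-` for gaps; only the gap
#'   structure of `pattern` is used for read-position bookkeeping, so it may
#'   be in converted space), `subject_start` (1-based reference position of
#'   the first aligned subject base), and `strand` (`"top"` or `"bottom"`).
#' @param read The oriented original read sequence (same orientation as the
#'   aligned pattern, before C/T or G/A collapsing).
#' @param ref An [amplicon_reference].
#' @return List with `cpg_calls` and `noncpg_vector`: named character
#'   vectors over the reference's full site maps, names = 0-based positions.
#' @export
call_methylation <- function(alignment, read, ref) {
  stopifnot(inherits(ref, "amplicon_reference"))
  strand <- match.arg(alignment$strand, c("top", "bottom"))
  walk <- .walk_alignment(alignment$pattern, alignment$subject,
                          alignment$subject_start, read)
  len <- ref$length
  covered <- rep(FALSE, len)
  bmap <- rep(NA_character_, len)
  covered[walk$ref_pos0 + 1L] <- TRUE
  bmap[walk$ref_pos0 + 1L] <- walk$base

  classify <- function(pos_evidence, pos_key, meth_base, unmeth_base,
                       levels_pair) {
    out <- rep("UNCOVERED", length(pos_evidence))
    inside <- pos_evidence >= 0L & pos_evidence < len & covered[pos_evidence + 1L]
    b <- bmap[pos_evidence[inside] + 1L]
    cl <- rep("AMBIG", length(b))
    cl[!is.na(b) & b == meth_base] <- levels_pair[1]
    cl[!is.na(b) & b == unmeth_base] <- levels_pair[2]
    out[inside] <- cl
    names(out) <- pos_key
    out
  }

  if (strand == "top") {
    cpg_calls <- classify(ref$cpg_sites, ref$cpg_sites, "C", "T",
                          c("METH", "UNMETH"))
    noncpg <- classify(ref$noncpg_c_top, ref$noncpg_c_top, "C", "T",
                       c("RETAINED", "CONVERTED"))
  } else {
    cpg_calls <- classify(ref$cpg_sites + 1L, ref$cpg_sites, "G", "A",
                          c("METH", "UNMETH"))
    noncpg <- classify(ref$noncpg_c_bottom, ref$noncpg_c_bottom, "G", "A",
                       c("RETAINED", "CONVERTED"))
  }
  list(cpg_calls = cpg_calls, noncpg_vector = noncpg)
}

## Internal: candidate descriptors (amplicon x strand x orientation) with
## collapsed patterns ready for alignment.
.alignment_candidates <- function(seqs, refs, params, orientations) {
  fwd <- Biostrings::DNAStringSet(seqs)
  orient_seqs <- list(forward = as.character(fwd))
  if ("reverse-complement" %in% orientations)
    orient_seqs[["reverse-complement"]] <-
      as.character(Biostrings::reverseComplement(fwd))
  cands <- list()
  for (ref in refs) for (strand in c("top", "bottom")) {
    conv_ref <- convert_reference(ref, strand)$converted_sequence
    for (orient in names(orient_seqs)) {
      cands[[length(cands) + 1L]] <- list(
        amplicon_id = ref$id, strand = strand, orientation = orient,
        subject = conv_ref,
        patterns = .collapse_read(orient_seqs[[orient]], strand),
        oriented = orient_seqs[[orient]])
    }
  }
  cands
}

.submat <- function(params) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
}

#' Align reads to bisulfite-converted amplicon references
#'
#' For each read, evaluates four candidates per amplicon (read and its
#' reverse complement, against the C-to-T converted top strand and the
#' G-to-A converted bottom strand), with the read collapsed into the same
#' three-letter space so that bisulfite conversion is alignment-neutral.
#' The best-scoring semi-global alignment wins; methylation state is then
#' read back from the original, uncollapsed bases via [call_methylation].
#'
#' A read whose best score is tied between two different amplicons is
#' discarded as ambiguous (multiplexed amplicons must not cross-contaminate);
#' a tie between candidates of the same amplicon is broken deterministically
#' (top before bottom, forward before reverse-complement). Reads whose best
#' identity falls below `params$min_identity` are reported unaligned.
#'
#' @param reads A `data.frame` with columns `read_id`, `sample_id`,
#'   `sequence` (as produced by [demux_reads]), or a named character vector
#'   of sequences.
#' @param refs Named list of [amplicon_reference] objects (or a single one).
#' @param params An [align_params] list.
#' @param orientations Orientations to evaluate. Defaults to both; reads
#'   already oriented upstream (e.g. by [demux_reads], which flips
#'   reverse-complement reads while trimming) can be aligned with
#'   `"forward"` only, halving the candidate set.
#' @return List with `aligned` (list of `aligned_read` objects: read_id,
#'   sample_id, amplicon_id, strand, orientation, start/end 0-based span,
#'   score, identity, cpg_calls, noncpg_vector) and `unaligned`
#'   (`data.frame` of read_id, reason).
#' @export
align_reads <- function(reads, refs, params = align_params(),
                        orientations = c("forward", "reverse-complement")) {
  if (inherits(refs, "amplicon_reference")) refs <- list(refs)
  if (length(refs) == 0L) stop("no amplicon references loaded")
  orientations <- match.arg(orientations, c("forward", "reverse-complement"),
                            several.ok = TRUE)
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("read_%d", seq_along(reads))
    reads <- data.frame(read_id = ids, sample_id = NA_character_,
                        sequence = as.character(reads),
                        stringsAsFactors = FALSE)
  }
  aligned <- list()
  unaligned <- data.frame(read_id = character(0), reason = character(0))
  if (nrow(reads) == 0L) return(list(aligned = aligned, unaligned = unaligned))
  keep <- nchar(reads$sequence) > 0L
  if (any(!keep))
    unaligned <- rbind(unaligned, data.frame(
      read_id = reads$read_id[!keep],
      reason = rep("empty_sequence", sum(!keep))))
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0L) return(list(aligned = aligned, unaligned = unaligned))

  n <- nrow(reads)
  submat <- .submat(params)
  cands <- .alignment_candidates(reads$sequence, refs, params, orientations)
  # pass 1: scores only, all candidates
  scores <- vapply(cands, function(cc)
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(cc$patterns),
      Biostrings::DNAString(cc$subject), type = "global-local",
      substitutionMatrix = submat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, scoreOnly = TRUE),
    numeric(n))
  if (n == 1L) scores <- matrix(scores, nrow = 1L)

  best <- apply(scores, 1L, max)
  winner <- integer(n)      # candidate index; 0 = ambiguous across amplicons
  cand_amp <- vapply(cands, `[[`, character(1), "amplicon_id")
  for (i in seq_len(n)) {
    hit <- which(scores[i, ] == best[i])
    if (length(unique(cand_amp[hit])) > 1L) {
      winner[i] <- 0L
    } else {
      winner[i] <- hit[1]   # candidate order is deterministic
    }
  }
  if (any(winner == 0L))
    unaligned <- rbind(unaligned, data.frame(
      read_id = reads$read_id[winner == 0L],
      reason = rep("ambiguous_amplicon", sum(winner == 0L))))

  ref_ids <- vapply(refs, `[[`, character(1), "id")
  results <- vector("list", n)
  # pass 2: full alignment of each read against its winning candidate only
  for (j in sort(unique(winner[winner > 0L]))) {
    idx <- which(winner == j)
    cc <- cands[[j]]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(cc$patterns[idx]),
      Biostrings::DNAString(cc$subject), type = "global-local",
      substitutionMatrix = submat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend)
    pats <- as.character(Biostrings::alignedPattern(aln))
    subs <- as.character(Biostrings::alignedSubject(aln))
    sstarts <- Biostrings::start(Biostrings::subject(aln))
    nmatches <- Biostrings::nmatch(aln)
    ref <- refs[[match(cc$amplicon_id, ref_ids)]]
    for (k in seq_along(idx)) {
      i <- idx[k]
      identity <- nmatches[k] / nchar(pats[k])
      if (identity < params$min_identity) {
        unaligned <- rbind(unaligned, data.frame(
          read_id = reads$read_id[i], reason = "low_identity"))
        next
      }
      calls <- call_methylation(
        list(pattern = pats[k], subject = subs[k],
             subject_start = sstarts[k], strand = cc$strand),
        cc$oriented[i], ref)
      n_sub_aligned <- sum(strsplit(subs[k], "", fixed = TRUE)[[1]] != "-")
      results[[i]] <- structure(list(
        read_id = reads$read_id[i], sample_id = reads$sample_id[i],
        amplicon_id = cc$amplicon_id, strand = cc$strand,
        orientation = cc$orientation,
        start = sstarts[k] - 1L, end = sstarts[k] - 1L + n_sub_aligned,
        score = best[i], identity = identity,
        cpg_calls = calls$cpg_calls, noncpg_vector = calls$noncpg_vector),
        class = "aligned_read")
    }
  }
  aligned <- results[!vapply(results, is.null, logical(1))]
  list(aligned = aligned, unaligned = unaligned)
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads] for one sequence.
#'
#' @param read A single read sequence (character).
#' @param refs Named list of [amplicon_reference] objects.
#' @param params An [align_params] list.
#' @param read_id,sample_id Identifiers attached to the result.
#' @return An `aligned_read` object, or `NULL` with attribute `reason` if
#'   the read could not be aligned.
#' @export
align_read <- function(read, refs, params = align_params(),
                       read_id = "read", sample_id = NA_character_) {
  res <- align_reads(data.frame(read_id = read_id, sample_id = sample_id,
                                sequence = read, stringsAsFactors = FALSE),
                     refs, params)
  if (length(res$aligned) == 1L) return(res$aligned[[1]])
  structure(NULL, reason = if (nrow(res$unaligned)) res$unaligned$reason[1]
                           else "unaligned")
}

#' @export
print.aligned_read <- function(x, ...) {
  cat(sprintf("aligned_read %s -> %s [%s/%s] span [%d,%d) score %.1f identity %.3f\n",
              x$read_id, x$amplicon_id, x$strand, x$orientation,
              x$start, x$end, x$score, x$identity))
  invisible(x)
}

#' Write per-read methylation calls as TSV
#'
#' One row per read x covered cytosine position with its call. Positions are
#' reported 1-based (stated in the header).
#'
#' @param aligned List of `aligned_read` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_read_calls_tsv <- function(aligned, path) {
  rows <- lapply(aligned, function(a) {
    cpg <- a$cpg_calls[a$cpg_calls != "UNCOVERED"]
    non <- a$noncpg_vector[a$noncpg_vector != "UNCOVERED"]
    data.frame(
      read_id = a$read_id, amplicon = a$amplicon_id, strand = a$strand,
      site_1based = c(as.integer(names(cpg)), as.integer(names(non))) + 1L,
      context = rep(c("CpG", "non-CpG"), c(length(cpg), length(non))),
      call = c(unname(cpg), unname(non)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
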