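DNA_ALPHABET <- c("A", "C", "G", "T", "N")

## Validate an uppercase DNA string; returns the per-base character vector.
## Errors name the first offending position (1-based, as in all user messages).
.dna_chars <- function(sequence, allow_n = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single character string")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  allowed <- if (allow_n) DNA_ALPHABET else DNA_ALPHABET[1:4]
  bad <- which(!(chars %in% allowed))
  if (length(bad) > 0L)
    stop(sprintf("invalid base '%s' at position %d (expected one of %s)",
                 chars[bad[1]], bad[1], paste(allowed, collapse = "/")))
  chars
}

#' Locate CpG sites in a DNA sequence
#'
#' Scans an uppercase DNA sequence for CpG dinucleotides and returns the
#' 0-based position of the cytosine of each CpG on the forward strand.
#' CpG is palindromic, so one forward-strand coordinate indexes the
#' biological site on both strands.
#'
#' @param sequence Single uppercase DNA string over `A/C/G/T/N`.
#' @return Strictly increasing integer vector of 0-based positions `p` with
#'   `substr(sequence, p + 1, p + 2) == "CG"`.
#' @examples
#' find_cpg_sites("ACGCGT")  # 1, 3
#' @export
find_cpg_sites <- function(sequence) {
  chars <- .dna_chars(sequence)
  n <- length(chars)
  if (n < 2L) return(integer(0))
  is_c <- chars[-n] == "C"
  is_g <- chars[-1L] == "G"
  which(is_c & is_g) - 1L
}

#' Classify cytosine context on both strands
#'
#' Partitions forward-strand cytosines into CpG and non-CpG context, and
#' identifies reverse-strand non-CpG cytosines (forward-strand guanines not
#' part of a CpG). Non-CpG cytosines are the informative positions for
#' per-read bisulfite conversion-rate estimation; CpG cytosines carry the
#' methylation signal.
#'
#' Positions whose dinucleotide context involves an `N` are excluded from all
#' maps. A terminal forward-strand `C` (no following base) is classified
#' non-CpG, as is a leading `G` on the reverse strand.
#'
#' @inheritParams find_cpg_sites
#' @return List with integer vectors of 0-based positions:
#'   `cpg_sites` (forward C of each CpG), `noncpg_c_top` (forward-strand
#'   non-CpG C), `noncpg_c_bottom` (reverse-strand non-CpG C, reported at the
#'   forward-strand G coordinate).
#' @examples
#' classify_cytosines("ACTG")
#' @export
classify_cytosines <- function(sequence) {
  chars <- .dna_chars(sequence)
  n <- length(chars)
  nxt <- c(chars[-1L], "")   # base after each position ("" past the end)
  prv <- c("", chars[-n])    # base before each position
  cpg <- which(chars == "C" & nxt == "G") - 1L
  noncpg_top <- which(chars == "C" & nxt != "G" & nxt != "N") - 1L
  noncpg_bottom <- which(chars == "G" & prv != "C" & prv != "N") - 1L
  list(cpg_sites = as.integer(cpg),
       noncpg_c_top = as.integer(noncpg_top),
       noncpg_c_bottom = as.integer(noncpg_bottom))
}

#' Construct an amplicon reference
#'
#' Builds the reference object used throughout the pipeline: the amplicon
#' sequence together with precomputed coordinate maps of CpG sites and
#' strand-specific non-CpG cytosines. All coordinates are 0-based internally;
#' exported tables are 1-based.
#'
#' @param id Amplicon identifier.
#' @param sequence Uppercase DNA string.
#' @return Object of class `amplicon_reference`: list with `id`, `sequence`,
#'   `length`, `cpg_sites`, `noncpg_c_top`, `noncpg_c_bottom`.
#' @examples
#' ref <- amplicon_reference("amp1", "AACGTTCG")
#' ref$cpg_sites
#' @export
amplicon_reference <- function(id, sequence) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string")
  maps <- classify_cytosines(sequence)
  structure(
    c(list(id = id, sequence = sequence, length = nchar(sequence)), maps),
    class = "amplicon_reference")
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("amplicon_reference '%s': %d bp, %d CpG sites, %d/%d non-CpG C (top/bottom)\n",
              x$id, x$length, length(x$cpg_sites),
              length(x$noncpg_c_top), length(x$noncpg_c_bottom)))
  invisible(x)
}

#' Read amplicon references from FASTA
#'
#' Loads a multi-record FASTA of amplicon sequences. The amplicon id is the
#' first whitespace-delimited token of each record header.
#'
#' @param path Path to a FASTA file.
#' @return Named list of [amplicon_reference] objects.
#' @export
read_amplicon_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate amplicon ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  refs <- lapply(seq_along(seqs), function(i)
    amplicon_reference(ids[i], toupper(as.character(seqs[[i]]))))
  names(refs) <- ids
  refs
}

#' Write amplicon references to FASTA
#'
#' @param refs Named list of [amplicon_reference] objects.
#' @param path Output FASTA path.
#' @export
write_amplicon_fasta <- function(refs, path) {
  seqs <- Biostrings::DNAStringSet(vapply(refs, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(refs, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' In-silico bisulfite conversion of a reference strand
#'
#' Produces the fully converted reference used for three-letter alignment:
#' on the top strand every `C` becomes `T`; on the bottom strand (represented
#' in forward-strand coordinates) every `G` becomes `A`.
#'
#' @param ref An [amplicon_reference].
#' @param strand `"top"` or `"bottom"`.
#' @return Object of class `converted_reference`: list with `amplicon_id`,
#'   `strand`, `converted_sequence`.
#' @examples
#' convert_reference(amplicon_reference("a", "ACGT"), "top")$converted_sequence
#' @export
convert_reference <- function(ref, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  stopifnot(inherits(ref, "amplicon_reference"))
  conv <- if (strand == "top") chartr("C", "T", ref$sequence)
          else chartr("G", "A", ref$sequence)
  structure(list(amplicon_id = ref$id, strand = strand,
                 converted_sequence = conv),
            class = "converted_reference")
}

#' Export CpG site coordinates as BED6
#'
#' Writes one BED6 line per CpG site (0-based half-open, the single C base of
#' each CpG on the forward strand), suitable for genome-browser style use.
#'
#' @param refs Named list of [amplicon_reference] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cpg_bed <- function(refs, path) {
  rows <- lapply(refs, function(r) {
    if (length(r$cpg_sites) == 0L) return(NULL)
    data.frame(chrom = r$id, start = r$cpg_sites, end = r$cpg_sites + 1L,
               name = sprintf("%s_CpG_%d", r$id, seq_along(r$cpg_sites)),
               score = 0L, strand = "+")
  })
  bed <- do.call(rbind, rows)
  if (is.null(bed)) bed <- data.frame()
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Reverse complement of a plain character DNA string.
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
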