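#' Run the full analysis pipeline
#'
#' Demultiplex, trim and length-filter barcoded reads, align them to the
#' bisulfite-converted amplicon references, apply the conversion-rate and
#' clonal-artifact filters per sample x amplicon, and quantify per-CpG
#' methylation with the depth gate.
#'
#' @param fastq Path to a FASTQ file, or a named character vector of read
#'   sequences.
#' @param refs Named list of [amplicon_reference] objects, or a FASTA path.
#' @param manifest A [barcode_manifest] or manifest TSV path.
#' @param max_edits Barcode edit budget (default 2).
#' @param min_len Minimum trimmed read length, exclusive (default 50).
#' @param min_conversion Conversion-rate threshold (default 0.95).
#' @param min_depth Site depth gate (default 10).
#' @param drop_clones Remove clonal duplicates (default `TRUE`).
#' @param align Params from [align_params].
#' @param outdir Optional directory for TSV outputs (`methylation.tsv`,
#'   `filter_report.tsv`, `demux_stats.tsv`).
#' @return List with `profiles` (named list of `methylation_profile`, names
#'   `"sample.amplicon"`), `filter_reports` (named list of `filter_report`),
#'   `demux` (output of [demux_reads]), and `unaligned` (`data.frame`).
#' @export
run_pipeline <- function(fastq, refs, manifest, max_edits = 2L,
                         min_len = 50L, min_conversion = 0.95,
                         min_depth = 10L, drop_clones = TRUE,
                         align = align_params(), outdir = NULL) {
  if (is.character(refs) && length(refs) == 1L && file.exists(refs))
    refs <- read_amplicon_fasta(refs)
  dm <- demux_reads(fastq, manifest, max_edits = max_edits,
                    min_len = min_len)
  usable <- dm$reads[dm$reads$sample_id != "unassigned" &
                       dm$reads$passed_length, , drop = FALSE]
  # demux_reads already flips reverse-complement reads into forward
  # orientation during trimming, so only forward candidates are needed
  al <- align_reads(usable, refs, params = align, orientations = "forward")

  by_group <- split(al$aligned, vapply(al$aligned, function(a)
    paste(a$sample_id, a$amplicon_id, sep = "."), character(1)))
  profiles <- list()
  reports <- list()
  for (key in names(by_group)) {
    grp <- by_group[[key]]
    amp <- grp[[1]]$amplicon_id
    flt <- apply_read_filters(grp, min_conversion = min_conversion,
                              drop_clones = drop_clones)
    reports[[key]] <- flt$report
    profiles[[key]] <- quantify(flt$pass, refs[[amp]], min_depth = min_depth,
                                sample_id = grp[[1]]$sample_id)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_profile_tsv(profiles, file.path(outdir, "methylation.tsv"))
    write_filter_report_tsv(reports, file.path(outdir, "filter_report.tsv"))
    utils::write.table(dm$stats, file.path(outdir, "demux_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(profiles = profiles, filter_reports = reports, demux = dm,
       unaligned = al$unaligned)
}
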