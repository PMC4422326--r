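#' Per-read bisulfite conversion rate
#'
#' Fraction of covered, unambiguous non-CpG cytosines read as converted:
#' `CONVERTED / (CONVERTED + RETAINED)`. Non-CpG cytosines are expected to
#' be unmethylated, so incomplete conversion shows up directly in this
#' statistic. A read with no informative non-CpG cytosine has an undefined
#' rate and is returned as `NA` with attribute `flag = "no_conversion_evidence"`.
#'
#' @param aligned An `aligned_read` (from [align_reads]) or a bare character
#'   vector of non-CpG calls (`CONVERTED`/`RETAINED`/`AMBIG`/`UNCOVERED`).
#' @return Numeric fraction in `[0, 1]`, or flagged `NA`.
#' @export
conversion_rate <- function(aligned) {
  v <- if (inherits(aligned, "aligned_read")) aligned$noncpg_vector else aligned
  n_conv <- sum(v == "CONVERTED")
  n_ret <- sum(v == "RETAINED")
  denom <- n_conv + n_ret
  if (denom == 0L)
    return(structure(NA_real_, flag = "no_conversion_evidence"))
  n_conv / denom
}

#' Filter reads by bisulfite conversion rate
#'
#' Passes reads whose conversion rate is at least `threshold` (the boundary
#' is inclusive: reads at exactly the threshold pass, because only rates
#' strictly below it indicate conversion failure). Reads with no informative
#' non-CpG cytosines cannot be verified and fail by default
#' (`fail_unverifiable = TRUE`).
#'
#' @param aligned List of `aligned_read` objects.
#' @param threshold Minimum conversion rate (default 0.95).
#' @param fail_unverifiable Whether reads with an undefined rate fail
#'   (default `TRUE`).
#' @return List with `pass` and `fail` (lists of `aligned_read`), `rates`
#'   (numeric, NA where undefined, in input order), and `n_flagged`.
#' @export
filter_by_conversion <- function(aligned, threshold = 0.95,
                                 fail_unverifiable = TRUE) {
  rates <- vapply(aligned, function(a) as.numeric(conversion_rate(a)),
                  numeric(1))
  undef <- is.na(rates)
  ok <- !undef & rates >= threshold
  if (!fail_unverifiable) ok <- ok | undef
  list(pass = aligned[ok], fail = aligned[!ok],
       rates = rates, n_flagged = sum(undef))
}

## Canonical per-read pattern key: full CpG + non-CpG call vectors over the
## amplicon site map, including UNCOVERED (identical spans required).
.pattern_key <- function(a) {
  paste(a$strand,
        paste(a$cpg_calls, collapse = ""),
        paste(a$noncpg_vector, collapse = ""), sep = "|")
}

#' Detect clonal PCR artifacts
#'
#' Groups reads of one sample x amplicon whose CpG calls and non-CpG
#' cytosine calls are identical across the full amplicon site map
#' (including uncovered positions, i.e. identical aligned spans) on the same
#' strand. Reads from PCR copies of a single original molecule share the
#' complete cytosine pattern, whereas independent molecules essentially
#' never do once an amplicon carries more than a handful of stochastically
#' converted positions. A group of size k contributes k - 1 removable
#' clones; one representative per group is retained.
#'
#' Grouping is order-invariant; the retained representative is the first
#' read after a stable sort by `read_id`, so results do not depend on input
#' order.
#'
#' @param aligned List of `aligned_read` objects for one sample x amplicon.
#' @return List with `groups` (list of integer index vectors into the input,
#'   each sorted by read_id), `keep` (logical vector: representative or
#'   singleton), and `n_clonal` (number of removable clones).
#' @export
detect_clonal <- function(aligned) {
  n <- length(aligned)
  if (n == 0L)
    return(list(groups = list(), keep = logical(0), n_clonal = 0L))
  keys <- vapply(aligned, .pattern_key, character(1))
  ids <- vapply(aligned, `[[`, character(1), "read_id")
  groups <- split(seq_len(n), keys)
  groups <- lapply(groups, function(g) g[order(ids[g])])
  names(groups) <- NULL
  keep <- rep(FALSE, n)
  for (g in groups) keep[g[1]] <- TRUE
  list(groups = groups, keep = keep, n_clonal = n - length(groups))
}

#' Apply conversion-rate and clonal filters
#'
#' The two read-level filters applied in order: conversion-rate filtering
#' first, then clonal-artifact detection among the survivors. The
#' accompanying report conserves reads exactly:
#' `n_input = n_low_conversion + n_clonal_removed + n_pass`.
#'
#' @param aligned List of `aligned_read` objects for one sample x amplicon.
#' @param min_conversion Conversion-rate threshold (default 0.95).
#' @param drop_clones Whether to remove clonal duplicates (default `TRUE`).
#' @param drop_all_clones If `TRUE`, removes every member of each clonal
#'   group instead of retaining one representative (default `FALSE`).
#' @param fail_unverifiable Passed to [filter_by_conversion].
#' @return List with `pass` (list of `aligned_read`) and `report` (class
#'   `filter_report`: n_input, n_low_conversion, n_clonal_removed, n_pass,
#'   mean_conversion_before, mean_conversion_after).
#' @export
apply_read_filters <- function(aligned, min_conversion = 0.95,
                               drop_clones = TRUE, drop_all_clones = FALSE,
                               fail_unverifiable = TRUE) {
  n_input <- length(aligned)
  conv <- filter_by_conversion(aligned, threshold = min_conversion,
                               fail_unverifiable = fail_unverifiable)
  mean_before <- if (n_input > 0L) mean(conv$rates, na.rm = TRUE) else NA_real_
  surv <- conv$pass
  n_low <- n_input - length(surv)
  if (drop_clones && length(surv) > 0L) {
    cl <- detect_clonal(surv)
    keep <- if (drop_all_clones) {
      sizes <- lengths(cl$groups)
      singleton <- logical(length(surv))
      for (g in cl$groups[sizes == 1L]) singleton[g] <- TRUE
      singleton
    } else cl$keep
    n_clonal <- length(surv) - sum(keep)
    surv <- surv[keep]
  } else {
    n_clonal <- 0L
  }
  rates_after <- vapply(surv, function(a) as.numeric(conversion_rate(a)),
                        numeric(1))
  mean_after <- if (length(surv) > 0L) mean(rates_after, na.rm = TRUE)
                else NA_real_
  report <- structure(list(
    n_input = n_input, n_low_conversion = n_low,
    n_clonal_removed = n_clonal, n_pass = length(surv),
    mean_conversion_before = mean_before,
    mean_conversion_after = mean_after), class = "filter_report")
  list(pass = surv, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "filter_report: %d reads in; %d below conversion threshold; ",
    "%d clonal removed; %d pass\n",
    "mean conversion rate: %.4f before, %.4f after filtering\n"),
    x$n_input, x$n_low_conversion, x$n_clonal_removed, x$n_pass,
    x$mean_conversion_before, x$mean_conversion_after))
  invisible(x)
}

#' Write filter reports as TSV
#'
#' @param reports Named list of `filter_report` objects (names =
#'   "sample.amplicon" or similar labels).
#' @param path Output path.
#' @export
write_filter_report_tsv <- function(reports, path) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(group = nm, n_input = r$n_input,
               n_low_conversion = r$n_low_conversion,
               n_clonal_removed = r$n_clonal_removed, n_pass = r$n_pass,
               mean_conversion_before = round(r$mean_conversion_before, 4),
               mean_conversion_after = round(r$mean_conversion_after, 4))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
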