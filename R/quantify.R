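#' Per-CpG methylation quantitation with a depth gate
#'
#' Aggregates filtered, aligned reads of one sample x amplicon into per-site
#' methylation levels: `level = n_meth / (n_meth + n_unmeth)`. Ambiguous
#' calls are excluded from both numerator and denominator; sites whose
#' informative depth falls below `min_depth` (10X by default) are dropped
#' from the profile and counted in attribute `n_sites_dropped`.
#'
#' @param aligned List of `aligned_read` objects (post-filtering).
#' @param ref The [amplicon_reference] they were aligned to.
#' @param min_depth Minimum informative depth for a site to be reported
#'   (default 10).
#' @param sample_id Sample label for the profile (taken from the first read
#'   when `NULL`).
#' @return Object of class `methylation_profile`: list with `sample_id`,
#'   `amplicon_id`, and `sites`, a `data.frame` (pos = 0-based CpG position,
#'   level, depth, n_meth, n_unmeth, n_ambig) ordered by position.
#' @export
quantify <- function(aligned, ref, min_depth = 10L, sample_id = NULL) {
  stopifnot(inherits(ref, "amplicon_reference"))
  if (is.null(sample_id))
    sample_id <- if (length(aligned) > 0L) aligned[[1]]$sample_id
                 else NA_character_
  pos <- ref$cpg_sites
  n_meth <- n_unmeth <- n_ambig <- integer(length(pos))
  if (length(aligned) == 0L) {
    warning("no reads to quantify for amplicon ", ref$id)
  } else {
    for (a in aligned) {
      if (!identical(a$amplicon_id, ref$id))
        stop("read ", a$read_id, " aligned to '", a$amplicon_id,
             "', not '", ref$id, "'")
      calls <- a$cpg_calls
      n_meth <- n_meth + (calls == "METH")
      n_unmeth <- n_unmeth + (calls == "UNMETH")
      n_ambig <- n_ambig + (calls == "AMBIG")
    }
  }
  depth <- n_meth + n_unmeth
  sites <- data.frame(pos = pos, level = ifelse(depth > 0, n_meth / depth, NA_real_),
                      depth = depth, n_meth = n_meth, n_unmeth = n_unmeth,
                      n_ambig = n_ambig)
  keep <- sites$depth >= min_depth
  dropped <- sum(!keep)
  sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sample_id = sample_id, amplicon_id = ref$id, sites = sites),
            class = "methylation_profile", n_sites_dropped = dropped,
            min_depth = min_depth)
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("methylation_profile %s / %s: %d sites (>= %dX), %d below depth gate\n",
              x$sample_id, x$amplicon_id, nrow(x$sites),
              attr(x, "min_depth"), attr(x, "n_sites_dropped")))
  if (nrow(x$sites) > 0L)
    cat(sprintf("  mean level %.3f, mean depth %.1fX\n",
                mean(x$sites$level), mean(x$sites$depth)))
  invisible(x)
}

#' Replicate reproducibility statistics
#'
#' Pairwise Pearson correlation and per-site standard deviation of
#' methylation levels across replicate profiles of the same amplicon.
#' Sites are restricted to those reported (i.e. past the depth gate) in all
#' replicates. The per-site SD uses the n - 1 denominator (sample statistic
#' over replicates). A replicate with zero variance across common sites has
#' no defined correlation; affected pairs are reported as `NA`, never
#' silently as 0 or 1.
#'
#' @param profiles List of two or more `methylation_profile` objects over
#'   the same amplicon.
#' @return Object of class `replicate_set`: list with `amplicon_id`,
#'   `n_common_sites`, `correlation` (symmetric matrix with unit diagonal),
#'   `mean_r` and `sd_r` (mean +/- SD over distinct pairs), `per_site_sd`
#'   (`data.frame` pos/sd), and `median_sd`.
#' @export
replicate_stats <- function(profiles) {
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, inherits, logical(1), "methylation_profile")))
  amp <- unique(vapply(profiles, `[[`, character(1), "amplicon_id"))
  if (length(amp) != 1L)
    stop("profiles span multiple amplicons: ", paste(amp, collapse = ", "))
  common <- Reduce(intersect, lapply(profiles, function(p) p$sites$pos))
  if (length(common) < 2L)
    stop("need at least 2 common sites for replicate statistics; found ",
         length(common))
  common <- sort(common)
  levels <- vapply(profiles, function(p)
    p$sites$level[match(common, p$sites$pos)], numeric(length(common)))
  k <- length(profiles)
  labels <- vapply(seq_len(k), function(i) {
    s <- profiles[[i]]$sample_id
    if (is.na(s)) sprintf("rep%d", i) else s
  }, character(1))
  labels <- make.unique(labels)
  cormat <- diag(1, k)
  dimnames(cormat) <- list(labels, labels)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    if (stats::sd(levels[, i]) == 0 || stats::sd(levels[, j]) == 0) {
      cormat[i, j] <- cormat[j, i] <- NA_real_
    } else {
      cormat[i, j] <- cormat[j, i] <- stats::cor(levels[, i], levels[, j])
    }
  }
  pair_r <- cormat[upper.tri(cormat)]
  per_site_sd <- data.frame(pos = common, sd = apply(levels, 1, stats::sd))
  structure(list(
    amplicon_id = amp, n_common_sites = length(common),
    correlation = cormat,
    mean_r = mean(pair_r, na.rm = TRUE),
    sd_r = stats::sd(pair_r[!is.na(pair_r)]),
    n_undefined_pairs = sum(is.na(pair_r)),
    per_site_sd = per_site_sd,
    median_sd = stats::median(per_site_sd$sd)), class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("replicate_set %s: %d replicates, %d common sites\n",
              x$amplicon_id, nrow(x$correlation), x$n_common_sites))
  cat(sprintf("  pairwise Pearson r: %.3f +/- %.3f", x$mean_r,
              ifelse(is.na(x$sd_r), 0, x$sd_r)))
  if (x$n_undefined_pairs > 0L)
    cat(sprintf(" (%d pair(s) undefined: zero variance)", x$n_undefined_pairs))
  cat(sprintf("\n  per-site SD: median %.4f\n", x$median_sd))
  invisible(x)
}

#' Compare site-level methylation between two platforms
#'
#' Intersects two site -> level maps (e.g. amplicon bisulfite sequencing vs
#' a methylation array or capture sequencing summary), computes the Pearson
#' correlation over paired levels and the signed per-site differences
#' (a - b) for bias inspection, such as the downward shift of intermediate
#' levels expected from PCR bias towards unmethylated templates.
#'
#' @param profile_a,profile_b Named numeric vectors (names = site keys in a
#'   shared coordinate system, values = levels in `[0, 1]`), or
#'   `methylation_profile` objects.
#' @return List with `n_common`, `pearson_r` (`NA` when undefined),
#'   `status` (`"ok"`, `"no_common_sites"`, `"zero_variance"`,
#'   `"too_few_sites"`), and `differences` (`data.frame` site, a, b, diff).
#' @export
compare_platforms <- function(profile_a, profile_b) {
  as_map <- function(p) {
    if (inherits(p, "methylation_profile"))
      stats::setNames(p$sites$level, p$sites$pos)
    else p
  }
  a <- as_map(profile_a); b <- as_map(profile_b)
  common <- intersect(names(a), names(b))
  if (length(common) == 0L)
    return(list(n_common = 0L, pearson_r = NA_real_,
                status = "no_common_sites",
                differences = data.frame(site = character(0), a = numeric(0),
                                         b = numeric(0), diff = numeric(0))))
  av <- unname(a[common]); bv <- unname(b[common])
  differences <- data.frame(site = common, a = av, b = bv, diff = av - bv)
  if (length(common) < 2L)
    return(list(n_common = length(common), pearson_r = NA_real_,
                status = "too_few_sites", differences = differences))
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    return(list(n_common = length(common), pearson_r = NA_real_,
                status = "zero_variance", differences = differences))
  list(n_common = length(common), pearson_r = stats::cor(av, bv),
       status = "ok", differences = differences)
}

#' Fraction of CpG islands coverable by one amplicon
#'
#' Given CpG-island intervals, computes the fraction whose length fits
#' within a single amplicon of at most `max_amplicon` bp. The boundary is
#' inclusive: an island of exactly `max_amplicon` bp counts as coverable,
#' since that amplicon length is achievable.
#'
#' @param islands BED intervals: a path to a BED file (0-based half-open),
#'   a `data.frame` with columns `start` and `end`, or a `GRanges`.
#' @param max_amplicon Maximum amplicon length in bp (default 1500).
#' @return List with `n_islands`, `n_coverable`, `fraction` (`NA` with
#'   `status = "empty"` for empty input), and `status`.
#' @export
island_coverage <- function(islands, max_amplicon = 1500L) {
  if (is.character(islands) && length(islands) == 1L) {
    widths <- .read_bed_widths(islands)
  } else if (is.data.frame(islands)) {
    if (!all(c("start", "end") %in% names(islands)))
      stop("island data.frame needs 'start' and 'end' columns")
    bad <- which(islands$end <= islands$start)
    if (length(bad) > 0L)
      stop("malformed interval (end <= start) at row ", bad[1])
    widths <- islands$end - islands$start
  } else if (inherits(islands, "GRanges")) {
    widths <- GenomicRanges::width(islands)
  } else {
    stop("'islands' must be a BED path, data.frame, or GRanges")
  }
  if (length(widths) == 0L)
    return(list(n_islands = 0L, n_coverable = 0L, fraction = NA_real_,
                status = "empty"))
  n_cov <- sum(widths <= max_amplicon)
  list(n_islands = length(widths), n_coverable = n_cov,
       fraction = n_cov / length(widths), status = "ok")
}

## BED reader returning interval widths; validates end > start with the
## offending line number before handing off to rtracklayer.
.read_bed_widths <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  body <- lines[keep]
  if (length(body) == 0L) return(integer(0))
  fields <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    lineno <- which(keep)[i]
    if (length(f) < 3L)
      stop("malformed BED line ", lineno, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop("malformed BED line ", lineno, ": non-numeric coordinates")
    if (e <= s)
      stop("malformed BED line ", lineno, ": end <= start")
  }
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    as.integer(GenomicRanges::width(gr))
  } else {
    vapply(fields, function(f) as.integer(as.numeric(f[3]) - as.numeric(f[2])),
           integer(1))
  }
}

#' Equimolar pooling volumes
#'
#' Volume of each purified amplicon to pool so that every amplicon from
#' every sample contributes an equal number of molecules to sequencing:
#' `V_i = M * L_i / (n * C_i * sum(L))`, where `M` is the total pooled mass,
#' `L_i` the amplicon length in bp, `C_i` its concentration (mass/volume),
#' and `n` the number of samples. Mass is proportional to molecules times
#' length, so allocating mass in proportion to `L_i` equalises molecule
#' counts; `V_i * C_i / L_i` is therefore constant across amplicons, and the
#' volumes of all `n * m` wells sum to mass `M`.
#'
#' @param total_mass `M`: total mass of the pooled library (e.g. ng).
#' @param lengths `L_i`: amplicon lengths in bp.
#' @param concentrations `C_i`: per-amplicon concentrations (e.g. ng/uL),
#'   recycled against `lengths` if scalar.
#' @param n_samples `n`: number of samples each amplicon is pooled from
#'   (default 1).
#' @return `data.frame` with `length`, `concentration`, `volume`, and
#'   `molar_share` (fraction of molecules, constant by construction), plus
#'   attributes `total_volume` (one sample) and `total_mass_check`
#'   (`sum over samples x amplicons of V_i * C_i`, equal to `M`).
#' @examples
#' pooling_volumes(500, c(800, 800), 50, n_samples = 1)
#' @export
pooling_volumes <- function(total_mass, lengths, concentrations,
                            n_samples = 1L) {
  if (!is.numeric(total_mass) || length(total_mass) != 1L || total_mass <= 0)
    stop("'total_mass' must be a single positive number")
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1)
    stop("'n_samples' must be a positive integer")
  if (length(lengths) == 0L) stop("'lengths' must be non-empty")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("'lengths' must all be positive")
  if (length(concentrations) == 1L)
    concentrations <- rep(concentrations, length(lengths))
  if (length(concentrations) != length(lengths))
    stop("'concentrations' must match 'lengths' in length")
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stop("'concentrations' must all be positive")
  volumes <- total_mass * lengths / (n_samples * concentrations * sum(lengths))
  out <- data.frame(length = lengths, concentration = concentrations,
                    volume = volumes,
                    molar_share = (volumes * concentrations / lengths) /
                      sum(volumes * concentrations / lengths))
  attr(out, "total_volume") <- sum(volumes)
  attr(out, "total_mass_check") <- n_samples * sum(volumes * concentrations)
  out
}

#' Write methylation profiles as TSV
#'
#' One row per sample x amplicon x site. Site coordinates are 1-based in
#' the export (internal coordinates are 0-based); levels are written to 3
#' decimal places for stable diffs, full precision retained in R objects.
#'
#' @param profiles List of `methylation_profile` objects.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profiles, path) {
  if (inherits(profiles, "methylation_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (nrow(p$sites) == 0L) return(NULL)
    data.frame(sample = p$sample_id, amplicon = p$amplicon_id,
               site_1based = p$sites$pos + 1L,
               level = round(p$sites$level, 3),
               depth = p$sites$depth, n_meth = p$sites$n_meth,
               n_unmeth = p$sites$n_unmeth, n_ambig = p$sites$n_ambig)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample = character(0), amplicon = character(0),
                      site_1based = integer(0), level = numeric(0),
                      depth = integer(0), n_meth = integer(0),
                      n_unmeth = integer(0), n_ambig = integer(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
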