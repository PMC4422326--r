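## Universal primer pair used by the simulator's default manifest. These
## mimic the anti-tag universal primers of a two-step barcoded bisulfite
## PCR design; any primer pair works as long as the manifest carries it.
SIM_PRIMER_FWD <- "GCAGTCGAACATGTAGCT"
SIM_PRIMER_REV <- "TGGATCACTTGTGCAAGC"

#' Generate a synthetic amplicon reference
#'
#' Builds a random amplicon sequence with a controlled number of CpG sites
#' placed at roughly even spacing, against a background guaranteed free of
#' accidental CpGs (so the CpG map is exactly the designed one). The
#' background retains plenty of non-CpG cytosines on both strands, which the
#' conversion-rate filter needs.
#'
#' @param id Amplicon identifier.
#' @param length Amplicon length in bp.
#' @param n_cpg Number of CpG sites to place.
#' @return An [amplicon_reference] with exactly `n_cpg` CpG sites.
#' @export
sim_amplicon <- function(id, length, n_cpg) {
  stopifnot(length >= 20, n_cpg >= 0, 3 * n_cpg < length)
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  # fixed, even CpG placement; sites are >= 3 bp apart by construction
  if (n_cpg > 0) {
    pos <- round(seq_len(n_cpg) * (length - 2) / (n_cpg + 1))
    chars[pos + 1L] <- "C"
    chars[pos + 2L] <- "G"
  } else {
    pos <- integer(0)
  }
  # remove accidental CpGs outside the designed positions
  repeat {
    cg <- which(chars[-length] == "C" & chars[-1L] == "G")
    cg <- setdiff(cg - 1L, pos)   # 0-based accidental CpG positions
    if (length(cg) == 0L) break
    chars[cg + 2L] <- sample(c("A", "T"), length(cg), replace = TRUE)
  }
  amplicon_reference(id, paste(chars, collapse = ""))
}

#' Generate a synthetic barcode manifest
#'
#' Random barcode pairs with a guaranteed minimum pairwise Levenshtein
#' distance, plus a fixed universal primer pair, for use by the simulator.
#'
#' @param sample_ids Character vector of sample names.
#' @param barcode_length Barcode length in bp (default 18).
#' @param min_dist Minimum pairwise edit distance among all barcodes
#'   (default 7, comfortably above twice the demultiplexing edit budget).
#' @return A [barcode_manifest].
#' @export
sim_manifest <- function(sample_ids, barcode_length = 18L, min_dist = 7L) {
  stopifnot(length(sample_ids) >= 1L)
  n_needed <- 2L * length(sample_ids)
  bcs <- character(0)
  tries <- 0L
  while (length(bcs) < n_needed) {
    cand <- paste(sample(c("A", "C", "G", "T"), barcode_length,
                         replace = TRUE), collapse = "")
    ok <- length(bcs) == 0L || min(utils::adist(cand, bcs)) >= min_dist
    if (ok) bcs <- c(bcs, cand)
    tries <- tries + 1L
    if (tries > 10000L) stop("could not generate barcodes at min_dist = ",
                             min_dist)
  }
  barcode_manifest(data.frame(
    sample_id = sample_ids,
    bc_fwd = bcs[seq_along(sample_ids)],
    bc_rev = bcs[length(sample_ids) + seq_along(sample_ids)],
    primer_fwd = SIM_PRIMER_FWD, primer_rev = SIM_PRIMER_REV,
    stringsAsFactors = FALSE))
}

#' Simulator configuration
#'
#' Bundles and validates everything the read simulator needs. The defaults
#' encode the study conditions this simulator emulates: mean bisulfite
#' conversion efficiency 0.97, a small clonal duplicate fraction (0.3% of
#' reads), CCS-level substitution/indel error, and no PCR bias
#' (`pcr_bias_weight = 1`; set it above 1 to weight template sampling by
#' `w^(number of unmethylated CpGs)`, reproducing the preferential
#' amplification of unmethylated templates).
#'
#' @param refs Named list of [amplicon_reference] objects.
#' @param levels Named list: per amplicon, numeric vector of true
#'   methylation levels in `[0, 1]`, one per CpG site of that amplicon.
#' @param manifest A [barcode_manifest]; samples = its `sample_id` column.
#' @param n_reads Reads emitted per sample x amplicon (default 100,
#'   i.e. ~100X nominal depth).
#' @param n_templates Size of the bisulfite-converted template pool each
#'   read is drawn from, per sample x amplicon (default `10 * n_reads`;
#'   reads sample distinct molecules, so the pool must be at least
#'   `n_reads`).
#' @param conversion_efficiency Probability that an unmethylated cytosine
#'   converts (default 0.97). Scalar, or named vector by sample for mixed
#'   designs.
#' @param sequencing_error Per-base substitution rate (default 0.005).
#' @param indel_rate Per-base indel rate (default 0.001).
#' @param clonal_fraction Fraction of reads that are PCR copies of an
#'   earlier emitted molecule (default 0.003).
#' @param pcr_bias_weight Template sampling weight multiplier per
#'   unmethylated CpG, `w >= 1` (default 1: off).
#' @param seed Integer seed fixing the full simulator output.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(refs, levels, manifest, n_reads = 100L,
                       n_templates = NULL, conversion_efficiency = 0.97,
                       sequencing_error = 0.005, indel_rate = 0.001,
                       clonal_fraction = 0.003, pcr_bias_weight = 1,
                       seed = 1L) {
  stopifnot(length(refs) >= 1L,
            all(vapply(refs, inherits, logical(1), "amplicon_reference")))
  if (is.null(names(refs)))
    names(refs) <- vapply(refs, `[[`, character(1), "id")
  stopifnot(inherits(manifest, "barcode_manifest"))
  if (is.null(n_templates)) n_templates <- 10L * n_reads
  stopifnot(n_reads >= 1L, n_templates >= n_reads)
  for (nm in names(refs)) {
    lv <- levels[[nm]]
    if (is.null(lv)) stop("no true levels given for amplicon ", nm)
    if (length(lv) != length(refs[[nm]]$cpg_sites))
      stop("amplicon ", nm, " has ", length(refs[[nm]]$cpg_sites),
           " CpG sites but ", length(lv), " levels were given")
    if (any(lv < 0 | lv > 1)) stop("levels for ", nm, " outside [0, 1]")
  }
  ce <- conversion_efficiency
  if (!is.null(names(ce))) {
    missing <- setdiff(manifest$sample_id, names(ce))
    if (length(missing) > 0L)
      stop("conversion_efficiency missing for samples: ",
           paste(missing, collapse = ", "))
  } else if (length(ce) != 1L) {
    stop("conversion_efficiency must be scalar or named by sample")
  }
  stopifnot(all(ce >= 0 & ce <= 1),
            sequencing_error >= 0, sequencing_error <= 1,
            indel_rate >= 0, indel_rate <= 1,
            clonal_fraction >= 0, clonal_fraction <= 1,
            pcr_bias_weight >= 1)
  structure(list(refs = refs, levels = levels, manifest = manifest,
                 n_reads = as.integer(n_reads),
                 n_templates = as.integer(n_templates),
                 conversion_efficiency = ce,
                 sequencing_error = sequencing_error,
                 indel_rate = indel_rate,
                 clonal_fraction = clonal_fraction,
                 pcr_bias_weight = pcr_bias_weight,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sample_efficiency <- function(config, sample_id) {
  ce <- config$conversion_efficiency
  if (!is.null(names(ce))) unname(ce[[sample_id]]) else ce
}

## Build one bisulfite-converted molecule in forward-strand coordinates.
## pattern: integer 0/1 per CpG site (1 = methylated on both strands).
.convert_molecule <- function(ref_chars, ref, pattern, strand, efficiency) {
  chars <- ref_chars
  if (strand == "top") {
    non <- ref$noncpg_c_top
    conv <- non[stats::runif(length(non)) < efficiency]
    chars[conv + 1L] <- "T"
    unmeth <- ref$cpg_sites[pattern == 0L]
    conv_cpg <- unmeth[stats::runif(length(unmeth)) < efficiency]
    chars[conv_cpg + 1L] <- "T"
  } else {
    non <- ref$noncpg_c_bottom
    conv <- non[stats::runif(length(non)) < efficiency]
    chars[conv + 1L] <- "A"
    unmeth <- ref$cpg_sites[pattern == 0L]
    conv_cpg <- unmeth[stats::runif(length(unmeth)) < efficiency]
    chars[conv_cpg + 2L] <- "A"   # the paired G at p + 1
  }
  paste(chars, collapse = "")
}

#' Simulate the bisulfite-converted template pool
#'
#' For every sample x amplicon, draws `n_templates` template molecules:
#' per-CpG methylation states are independent Bernoulli draws at each
#' site's true level; each unmethylated CpG cytosine and each non-CpG
#' cytosine converts with probability `conversion_efficiency` (methylated
#' CpG cytosines never convert); the strand is chosen uniformly. Molecules
#' are represented in forward-strand coordinates (bottom-strand conversion
#' appears as G-to-A).
#'
#' With `exact = TRUE` the stochastic draws are replaced by exhaustive
#' enumeration: molecule j of d has site s methylated iff
#' `j <= round(level_s * d)`, conversion is complete, and strands alternate,
#' so a full pass of the pipeline over all templates recovers every true
#' level exactly.
#'
#' @param config A [sim_config].
#' @param exact Exhaustive noise-free enumeration instead of sampling.
#' @return List of molecule groups, one per sample x amplicon: list with
#'   `sample_id`, `amplicon_id`, and `molecules` (each: `template_id`,
#'   `strand`, `pattern`, `n_unmeth`, `seq`).
#' @export
simulate_templates <- function(config, exact = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  groups <- list()
  for (sample_id in config$manifest$sample_id) {
    eff <- if (exact) 1.0 else .sample_efficiency(config, sample_id)
    for (amp in names(config$refs)) {
      ref <- config$refs[[amp]]
      ref_chars <- strsplit(ref$sequence, "", fixed = TRUE)[[1]]
      lv <- config$levels[[amp]]
      d <- config$n_templates
      mols <- vector("list", d)
      for (j in seq_len(d)) {
        if (exact) {
          pattern <- as.integer(j <= round(lv * d))
          strand <- if (j %% 2L == 1L) "top" else "bottom"
        } else {
          pattern <- as.integer(stats::runif(length(lv)) < lv)
          strand <- if (stats::runif(1) < 0.5) "top" else "bottom"
        }
        mols[[j]] <- list(
          template_id = sprintf("%s.%s.t%05d", sample_id, amp, j),
          strand = strand, pattern = pattern,
          n_unmeth = sum(pattern == 0L),
          seq = .convert_molecule(ref_chars, ref, pattern, strand, eff))
      }
      groups[[length(groups) + 1L]] <- list(
        sample_id = sample_id, amplicon_id = amp, molecules = mols)
    }
  }
  groups
}

## Substitution + indel error injection; returns list(seq, n_subs, n_indels).
.inject_errors <- function(seq, sub_rate, indel_rate) {
  if (sub_rate == 0 && indel_rate == 0)
    return(list(seq = seq, n_subs = 0L, n_indels = 0L))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  subs <- which(stats::runif(n) < sub_rate)
  for (i in subs)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  ind <- which(stats::runif(n) < indel_rate)
  if (length(ind) > 0L) {
    # apply right-to-left so earlier positions stay valid
    for (i in rev(ind)) {
      if (stats::runif(1) < 0.5) {
        chars <- chars[-i]
      } else {
        chars <- append(chars, sample(c("A", "C", "G", "T"), 1L), after = i - 1L)
      }
    }
  }
  list(seq = paste(chars, collapse = ""), n_subs = length(subs),
       n_indels = length(ind))
}

#' Emit barcoded reads from a template pool
#'
#' Samples `n_reads` distinct templates per sample x amplicon with
#' probability proportional to `pcr_bias_weight ^ n_unmethylated_CpGs`
#' (uniform when the weight is 1), turns a `clonal_fraction` of read slots
#' into exact PCR copies of a previously emitted molecule (identical
#' converted sequence, hence identical CpG and non-CpG cytosine patterns,
#' before independent error injection), attaches sample barcodes and
#' universal primers, flips half the reads to the opposite orientation,
#' and injects substitution and indel errors.
#'
#' @param molecules Output of [simulate_templates].
#' @param config The same [sim_config].
#' @return List with `reads` (`data.frame`: read_id, sample_id_true,
#'   sequence) and `truth` (`data.frame` per read: template, strand,
#'   clone_of, methylation pattern, counts of converted/retained non-CpG
#'   cytosines, injected error counts, orientation).
#' @export
simulate_reads <- function(molecules, config) {
  stopifnot(inherits(config, "sim_config"))
  man <- config$manifest
  read_rows <- list()
  truth_rows <- list()
  for (grp in molecules) {
    row <- man[man$sample_id == grp$sample_id, , drop = FALSE]
    stopifnot(nrow(row) == 1L)
    mols <- grp$molecules
    w <- config$pcr_bias_weight ^ vapply(mols, `[[`, numeric(1), "n_unmeth")
    n <- config$n_reads
    draw <- sample(length(mols), n, replace = FALSE, prob = w)
    clone_of <- rep(NA_integer_, n)
    if (config$clonal_fraction > 0 && n > 1L) {
      clone_slots <- which(stats::runif(n) < config$clonal_fraction)
      clone_slots <- clone_slots[clone_slots > 1L]
      for (i in clone_slots) {
        src <- sample(i - 1L, 1L)
        draw[i] <- draw[src]
        clone_of[i] <- src
      }
    }
    ref <- config$refs[[grp$amplicon_id]]
    for (i in seq_len(n)) {
      m <- mols[[draw[i]]]
      read_id <- sprintf("%s.%s.r%04d", grp$sample_id, grp$amplicon_id, i)
      full <- paste0(row$bc_fwd, row$primer_fwd, m$seq,
                     .revcomp(row$primer_rev), .revcomp(row$bc_rev))
      orientation <- if (stats::runif(1) < 0.5) "forward"
                     else "reverse-complement"
      if (orientation == "reverse-complement") full <- .revcomp(full)
      err <- .inject_errors(full, config$sequencing_error, config$indel_rate)
      # truth conversion counts from the pre-error molecule sequence
      mchars <- strsplit(m$seq, "", fixed = TRUE)[[1]]
      if (m$strand == "top") {
        non <- ref$noncpg_c_top
        n_conv <- sum(mchars[non + 1L] == "T")
      } else {
        non <- ref$noncpg_c_bottom
        n_conv <- sum(mchars[non + 1L] == "A")
      }
      read_rows[[length(read_rows) + 1L]] <- data.frame(
        read_id = read_id, sample_id_true = grp$sample_id,
        sequence = err$seq, stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        read_id = read_id, sample_id = grp$sample_id,
        amplicon_id = grp$amplicon_id, template_id = m$template_id,
        strand = m$strand,
        clone_of = if (is.na(clone_of[i])) NA_character_ else
          sprintf("%s.%s.r%04d", grp$sample_id, grp$amplicon_id, clone_of[i]),
        pattern = paste(m$pattern, collapse = ""),
        n_meth_cpg = sum(m$pattern),
        n_noncpg_total = length(non), n_noncpg_converted = n_conv,
        conversion_efficiency = .sample_efficiency(config, grp$sample_id),
        n_subs = err$n_subs, n_indels = err$n_indels,
        orientation = orientation, stringsAsFactors = FALSE)
    }
  }
  list(reads = do.call(rbind, read_rows), truth = do.call(rbind, truth_rows))
}

#' Run the full simulator
#'
#' Seeds the random number generator from `config$seed` (so the same
#' configuration always yields byte-identical output), simulates the
#' template pool and the reads, and optionally writes the dataset to disk:
#' `reads.fastq`, `truth_reads.tsv`, `truth_sites.tsv` (per-site true
#' levels), `manifest.tsv`, and `refs.fasta`.
#'
#' @param config A [sim_config].
#' @param outdir Optional output directory.
#' @param exact Passed to [simulate_templates].
#' @return List with `reads`, `truth`, `truth_sites`, `manifest`, `refs`.
#' @export
simulate_dataset <- function(config, outdir = NULL, exact = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  molecules <- simulate_templates(config, exact = exact)
  rt <- simulate_reads(molecules, config)
  truth_sites <- do.call(rbind, lapply(names(config$refs), function(amp)
    data.frame(amplicon_id = amp,
               pos = config$refs[[amp]]$cpg_sites,
               true_level = config$levels[[amp]])))
  out <- list(reads = rt$reads, truth = rt$truth, truth_sites = truth_sites,
              manifest = config$manifest, refs = config$refs)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    .write_fastq(rt$reads$sequence, rt$reads$read_id,
                 path = file.path(outdir, "reads.fastq"))
    utils::write.table(rt$truth, file.path(outdir, "truth_reads.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth_sites, file.path(outdir, "truth_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(config$manifest),
                       file.path(outdir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_amplicon_fasta(config$refs, file.path(outdir, "refs.fasta"))
  }
  out
}

#' Default amplicon methylation profiles
#'
#' Builds the three-amplicon design the package uses as its standard test
#' bed, emulating CpG islands with low, intermediate, and high methylation:
#' the low island has all sites unmethylated, the high island all sites
#' fully methylated, and the intermediate island (imprinted-like, mean 0.5)
#' cycles site levels through 0, 0.25, 0.5, 0.75, 1 so that replicate
#' correlation is informative.
#'
#' @param length Amplicon length in bp (default 700).
#' @param n_cpg CpG sites per amplicon (default 24).
#' @return List with `refs` and `levels` ready for [sim_config].
#' @export
island_profiles <- function(length = 700L, n_cpg = 24L) {
  refs <- list(low = sim_amplicon("low", length, n_cpg),
               intermediate = sim_amplicon("intermediate", length, n_cpg),
               high = sim_amplicon("high", length, n_cpg))
  levels <- list(low = rep(0, n_cpg),
                 intermediate = rep(c(0, 0.25, 0.5, 0.75, 1),
                                    length.out = n_cpg),
                 high = rep(1, n_cpg))
  list(refs = refs, levels = levels)
}
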