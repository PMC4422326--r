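# Small fixtures built in code for the unit tests.

# Fully bisulfite-convert a sequence in silico (no methylation): top strand
# C->T, bottom strand G->A, in forward coordinates.
full_convert <- function(seq, strand = "top") {
  if (strand == "top") chartr("C", "T", seq) else chartr("G", "A", seq)
}

rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

# A minimal two-sample manifest with fixed, distant barcodes.
tiny_manifest <- function() {
  barcode_manifest(data.frame(
    sample_id = c("sampleA", "sampleB"),
    bc_fwd = c("ACACACACACACACACAC", "GTGTGTGTGTGTGTGTGT"),
    bc_rev = c("AAGGAAGGAAGGAAGGAA", "CCTTCCTTCCTTCCTTCC"),
    primer_fwd = "GCAGTCGAACATGTAGCT",
    primer_rev = "TGGATCACTTGTGCAAGC",
    stringsAsFactors = FALSE))
}

# Assemble a structured read: fwd barcode + fwd primer + insert +
# rc(rev primer) + rc(rev barcode).
structured_read <- function(insert, manifest, sample = manifest$sample_id[1]) {
  row <- manifest[manifest$sample_id == sample, ]
  paste0(row$bc_fwd, row$primer_fwd, insert,
         rc(row$primer_rev), rc(row$bc_rev))
}

# Build an aligned_read by hand for filter-level tests. Calls are given as
# character vectors over the full reference site maps.
make_aligned <- function(read_id, cpg_calls, noncpg_vector, strand = "top",
                         sample_id = "s", amplicon_id = "amp") {
  structure(list(read_id = read_id, sample_id = sample_id,
                 amplicon_id = amplicon_id, strand = strand,
                 orientation = "forward", start = 0L, end = 0L,
                 score = 0, identity = 1,
                 cpg_calls = cpg_calls, noncpg_vector = noncpg_vector),
            class = "aligned_read")
}

# Convenience: a call vector of n CONVERTED and m RETAINED non-CpG sites.
conv_vector <- function(n_conv, n_ret) {
  c(rep("CONVERTED", n_conv), rep("RETAINED", n_ret))
}
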