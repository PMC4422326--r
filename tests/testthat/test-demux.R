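test_that("exact barcode prefix assigns with zero edits", {
  man <- tiny_manifest()
  read <- structured_read(strrep("T", 100), man, "sampleA")
  a <- assign_barcode(read, man)
  expect_identical(a$sample_id, "sampleA")
  expect_identical(a$edits, 0L)
  expect_identical(a$orientation, "forward")
})

test_that("one substitution plus one deletion still assigns at edits = 2", {
  man <- tiny_manifest()
  bc <- man$bc_fwd[2]
  # substitute position 3, delete position 10
  mut <- paste0(substr(bc, 1, 2), "T", substr(bc, 4, 9), substr(bc, 11, 18))
  read <- paste0(mut, strrep("A", 60))
  a <- assign_barcode(read, man)
  expect_identical(a$sample_id, "sampleB")
  expect_identical(a$edits, 2L)
  # independent full edit-distance confirmation
  expect_identical(oracle_prefix_distance(read, bc), 2)
})

test_that("distance-3 prefixes and inter-sample ties go unassigned", {
  man <- tiny_manifest()
  bc <- man$bc_fwd[1]
  mut <- paste0("TTT", substr(bc, 4, 18))  # 3 substitutions
  a <- assign_barcode(paste0(mut, strrep("A", 60)), man)
  expect_true(is.na(a$sample_id))
  expect_identical(a$reason, "no_barcode_match")

  # two samples with barcodes equidistant from the read prefix
  man2 <- barcode_manifest(data.frame(
    sample_id = c("x", "y"),
    bc_fwd = c("AAAAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAATT"),
    bc_rev = c("GGGGGGGGGGGGGGGGGG", "GGGGGGGGGGGGGGGGAA"),
    primer_fwd = "GCAGTCGAACATGTAGCT", primer_rev = "TGGATCACTTGTGCAAGC",
    stringsAsFactors = FALSE))
  tie_read <- paste0("AAAAAAAAAAAAAAAAAT", strrep("C", 40))  # 1 edit from both
  a2 <- assign_barcode(tie_read, man2)
  expect_true(is.na(a2$sample_id))
  expect_identical(a2$reason, "ambiguous_barcode_tie")
})

test_that("assignment decisions equal the full edit-distance oracle", {
  set.seed(19)
  man <- sim_manifest(c("s1", "s2", "s3"))
  for (i in 1:80) {
    kind <- i %% 4
    prefix <- if (kind == 0) {
      random_dna(40)                      # unrelated
    } else {
      bc <- man$bc_fwd[sample(3, 1)]
      n_mut <- sample(0:3, 1)
      chars <- strsplit(paste0(bc, random_dna(25)), "")[[1]]
      for (p in sample(18, n_mut)) chars[p] <- sample(c("A","C","G","T"), 1)
      paste(chars, collapse = "")
    }
    got <- assign_barcode(prefix, man)$sample_id
    expect_identical(got, oracle_assign(prefix, man),
                     info = paste("case", i))
  }
})

test_that("reverse-complement reads are recognized and oriented", {
  man <- tiny_manifest()
  read <- structured_read(strrep("T", 80), man, "sampleA")
  a <- assign_barcode(rc(read), man)
  expect_identical(a$sample_id, "sampleA")
  expect_identical(a$orientation, "reverse-complement")
})

test_that("trimming recovers the exact insert from constructed reads", {
  man <- tiny_manifest()
  insert <- "TTATTGGTTAAATTTGAT"
  read <- structured_read(insert, man, "sampleA")
  tr <- trim_read(read, "sampleA", "forward", man)
  expect_identical(tr$trimmed_sequence, insert)
  expect_length(tr$flags, 0)
  # same read reverse-complemented
  tr2 <- trim_read(rc(read), "sampleA", "reverse-complement", man)
  expect_identical(tr2$trimmed_sequence, insert)
})

test_that("unassigned reads pass through trimming unchanged and flagged", {
  man <- tiny_manifest()
  tr <- trim_read("TTTTTTTTTTTTTTTTTTTTTTTT", NA_character_, NA, man)
  expect_identical(tr$trimmed_sequence, "TTTTTTTTTTTTTTTTTTTTTTTT")
  expect_identical(tr$flags, "unassigned")
})

test_that("inserts survive trimming under simulated barcode errors", {
  set.seed(11)
  man <- tiny_manifest()
  n_exact <- 0
  for (i in 1:100) {
    insert <- random_dna(60)
    sample_id <- sample(man$sample_id, 1)
    read <- structured_read(insert, man, sample_id)
    # inject 0-2 errors inside the leading barcode
    n_err <- sample(0:2, 1)
    chars <- strsplit(read, "")[[1]]
    for (p in sample(18, n_err)) chars[p] <- sample(c("A","C","G","T"), 1)
    read <- paste(chars, collapse = "")
    a <- assign_barcode(read, man)
    expect_identical(a$sample_id, sample_id)
    tr <- trim_read(read, a$sample_id, a$orientation, man)
    n_exact <- n_exact + identical(tr$trimmed_sequence, insert)
  }
  expect_identical(as.integer(n_exact), 100L)
})

test_that("length filter is strict at the boundary", {
  set.seed(5)
  lens <- c(49L, 50L, 51L)
  keep <- length_filter(lens, min_len = 50)
  expect_identical(as.logical(keep), c(FALSE, FALSE, TRUE))
  expect_identical(as.logical(length_filter(lens, 50, inclusive = TRUE)),
                   c(FALSE, TRUE, TRUE))
  expect_length(length_filter(integer(0)), 0)
  # recount property on many simulated lengths
  lens2 <- sample(30:80, 1000, replace = TRUE)
  expect_identical(sum(length_filter(lens2, 50)), sum(lens2 > 50))
})

test_that("every read lands in exactly one demultiplexing bin", {
  set.seed(23)
  man <- tiny_manifest()
  reads <- c(
    vapply(1:10, function(i) structured_read(random_dna(70), man, "sampleA"),
           character(1)),
    vapply(1:8, function(i) structured_read(random_dna(70), man, "sampleB"),
           character(1)),
    vapply(1:5, function(i) random_dna(90), character(1)))
  names(reads) <- sprintf("r%02d", seq_along(reads))
  dm <- demux_reads(reads, man, min_len = 50)
  expect_identical(nrow(dm$reads), length(reads))
  counts <- table(dm$reads$sample_id)
  expect_identical(sum(counts), length(reads))
  expect_identical(as.integer(counts[["sampleA"]]), 10L)
  expect_identical(as.integer(counts[["sampleB"]]), 8L)
  expect_identical(as.integer(counts[["unassigned"]]), 5L)
})

test_that("demultiplexing is orientation-symmetric under role swap", {
  set.seed(29)
  man <- tiny_manifest()
  reads <- c(
    vapply(1:6, function(i) structured_read(random_dna(60), man, "sampleA"),
           character(1)),
    vapply(1:6, function(i) structured_read(random_dna(60), man, "sampleB"),
           character(1)))
  # flip half the reads to mixed orientations
  reads[c(2, 4, 7, 11)] <- vapply(reads[c(2, 4, 7, 11)], rc, character(1))
  names(reads) <- sprintf("r%02d", seq_along(reads))
  dm1 <- demux_reads(reads, man)
  # reverse-complement every read and swap barcode/primer roles
  flipped <- vapply(reads, rc, character(1))
  man2 <- barcode_manifest(data.frame(
    sample_id = man$sample_id, bc_fwd = man$bc_rev, bc_rev = man$bc_fwd,
    primer_fwd = man$primer_rev, primer_rev = man$primer_fwd,
    stringsAsFactors = FALSE))
  dm2 <- demux_reads(flipped, man2)
  expect_identical(dm1$reads$sample_id, dm2$reads$sample_id)
})

test_that("raising the edit budget never loses assignments", {
  set.seed(31)
  man <- sim_manifest(c("s1", "s2", "s3"))
  prefixes <- character(60)
  for (i in seq_along(prefixes)) {
    bc <- man$bc_fwd[sample(3, 1)]
    chars <- strsplit(paste0(bc, random_dna(20)), "")[[1]]
    for (p in sample(18, sample(0:4, 1))) chars[p] <- sample(c("A","C","G","T"), 1)
    prefixes[i] <- paste(chars, collapse = "")
  }
  n_assigned <- vapply(0:4, function(k)
    sum(vapply(prefixes, function(r)
      !is.na(assign_barcode(r, man, max_edits = k)$sample_id), logical(1))),
    numeric(1))
  expect_true(all(diff(n_assigned) >= 0))
})

test_that("demux writes per-sample FASTQ and stats", {
  set.seed(37)
  man <- tiny_manifest()
  reads <- c(a1 = structured_read(random_dna(60), man, "sampleA"),
             b1 = structured_read(random_dna(60), man, "sampleB"),
             junk = random_dna(80))
  outdir <- withr::local_tempdir()
  dm <- demux_reads(reads, man, outdir = outdir)
  expect_true(file.exists(file.path(outdir, "sampleA.fastq")))
  expect_true(file.exists(file.path(outdir, "unassigned.fastq")))
  expect_true(file.exists(file.path(outdir, "demux_stats.tsv")))
  fq <- Biostrings::readDNAStringSet(file.path(outdir, "sampleA.fastq"),
                                     format = "fastq")
  expect_identical(names(fq), "a1")
})
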