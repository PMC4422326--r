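# A reference with known CpG positions for quantitation tests.
quant_ref <- function() amplicon_reference("amp", "AACGTTACGTTTACGTT")
# CpG sites: 2, 7, 13

# Build reads that report fixed calls at the three sites.
quant_reads <- function(calls_per_read, sample_id = "s") {
  lapply(seq_along(calls_per_read), function(i)
    make_aligned(sprintf("%s_r%03d", sample_id, i),
                 stats::setNames(calls_per_read[[i]], c("2", "7", "13")),
                 conv_vector(5, 0), sample_id = sample_id))
}

test_that("levels are n_meth / (n_meth + n_unmeth) with a 10X depth gate", {
  ref <- quant_ref()
  # site 2: 7 METH + 3 UNMETH = 10X -> retained at 0.7
  # site 7: 5 METH + 4 UNMETH + 1 AMBIG = 9X informative -> dropped
  # site 13: uncovered everywhere -> dropped
  calls <- c(rep(list(c("METH", "METH", "UNCOVERED")), 5),
             rep(list(c("METH", "UNMETH", "UNCOVERED")), 2),
             rep(list(c("UNMETH", "UNMETH", "UNCOVERED")), 2),
             list(c("UNMETH", "AMBIG", "UNCOVERED")))
  p <- quantify(quant_reads(calls), ref, min_depth = 10)
  expect_identical(nrow(p$sites), 1L)
  expect_identical(p$sites$pos, 2L)
  expect_equal(p$sites$level, 0.7)
  expect_identical(p$sites$depth, 10L)
  expect_identical(attr(p, "n_sites_dropped"), 2L)
  # AMBIG excluded from numerator and denominator
  p9 <- quantify(quant_reads(calls), ref, min_depth = 9)
  s7 <- p9$sites[p9$sites$pos == 7, ]
  expect_identical(s7$depth, 9L)
  expect_equal(s7$level, 5 / 9)
  expect_identical(s7$n_ambig, 1L)
})

test_that("raising the depth gate never adds sites", {
  set.seed(73)
  ref <- quant_ref()
  calls <- replicate(25, sample(c("METH", "UNMETH", "UNCOVERED"), 3,
                                replace = TRUE), simplify = FALSE)
  reads <- quant_reads(calls)
  n_sites <- vapply(c(1, 5, 10, 20), function(d)
    nrow(quantify(reads, ref, min_depth = d)$sites), numeric(1))
  expect_true(all(diff(n_sites) <= 0))
})

test_that("binomial sampling bounds the estimate at 100X", {
  set.seed(21)
  ref <- quant_ref()
  n <- 100
  reps <- 20
  levels <- vapply(seq_len(reps), function(r) {
    draws <- sample(c("METH", "UNMETH"), n, replace = TRUE)
    calls <- lapply(draws, function(d) c(d, "UNCOVERED", "UNCOVERED"))
    p <- quantify(quant_reads(calls), ref, min_depth = 10)
    # the estimator reproduces the realized draw fraction exactly
    expect_equal(p$sites$level[1], mean(draws == "METH"))
    p$sites$level[1]
  }, numeric(1))
  # and is unbiased: mean over replicates within 3 SEs of truth
  expect_lt(abs(mean(levels) - 0.5), 3 * sqrt(0.25 / (n * reps)))
})

test_that("empty input yields an empty profile with a warning", {
  expect_warning(p <- quantify(list(), quant_ref()), "no reads")
  expect_identical(nrow(p$sites), 0L)
})

test_that("replicate statistics: identical and anticorrelated profiles", {
  # identical profiles -> r = 1, SD = 0
  p <- structure(list(sample_id = "a", amplicon_id = "amp",
                      sites = data.frame(pos = c(2L, 7L, 13L),
                                         level = c(0.2, 0.5, 0.9),
                                         depth = 20L, n_meth = 10L,
                                         n_unmeth = 10L, n_ambig = 0L)),
                 class = "methylation_profile")
  p2 <- p; p2$sample_id <- "b"
  rs <- replicate_stats(list(p, p2))
  expect_equal(unname(rs$correlation[1, 2]), 1.0)
  expect_true(all(rs$per_site_sd$sd == 0))
  expect_equal(rs$median_sd, 0)
  # perfect anticorrelation on two sites
  q1 <- p;  q1$sites <- data.frame(pos = c(2L, 7L), level = c(0.2, 0.8),
                                   depth = 20L, n_meth = 4L, n_unmeth = 16L,
                                   n_ambig = 0L)
  q2 <- q1; q2$sites$level <- c(0.8, 0.2); q2$sample_id <- "b"
  rs2 <- replicate_stats(list(q1, q2))
  expect_equal(unname(rs2$correlation[1, 2]), -1.0)
})

test_that("replicate statistics equal the textbook formulas", {
  set.seed(79)
  ref <- quant_ref()
  mk <- function(levels, id) structure(
    list(sample_id = id, amplicon_id = "amp",
         sites = data.frame(pos = c(2L, 7L, 13L), level = levels,
                            depth = 50L, n_meth = 0L, n_unmeth = 0L,
                            n_ambig = 0L)),
    class = "methylation_profile")
  lv <- matrix(runif(9), nrow = 3)   # 3 sites x 3 replicates
  profs <- lapply(1:3, function(j) mk(lv[, j], paste0("rep", j)))
  rs <- replicate_stats(profs)
  # direct recomputation: Pearson r and n-1 SD
  for (i in 1:2) for (j in (i + 1):3) {
    xi <- lv[, i]; xj <- lv[, j]
    r_direct <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(unname(rs$correlation[i, j]), r_direct)
  }
  sd_direct <- apply(lv, 1, function(x)
    sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
  expect_equal(rs$per_site_sd$sd, sd_direct)
  expect_equal(rs$median_sd, sort(sd_direct)[2])
})

test_that("zero-variance replicates give NA correlation, not 0 or 1", {
  flat <- structure(list(sample_id = "a", amplicon_id = "amp",
                         sites = data.frame(pos = c(2L, 7L), level = c(0.5, 0.5),
                                            depth = 20L, n_meth = 10L,
                                            n_unmeth = 10L, n_ambig = 0L)),
                    class = "methylation_profile")
  vary <- flat; vary$sites$level <- c(0.2, 0.8); vary$sample_id <- "b"
  rs <- replicate_stats(list(flat, vary))
  expect_true(is.na(rs$correlation[1, 2]))
  expect_identical(rs$n_undefined_pairs, 1L)
})

test_that("platform comparison intersects sites and computes r", {
  a <- c(`2` = 0.1, `7` = 0.5, `13` = 0.9)
  expect_equal(compare_platforms(a, a)$pearson_r, 1.0)
  expect_true(all(compare_platforms(a, a)$differences$diff == 0))
  # disjoint maps
  b <- c(`100` = 0.5)
  cmp <- compare_platforms(a, b)
  expect_identical(cmp$n_common, 0L)
  expect_true(is.na(cmp$pearson_r))
  expect_identical(cmp$status, "no_common_sites")
  # noisy pair equals the closed-form recomputation on the same draws
  set.seed(2)
  truth <- runif(200)
  x <- truth + rnorm(200, 0, 0.05)
  y <- truth + rnorm(200, 0, 0.05)
  names(x) <- names(y) <- seq_along(x)
  cmp2 <- compare_platforms(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cmp2$pearson_r, unname(r_direct))
  expect_identical(cmp2$n_common, 200L)
})

test_that("island coverage counts lengths with an inclusive boundary", {
  islands <- data.frame(start = c(0, 1000, 5000),
                        end = c(200, 2500, 6600))   # lengths 200, 1500, 1600
  cov <- island_coverage(islands, max_amplicon = 1500)
  expect_identical(cov$n_islands, 3L)
  expect_identical(cov$n_coverable, 2L)
  expect_equal(cov$fraction, 2 / 3)
  # empty input is reported, not guessed
  empty <- island_coverage(data.frame(start = numeric(0), end = numeric(0)))
  expect_true(is.na(empty$fraction))
  expect_identical(empty$status, "empty")
})

test_that("BED islands load and malformed intervals name the line", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t200\tisl1", "chr1\t1000\t2500\tisl2",
               "chr2\t5000\t6600\tisl3"), path)
  cov <- island_coverage(path, max_amplicon = 1500)
  expect_equal(cov$fraction, 2 / 3)
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t200", "chr1\t500\t400"), bad)
  expect_error(island_coverage(bad), "line 2")
})

test_that("pooling volumes follow the equimolar formula", {
  # symmetric two-amplicon case
  v <- pooling_volumes(500, c(800, 800), 50, n_samples = 1)
  expect_equal(v$volume, c(5, 5))
  # single amplicon: L_i / sum(L) = 1
  v1 <- pooling_volumes(500, 800, 50)
  expect_equal(v1$volume, 10)
  expect_error(pooling_volumes(-1, 800, 50), "total_mass")
  expect_error(pooling_volumes(500, c(800, 0), 50), "lengths")
  expect_error(pooling_volumes(500, 800, -2), "concentrations")
})

test_that("pooling is equimolar and mass-conserving for random specs", {
  set.seed(17)
  for (i in 1:50) {
    m_amp <- sample(1:8, 1)
    n <- sample(1:30, 1)
    M <- runif(1, 10, 2000)
    L <- runif(m_amp, 100, 2000)
    C <- runif(m_amp, 1, 200)
    v <- pooling_volumes(M, L, C, n)
    molar <- v$volume * C / L
    expect_lt(max(abs(molar - molar[1])) / molar[1], 1e-12)
    expect_lt(abs(attr(v, "total_mass_check") - M) / M, 1e-12)
  }
})
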