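# toy site table builder: states given as per-site counts
toy_sites <- function(pos0, depth, implausible = 0L, contig = "chr1",
                      state = "MM") {
  n <- length(pos0)
  m <- matrix(0L, n, 9, dimnames = list(NULL, CPG_STATES))
  depth <- rep_len(depth, n)
  implausible <- rep_len(as.integer(implausible), n)
  state <- rep_len(state, n)
  for (i in seq_len(n)) m[i, state[i]] <- depth[i] - implausible[i]
  df <- data.frame(contig = rep_len(contig, n), pos0 = pos0, m,
                   implausible = implausible, depth = depth,
                   stringsAsFactors = FALSE)
  structure(df, class = c("site_state_counts", "data.frame"))
}

test_that("depth, blacklist and error filters fire in documented order", {
  sites <- toy_sites(pos0 = seq(0, 90, by = 10), depth = 1:10)
  f <- filter_sites(sites, min_depth = 5)
  expect_equal(f$report[["depth"]], 4L)
  expect_equal(f$report[["retained"]], 6L)
  expect_equal(nrow(f$sites), 6L)

  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(31, 60))
  f2 <- filter_sites(sites, min_depth = 5, blacklist = bl)
  # dyads at pos0 30, 40, 50 overlap the blacklist, but pos0 30 already
  # failed the depth filter, so only two count under "blacklist"
  expect_equal(f2$report[["depth"]], 4L)
  expect_equal(f2$report[["blacklist"]], 2L)
  expect_equal(f2$report[["retained"]], 4L)

  sites3 <- toy_sites(pos0 = c(0, 10, 20), depth = 10,
                      implausible = c(0L, 1L, 2L))
  f3 <- filter_sites(sites3, min_depth = 5, max_errors = 1)
  expect_equal(f3$report[["errors"]], 1L)
  expect_equal(f3$sites$pos0, c(0L, 10L))

  # removal reasons partition the removed set
  f4 <- filter_sites(toy_sites(pos0 = seq(0, 90, 10), depth = c(1:9, 10),
                               implausible = c(rep(0L, 9), 3L)),
                     min_depth = 5, blacklist = bl, max_errors = 1)
  expect_equal(sum(f4$report[c("depth", "blacklist", "errors",
                               "retained")]), 10L)
})

test_that("blacklists can come from BED files; malformed BED errors", {
  sites <- toy_sites(pos0 = c(100, 200), depth = 10)
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t90\t110", bed)
  f <- filter_sites(sites, min_depth = 1, blacklist = bed)
  expect_equal(f$sites$pos0, 200L)
  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\tnotanumber\t110"), bad)
  expect_error(filter_sites(sites, blacklist = bad), "malformed BED")
  unlink(c(bed, bad))
})

test_that("site fractions are percentages that sum to 100 with groups", {
  m <- matrix(0L, 2, 9, dimnames = list(NULL, CPG_STATES))
  m[1, c("MM", "MC", "CM")] <- c(6L, 2L, 2L)
  m[2, c("HC", "CH", "HH")] <- c(1L, 1L, 2L)
  sites <- structure(
    data.frame(contig = "c", pos0 = c(0L, 10L), m,
               implausible = c(1L, 0L), depth = c(11L, 4L)),
    class = c("site_state_counts", "data.frame"))
  fr <- site_fractions(sites)
  expect_equal(rowSums(fr[, CPG_STATES]), c(100, 100), ignore_attr = TRUE)
  expect_equal(fr$MC_CM, fr$MC + fr$CM)
  expect_equal(fr$HC_CH[2], 50)
  expect_equal(fr$HM_MH, c(0, 0))
})

test_that("region means average contained sites and honor empty regions", {
  sites <- toy_sites(pos0 = c(10, 30, 200), depth = 10,
                     state = c("HC", "CH", "MM"))
  fr <- site_fractions(sites)
  regions <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(1, 100, 500),
                                                     c(50, 150, 600)))
  rm_ <- region_means(fr, regions)
  # region 1 holds one pure-HC and one pure-CH site: HC+CH mean is 100,
  # each component 50
  expect_equal(rm_$n_sites, c(2L, 0L, 0L))
  expect_equal(rm_$HC[1], 50)
  expect_equal(rm_$HC_CH[1], 100)
  expect_true(all(is.na(rm_$MM[2:3])))  # empty regions are missing, not 0
  # permutation invariance and additivity over disjoint unions
  rm_shuf <- region_means(fr[c(3, 1, 2), ], rev(regions))
  expect_equal(rm_shuf$HC_CH[3], rm_$HC_CH[1])
  expect_equal(rm_shuf$n_sites, rev(rm_$n_sites))
})

test_that("regions read from BED produce the same means", {
  sites <- toy_sites(pos0 = c(10, 30), depth = 10, state = c("MM", "CC"))
  fr <- site_fractions(sites)
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t50\tr1", bed)
  rm_ <- region_means(fr, bed)
  expect_equal(rm_$MM, 50)
  expect_equal(rm_$start, 0L)
  expect_equal(rm_$end, 50L)
  unlink(bed)
})

test_that("shuffled backgrounds reproduce the genome mean on uniform data", {
  # uniform methylome: every site 60% MM / 40% CC
  pos <- seq(5, 4995, by = 10)
  m <- matrix(0L, length(pos), 9, dimnames = list(NULL, CPG_STATES))
  m[, "MM"] <- 6L
  m[, "CC"] <- 4L
  sites <- structure(
    data.frame(contig = "chr1", pos0 = pos, m, implausible = 0L,
               depth = 10L),
    class = c("site_state_counts", "data.frame"))
  fr <- site_fractions(sites)
  regions <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(1, 2001), c(400, 2400)))
  bg <- shuffled_background(fr, regions, c(chr1 = 5000), n_shuffles = 25,
                            seed = 81)
  expect_equal(dim(bg), c(25L, 12L))
  expect_true(all(abs(bg[, "MM"] - 60) < 1e-9))
  bg2 <- shuffled_background(fr, regions, c(chr1 = 5000), n_shuffles = 25,
                             seed = 81)
  expect_identical(bg, bg2)
  expect_error(shuffled_background(fr, regions, c(chr1 = 100), 5, 1),
               "longer than its contig")
})

test_that("background dispersion shrinks with more regions", {
  set.seed(82)
  pos <- seq(2, 9998, by = 7)
  m <- matrix(0L, length(pos), 9, dimnames = list(NULL, CPG_STATES))
  mmc <- rbinom(length(pos), 10, 0.6)
  m[, "MM"] <- mmc
  m[, "CC"] <- 10L - mmc
  sites <- structure(
    data.frame(contig = "chr1", pos0 = pos, m, implausible = 0L,
               depth = 10L),
    class = c("site_state_counts", "data.frame"))
  fr <- site_fractions(sites)
  few <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:2 * 100, width = 80))
  many <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(1:40 * 200, width = 80))
  bg_few <- shuffled_background(fr, few, c(chr1 = 10000), 60, seed = 83)
  bg_many <- shuffled_background(fr, many, c(chr1 = 10000), 60, seed = 84)
  expect_lt(sd(bg_many[, "MM"]), sd(bg_few[, "MM"]))
})

test_that("binned profiles are consistent, symmetric and flat when uniform", {
  pos <- seq(0, 999, by = 10)
  m <- matrix(0L, length(pos), 9, dimnames = list(NULL, CPG_STATES))
  m[, "MM"] <- 5L
  m[, "CC"] <- 5L
  sites <- structure(
    data.frame(contig = "chr1", pos0 = pos, m, implausible = 0L,
               depth = 10L),
    class = c("site_state_counts", "data.frame"))
  fr <- site_fractions(sites)
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(401, 600))
  # single region, one bin spanning it: equals the region mean
  pr <- binned_profile(fr, region, bin = 100L, flank = 100L, mode = "center")
  rm_ <- region_means(fr, region)
  mid_bins <- pr$bin_start >= -100 & pr$bin_end <= 100
  expect_equal(mean(pr$mean[mid_bins]), rm_$MM[1])
  # uniform data: profile flat at 50 everywhere it has sites
  expect_true(all(abs(pr$mean[pr$n_regions > 0] - 50) < 1e-9))
  prs <- binned_profile(fr, region, bin = 100L, flank = 0L, mode = "scaled",
                        scaled_length = 1000L)
  expect_true(all(abs(prs$mean[prs$n_regions > 0] - 50) < 1e-9))
})

test_that("center-mode profiles mirror a strand-symmetric landscape", {
  # MM on the left of the anchor, CC on the right, mirrored pair of sites
  pos <- c(485, 515)
  m <- matrix(0L, 2, 9, dimnames = list(NULL, CPG_STATES))
  m[, "MM"] <- c(10L, 0L)
  m[, "CC"] <- c(0L, 10L)
  sites <- structure(
    data.frame(contig = "chr1", pos0 = pos, m, implausible = 0L,
               depth = 10L),
    class = c("site_state_counts", "data.frame"))
  fr <- site_fractions(sites)
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(451, 550))
  pr_mm <- binned_profile(fr, region, bin = 20L, flank = 60L, level = "MM")
  pr_cc <- binned_profile(fr, region, bin = 20L, flank = 60L, level = "CC")
  expect_equal(pr_mm$mean, rev(pr_cc$mean))
})
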