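#' Read a BED file of intervals
#'
#' Thin wrapper over \code{rtracklayer::import} returning a
#' \link[GenomicRanges]{GRanges}; parse failures are reported as format
#' errors with the offending file.
#'
#' @param path BED file path (0-based half-open intervals).
#' @return a \code{GRanges}.
#' @export
read_bed <- function(path) {
  tryCatch(rtracklayer::import(path, format = "BED"),
           error = function(e) {
             stop("malformed BED file '", path, "': ", conditionMessage(e))
           })
}

# GRanges of the dyads (plus-strand C and the G), 1-based internally
sites_granges <- function(sites) {
  GenomicRanges::GRanges(sites$contig,
                         IRanges::IRanges(start = sites$pos0 + 1L,
                                          width = 2L))
}

#' Filter CpG sites by depth, blacklist and calling errors
#'
#' Applies the three site-level filters in a fixed order: double-stranded
#' depth below \code{min_depth}; overlap with a blacklisted region; more
#' than \code{max_errors} implausible (calling-error) quads. Each removed
#' site is counted once, under the first criterion it fails.
#'
#' @param sites a \code{site_state_counts} table.
#' @param min_depth minimum double-stranded depth (default 5).
#' @param blacklist \code{GRanges}, BED path, or \code{NULL}.
#' @param max_errors maximum implausible quads tolerated per site (default
#'   1; "multiple" calling errors, i.e. 2 or more, discard the site).
#' @return list with \code{sites} (retained table) and \code{report}
#'   (named counts: \code{depth, blacklist, errors, retained}).
#' @export
filter_sites <- function(sites, min_depth = 5L, blacklist = NULL,
                         max_errors = 1L) {
  stopifnot(min_depth >= 1L)
  if (is.character(blacklist)) blacklist <- read_bed(blacklist)
  fail_depth <- sites$depth < min_depth
  fail_bl <- rep(FALSE, nrow(sites))
  if (!is.null(blacklist) && length(blacklist) > 0L && nrow(sites) > 0L) {
    ov <- GenomicRanges::findOverlaps(sites_granges(sites), blacklist)
    fail_bl[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  fail_err <- sites$implausible > max_errors
  reason_depth <- fail_depth
  reason_bl <- !fail_depth & fail_bl
  reason_err <- !fail_depth & !fail_bl & fail_err
  keep <- !(fail_depth | fail_bl | fail_err)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(sites = out,
       report = c(depth = sum(reason_depth), blacklist = sum(reason_bl),
                  errors = sum(reason_err), retained = sum(keep)))
}

#' Per-site state percentages
#'
#' Converts a (filtered) site count table to per-site percentages of each
#' state over the valid calls, plus the grouped asymmetric-state totals
#' MC+CM, HC+CH and HM+MH.
#'
#' @param sites a \code{site_state_counts} table.
#' @return a \code{site_fractions} data.frame: \code{contig, pos0}, the
#'   nine state percentages (0-100), \code{MC_CM, HC_CH, HM_MH},
#'   \code{depth}.
#' @export
site_fractions <- function(sites) {
  cnt <- as.matrix(sites[, CPG_STATES, drop = FALSE])
  valid <- rowSums(cnt)
  pct <- 100 * cnt / ifelse(valid == 0, NA_real_, valid)
  df <- data.frame(contig = sites$contig, pos0 = sites$pos0, pct,
                   MC_CM = pct[, "MC"] + pct[, "CM"],
                   HC_CH = pct[, "HC"] + pct[, "CH"],
                   HM_MH = pct[, "HM"] + pct[, "MH"],
                   depth = sites$depth, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("site_fractions", "data.frame"))
}

level_columns <- function() c(CPG_STATES, "MC_CM", "HC_CH", "HM_MH")

#' Mean state levels per region
#'
#' For each region, the mean over contained CpG sites of each state
#' percentage (and grouped percentages). Regions containing no site emit
#' \code{NA}, not zero.
#'
#' @param fractions a \code{site_fractions} table.
#' @param regions \code{GRanges} or BED path.
#' @return data.frame with region coordinates (\code{contig, start, end},
#'   0-based half-open), \code{n_sites}, and one mean column per level.
#' @export
region_means <- function(fractions, regions) {
  if (is.character(regions)) regions <- read_bed(regions)
  gr_sites <- sites_granges(fractions)
  ov <- GenomicRanges::findOverlaps(gr_sites, regions)
  cols <- level_columns()
  n <- length(regions)
  out <- data.frame(contig = as.character(GenomicRanges::seqnames(regions)),
                    start = GenomicRanges::start(regions) - 1L,
                    end = GenomicRanges::end(regions),
                    n_sites = 0L, stringsAsFactors = FALSE)
  m <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  if (length(ov) > 0L) {
    sh <- S4Vectors::queryHits(ov)
    rh <- S4Vectors::subjectHits(ov)
    out$n_sites <- tabulate(rh, nbins = n)
    for (col in cols) {
      sums <- tapply(fractions[[col]][sh], rh, sum)
      ridx <- as.integer(names(sums))
      m[ridx, col] <- sums / out$n_sites[ridx]
    }
  }
  cbind(out, m)
}

#' Background state levels from shuffled regions
#'
#' Repeatedly re-places every region uniformly at random within its own
#' contig (length preserved) and records the across-region mean of each
#' state level, giving the background distribution against which observed
#' region levels can be compared.
#'
#' @param fractions a \code{site_fractions} table.
#' @param regions \code{GRanges} or BED path.
#' @param genome_sizes named vector of contig lengths (bp).
#' @param n_shuffles number of shuffles (>= 1).
#' @param seed integer seed.
#' @return matrix \code{n_shuffles} x levels; each entry is the mean over
#'   regions (ignoring empty regions) of the region mean level.
#' @export
shuffled_background <- function(fractions, regions, genome_sizes,
                                n_shuffles = 100L, seed = NULL) {
  stopifnot(n_shuffles >= 1L)
  if (is.character(regions)) regions <- read_bed(regions)
  ct <- as.character(GenomicRanges::seqnames(regions))
  w <- GenomicRanges::width(regions)
  if (any(!(ct %in% names(genome_sizes)))) {
    stop("region contig absent from genome_sizes")
  }
  L <- unname(genome_sizes[ct])
  if (any(w > L)) stop("region longer than its contig; cannot shuffle")
  cols <- level_columns()
  with_seed(seed, {
    out <- matrix(NA_real_, n_shuffles, length(cols),
                  dimnames = list(NULL, cols))
    for (s in seq_len(n_shuffles)) {
      new_start <- floor(runif(length(w), 0, L - w + 1))
      shuf <- GenomicRanges::GRanges(
        ct, IRanges::IRanges(start = new_start + 1L, width = w))
      rm_ <- region_means(fractions, shuf)
      out[s, ] <- colMeans(rm_[, cols, drop = FALSE], na.rm = TRUE)
    }
    out
  })
}

#' Binned meta-profile of state levels over regions
#'
#' \code{center} mode anchors each region at its midpoint and averages site
#' levels in fixed bins over \code{[-flank, +flank)}. \code{scaled} mode
#' rescales each region body to a fixed pseudo-length before binning, with
#' unscaled flanks on either side. Bin values are the mean over sites in
#' the bin, averaged across regions; bins with no sites in a region are
#' ignored for that region (missing, not zero).
#'
#' @param fractions a \code{site_fractions} table.
#' @param regions \code{GRanges} or BED path.
#' @param bin bin size in bp (>= 1).
#' @param flank flank size in bp; must be a multiple of \code{bin}.
#' @param mode \code{"center"} or \code{"scaled"}.
#' @param scaled_length pseudo-length regions are scaled to in
#'   \code{scaled} mode; must be a multiple of \code{bin}.
#' @param level which level column to profile (default \code{"MM"}).
#' @return data.frame \code{bin_start, bin_end, mean, n_regions}; bin
#'   coordinates are relative to the anchor (center mode) or to the scaled
#'   body start (scaled mode, flanks negative).
#' @export
binned_profile <- function(fractions, regions, bin = 200L, flank = 1000L,
                           mode = c("center", "scaled"),
                           scaled_length = 5000L, level = "MM") {
  mode <- match.arg(mode)
  stopifnot(bin >= 1L, flank %% bin == 0L, level %in% level_columns())
  if (is.character(regions)) regions <- read_bed(regions)
  ct <- as.character(GenomicRanges::seqnames(regions))
  rstart <- GenomicRanges::start(regions) - 1L
  rend <- GenomicRanges::end(regions)
  if (mode == "center") {
    edges <- seq(-flank, flank, by = bin)
  } else {
    stopifnot(scaled_length %% bin == 0L)
    edges <- seq(-flank, scaled_length + flank, by = bin)
  }
  nb <- length(edges) - 1L
  acc <- matrix(0, length(regions), nb)
  hasv <- matrix(FALSE, length(regions), nb)
  fr_ct <- fractions$contig
  fr_pos <- fractions$pos0
  fr_val <- fractions[[level]]
  for (r in seq_along(regions)) {
    on_ct <- fr_ct == ct[r]
    pos <- fr_pos[on_ct]
    val <- fr_val[on_ct]
    if (mode == "center") {
      anchor <- (rstart[r] + rend[r]) %/% 2L
      rel <- pos - anchor
    } else {
      body <- pos >= rstart[r] & pos < rend[r]
      rel <- numeric(length(pos))
      rel[body] <- (pos[body] - rstart[r]) / (rend[r] - rstart[r]) *
        scaled_length
      rel[!body] <- ifelse(pos[!body] < rstart[r], pos[!body] - rstart[r],
                           pos[!body] - rend[r] + scaled_length)
    }
    bi <- findInterval(rel, edges, rightmost.closed = FALSE)
    ok <- bi >= 1L & bi <= nb & rel < edges[nb + 1L] & !is.na(val)
    if (!any(ok)) next
    means <- tapply(val[ok], bi[ok], mean)
    idx <- as.integer(names(means))
    acc[r, idx] <- means
    hasv[r, idx] <- TRUE
  }
  nreg <- colSums(hasv)
  avg <- ifelse(nreg > 0, colSums(acc * hasv) / nreg, NA_real_)
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1L],
             mean = avg, n_regions = nreg)
}

#' Write per-site fractions as TSV or BED-flavored track
#'
#' @param fractions a \code{site_fractions} table.
#' @param path output path.
#' @param format \code{"tsv"} (all columns) or \code{"bed"} (dyad interval
#'   plus one chosen level as score).
#' @param level level column used as BED score.
#' @export
write_site_fractions <- function(fractions, path, format = c("tsv", "bed"),
                                 level = "MM") {
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv(as.data.frame(fractions), path)
  } else {
    df <- data.frame(fractions$contig, fractions$pos0, fractions$pos0 + 2L,
                     level, fractions[[level]])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
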