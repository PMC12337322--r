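#' Index a reference for converted-space alignment
#'
#' Deaminated reads live in a three-letter alphabet (C collapsed into T on
#' the read-out strand), so alignment seeds on the C-to-T-collapsed
#' reference, separately for the plus strand and the reverse complement.
#' The index also caches CpG dyad positions for calling. This is a
#' desk-scale seeded aligner intended for references up to a few megabases.
#'
#' @param reference \link[Biostrings]{DNAStringSet}, named character vector,
#'   or \code{duplex_methylome}.
#' @param k seed length on the collapsed alphabet.
#' @return an object of class \code{ref_index}.
#' @export
ref_index <- function(reference, k = 16L) {
  ref <- as_ref_chars(reference)
  stopifnot(k >= 8L)
  rc <- revcomp(ref)
  sites <- cpg_sites(ref)
  cpg <- split(sites$pos0, sites$contig)
  structure(list(contigs = names(ref), len = setNames(nchar(ref), names(ref)),
                 plus_raw = ref, minus_raw = setNames(rc, names(ref)),
                 plus_col = setNames(collapse3(ref), names(ref)),
                 minus_col = setNames(collapse3(rc), names(ref)),
                 cpg = cpg, k = k),
            class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat(sprintf("ref_index: %d contig(s), %d bp, k=%d\n",
              length(x$contigs), sum(x$len), x$k))
  invisible(x)
}

# candidate fragment starts for one collapsed read on one collapsed strand
# string; returns 0-based starts implied by exact k-mer seed hits at up to
# three read offsets
seed_starts <- function(read_col, strand_col, k) {
  lr <- nchar(read_col)
  if (lr < k) return(integer(0))
  offs <- unique(pmax(1L, c(1L, (lr - k) %/% 2L + 1L, lr - k + 1L)))
  out <- integer(0)
  for (o in offs) {
    kmer <- substr(read_col, o, o + k - 1L)
    m <- gregexpr(kmer, strand_col, fixed = TRUE)[[1L]]
    h <- as.integer(m)
    if (!(length(h) == 1L && h[1L] == -1L)) {
      out <- c(out, h - 1L - (o - 1L))
    }
  }
  unique(out)
}

#' Align one insert quad in converted space
#'
#' Inserts a (original plus) and b (original minus) determine the locus:
#' exact k-mer seeds from their collapsed sequences propose candidate
#' fragment intervals, which are then scored full-length under the
#' asymmetric conversion rule (read T matches reference C or T; read C
#' matches only reference C; A/G exact). Inserts c and d are scored at the
#' same locus for complementary consistency but do not seed. The unique
#' best-scoring interval within the mismatch budget wins; ties or no
#' candidate give an unaligned result.
#'
#' The fragment interval is taken from insert a (full length at candidate
#' start); b, c, d may be 3'-truncated by the read length and are scored
#' over the subinterval they cover.
#'
#' @param quad list or one-row data.frame with \code{a, b, c, d}.
#' @param index a \code{\link{ref_index}}.
#' @param max_mismatch_rate mismatch budget as a fraction of total scored
#'   bases.
#' @return list \code{contig, start, end, score, aligned}; \code{aligned =
#'   FALSE} (with NA coordinates) when no unique acceptable match exists.
#' @export
align_quad <- function(quad, index, max_mismatch_rate = 0.1) {
  a <- quad$a; b <- quad$b; cc <- quad$c; d <- quad$d
  la <- nchar(a); lb <- nchar(b); lc <- nchar(cc); ld <- nchar(d)
  k <- index$k
  ca <- collapse3(a)
  cb <- collapse3(b)
  budget <- floor(max_mismatch_rate * (la + lb + lc + ld))

  unaligned <- list(contig = NA_character_, start = NA_integer_,
                    end = NA_integer_, score = NA_integer_, aligned = FALSE)
  best <- NULL
  best_score <- budget + 1L
  tie <- FALSE
  for (ct in index$contigs) {
    L <- index$len[[ct]]
    s_a <- seed_starts(ca, index$plus_col[[ct]], k)
    # b seeds the minus strand; its first base sits at plus position end-1
    ends_b <- L - (seed_starts(cb, index$minus_col[[ct]], k)) # = end of fragment
    cand <- unique(c(s_a, ends_b - la))
    cand <- cand[cand >= 0L & cand + la <= L]
    for (s0 in cand) {
      e0 <- s0 + la
      sc <- conv_mismatch(a, substr(index$plus_raw[[ct]], s0 + 1L, e0))
      if (is.na(sc) || sc > best_score) next
      # minus-oriented segment for plus range [e0-n, e0)
      mseg <- function(n) substr(index$minus_raw[[ct]], L - e0 + 1L,
                                 L - e0 + n)
      sc <- sc + conv_mismatch(b, mseg(lb))
      if (is.na(sc) || sc > best_score) next
      sc <- sc + conv_mismatch(cc, substr(index$plus_raw[[ct]], s0 + 1L,
                                          s0 + lc))
      if (is.na(sc) || sc > best_score) next
      sc <- sc + conv_mismatch(d, mseg(ld))
      if (is.na(sc) || sc > best_score || sc > budget) next
      if (!is.null(best) && sc == best_score &&
          !(best$contig == ct && best$start == s0)) {
        tie <- TRUE
        next
      }
      if (is.null(best) || sc < best_score) {
        best <- list(contig = ct, start = s0, end = e0, score = sc,
                     aligned = TRUE)
        best_score <- sc
        tie <- FALSE
      }
    }
  }
  if (is.null(best) || tie) unaligned else best
}

#' Align a table of insert quads
#'
#' @param quads data.frame with columns \code{name, a, b, c, d}.
#' @param index a \code{\link{ref_index}}.
#' @param max_mismatch_rate per-quad mismatch budget (fraction of bases).
#' @return data.frame \code{name, contig, start, end, score, aligned}; one
#'   row per input quad.
#' @export
align_quads <- function(quads, index, max_mismatch_rate = 0.1) {
  n <- nrow(quads)
  contig <- character(n); start <- integer(n); end <- integer(n)
  score <- integer(n); aligned <- logical(n)
  for (i in seq_len(n)) {
    al <- align_quad(quads[i, ], index, max_mismatch_rate)
    contig[i] <- al$contig; start[i] <- al$start; end[i] <- al$end
    score[i] <- al$score; aligned[i] <- al$aligned
  }
  data.frame(name = quads$name, contig = contig, start = start, end = end,
             score = score, aligned = aligned, stringsAsFactors = FALSE)
}

#' Coordinate-based duplicate removal
#'
#' Keeps one representative per fragment interval (contig, start, end); the
#' representative is the lexicographically smallest read name, which makes
#' the operation deterministic and idempotent. Unaligned rows are dropped.
#'
#' @param alignments data.frame from \code{\link{align_quads}}.
#' @return the deduplicated alignment data.frame.
#' @export
deduplicate <- function(alignments) {
  al <- alignments[alignments$aligned %in% TRUE, , drop = FALSE]
  if (nrow(al) == 0L) return(al)
  al <- al[order(al$name), , drop = FALSE]
  key <- paste(al$contig, al$start, al$end)
  out <- al[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract per-fragment call quads at every covered CpG dyad
#'
#' For each aligned (and deduplicated) fragment and each CpG dyad fully
#' inside the fragment interval and covered by all four inserts, reads out
#' the four binary calls: insert base C gives 1, T gives 0; any other base
#' at a call position skips the dyad for that fragment (counted in the
#' \code{skipped} attribute).
#'
#' @param alignments deduplicated alignment data.frame.
#' @param quads the insert-quad data.frame the alignments came from.
#' @param index the \code{\link{ref_index}}.
#' @return data.frame \code{name, contig, pos0, a, d, b, c}; attribute
#'   \code{skipped} counts dyads dropped for a non-C/T base.
#' @export
call_quads <- function(alignments, quads, index) {
  qi <- match(alignments$name, quads$name)
  stopifnot(!anyNA(qi))
  out <- vector("list", nrow(alignments))
  skipped <- 0L
  for (i in seq_len(nrow(alignments))) {
    ct <- alignments$contig[i]
    s0 <- alignments$start[i]
    e0 <- alignments$end[i]
    pos <- index$cpg[[ct]]
    pos <- pos[pos >= s0 & pos + 1L <= e0 - 1L]
    if (length(pos) == 0L) next
    q <- quads[qi[i], ]
    la <- nchar(q$a); lb <- nchar(q$b); lc <- nchar(q$c); ld <- nchar(q$d)
    off_p <- pos - s0 + 1L   # dyad C in plus-oriented inserts (a, c)
    off_m <- e0 - pos - 1L   # dyad C in minus-oriented inserts (b, d)
    cov <- off_p <= la & off_p <= lc & off_m <= lb & off_m <= ld
    pos <- pos[cov]; off_p <- off_p[cov]; off_m <- off_m[cov]
    if (length(pos) == 0L) next
    base_call <- function(seq, off) {
      ch <- substring(seq, off, off)
      ifelse(ch == "C", 1L, ifelse(ch == "T", 0L, NA_integer_))
    }
    a <- base_call(q$a, off_p)
    d <- base_call(q$d, off_m)
    b <- base_call(q$b, off_m)
    cc <- base_call(q$c, off_p)
    ok <- !(is.na(a) | is.na(d) | is.na(b) | is.na(cc))
    skipped <- skipped + sum(!ok)
    if (!any(ok)) next
    out[[i]] <- data.frame(name = alignments$name[i], contig = ct,
                           pos0 = pos[ok], a = a[ok], d = d[ok], b = b[ok],
                           c = cc[ok], stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out) > 0L) {
    do.call(rbind, out)
  } else {
    data.frame(name = character(0), contig = character(0), pos0 = integer(0),
               a = integer(0), d = integer(0), b = integer(0), c = integer(0))
  }
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Compile per-fragment calls into per-site state counts
#'
#' Each call quad is decoded into one of the nine duplex states or flagged
#' implausible. Valid states increment the per-site state counters;
#' implausible quads are tallied separately (kept for QC, excluded from
#' state fractions downstream). Depth is the number of deduplicated
#' fragments contributing any decodeable-or-implausible quad at the dyad.
#'
#' @param calls data.frame from \code{\link{call_quads}}.
#' @return a \code{site_state_counts} data.frame: \code{contig, pos0}, one
#'   count column per state, \code{implausible}, \code{depth}.
#' @export
compile_sites <- function(calls) {
  lev <- c(CPG_STATES, "implausible")
  if (nrow(calls) == 0L) {
    m <- as.data.frame(matrix(integer(0), 0, length(lev),
                              dimnames = list(NULL, lev)))
    return(structure(cbind(data.frame(contig = character(0),
                                      pos0 = integer(0)), m,
                           depth = integer(0)),
                     class = c("site_state_counts", "data.frame")))
  }
  st <- decode_state(calls$a, calls$d, calls$b, calls$c)
  st[is.na(st)] <- "implausible"
  key <- paste(calls$contig, calls$pos0, sep = "\r")
  tab <- table(key, factor(st, levels = lev))
  keys <- rownames(tab)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  df <- data.frame(contig = vapply(parts, `[`, character(1), 1L),
                   pos0 = as.integer(vapply(parts, `[`, character(1), 2L)),
                   stringsAsFactors = FALSE)
  counts <- as.data.frame.matrix(tab)
  df <- cbind(df, counts)
  df$depth <- rowSums(counts)
  df <- df[order(df$contig, df$pos0), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("site_state_counts", "data.frame"))
}

#' Write / read a per-site state-count table
#'
#' @param sites a \code{site_state_counts} data.frame.
#' @param path TSV path.
#' @export
write_site_counts <- function(sites, path) {
  write_tsv(as.data.frame(sites), path)
}

#' @rdname write_site_counts
#' @export
read_site_counts <- function(path) {
  df <- read_tsv(path)
  structure(df, class = c("site_state_counts", "data.frame"))
}
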