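#' Filter read pairs by hairpin-adapter configuration
#'
#' A read pair is a target (retained) iff Read 1 contains the intact hairpin
#' adapter at exactly one position and Read 2 contains the cleavage remnant
#' at exactly one position, each within \code{max_mismatch} substitutions.
#' Ligation side products carry a different adapter configuration and fail
#' this test. Matching is in deaminated read space by Hamming distance at
#' each offset (no indels).
#'
#' @param fastq_r1,fastq_r2 paths to (optionally gzipped) FASTQ files, or
#'   named character vectors of read sequences (e.g. from
#'   \code{\link{simulate_reads}}).
#' @param adapters a \code{\link{hairpin_adapters}} configuration.
#' @param max_mismatch maximum substitutions per adapter match.
#' @return list with \code{r1, r2} (retained pairs), \code{hit1, hit2}
#'   (1-based start of the adapter match in each retained read) and
#'   \code{rejects}, a named integer vector of rejection-reason counts
#'   (\code{no_adapter}, \code{ambiguous}).
#' @export
filter_target_pairs <- function(fastq_r1, fastq_r2,
                                adapters = hairpin_adapters(),
                                max_mismatch = 2L) {
  r1 <- if (is.character(fastq_r1) && is.null(names(fastq_r1))) {
    read_fastq(fastq_r1)
  } else fastq_r1
  r2 <- if (is.character(fastq_r2) && is.null(names(fastq_r2))) {
    read_fastq(fastq_r2)
  } else fastq_r2
  if (!identical(names(r1), names(r2))) {
    stop("R1/R2 read names do not match")
  }
  h1 <- adapter_hits(r1, adapters$intact_rs, max_mismatch)
  h2 <- adapter_hits(r2, adapters$remnant_rs, max_mismatch)
  keep <- h1$count == 1L & h2$count == 1L
  no_adapter <- sum(!keep & (h1$count == 0L | h2$count == 0L))
  ambiguous <- sum(!keep) - no_adapter
  list(r1 = r1[keep], r2 = r2[keep],
       hit1 = h1$start[keep], hit2 = h2$start[keep],
       rejects = c(no_adapter = no_adapter, ambiguous = ambiguous))
}

# vectorized approximate matching of one adapter against many reads
adapter_hits <- function(reads, pattern, max_mismatch) {
  subj <- Biostrings::DNAStringSet(reads)
  m <- Biostrings::vmatchPattern(pattern, subj, max.mismatch = max_mismatch,
                                 fixed = TRUE)
  cnt <- S4Vectors::elementNROWS(m)
  st <- rep(NA_integer_, length(reads))
  st[cnt == 1L] <- unlist(BiocGenerics::start(m)[cnt == 1L], use.names = FALSE)
  list(count = cnt, start = st)
}

#' Extract the four insert sequences from one retained read pair
#'
#' Read 1 splits at the intact-adapter match into insert a (before) and
#' insert b (after, trimmed of the trailing cleavage remnant); Read 2 splits
#' at the remnant match into insert c and insert d (trimmed of the trailing
#' intact adapter). Trailing adapters truncated by the end of the read are
#' trimmed by longest-prefix match. Pairs yielding any empty insert are
#' discarded (reason \code{incomplete_quad}).
#'
#' @param r1,r2 read sequences (single strings).
#' @param adapters a \code{\link{hairpin_adapters}} configuration.
#' @param max_mismatch maximum substitutions per adapter match.
#' @return named list \code{a, b, c, d}, or \code{NULL} when the pair does
#'   not yield all four inserts.
#' @export
extract_inserts <- function(r1, r2, adapters = hairpin_adapters(),
                            max_mismatch = 2L) {
  f <- filter_target_pairs(setNames(r1, "x"), setNames(r2, "x"),
                           adapters, max_mismatch)
  if (length(f$r1) == 0L) return(NULL)
  q <- extract_from_hits(f$r1, f$r2, f$hit1, f$hit2, adapters, max_mismatch)
  if (nrow(q) == 0L ||
      any(nchar(c(q$a, q$b, q$c, q$d)) == 0L)) {
    return(NULL)
  }
  list(a = q$a, b = q$b, c = q$c, d = q$d)
}

# vectorized splitting of retained pairs at known adapter hit positions
extract_from_hits <- function(r1, r2, hit1, hit2, adapters, max_mismatch) {
  li <- nchar(adapters$intact_rs)
  lr <- nchar(adapters$remnant_rs)
  a <- substr(r1, 1L, hit1 - 1L)
  tail1 <- substr(r1, hit1 + li, nchar(r1))
  b <- cut_trailing(tail1, adapters$remnant_rs, max_mismatch)
  cc <- substr(r2, 1L, hit2 - 1L)
  tail2 <- substr(r2, hit2 + lr, nchar(r2))
  d <- cut_trailing(tail2, adapters$intact_rs, max_mismatch)
  data.frame(name = names(r1), a = a, b = b, c = cc, d = d,
             stringsAsFactors = FALSE, row.names = NULL)
}

# remove a trailing adapter from each sequence: first by full approximate
# match anywhere in the tail (first hit wins), then by longest adapter
# prefix matching the sequence end (the read may truncate the adapter)
cut_trailing <- function(seqs, adapter, max_mismatch) {
  hits <- adapter_first_hit(seqs, adapter, max_mismatch)
  out <- ifelse(is.na(hits), seqs, substr(seqs, 1L, hits - 1L))
  need <- which(is.na(hits) & nchar(out) > 0L)
  for (i in need) {
    out[i] <- trim_partial_suffix(out[i], adapter, max_mismatch)
  }
  out
}

adapter_first_hit <- function(seqs, pattern, max_mismatch) {
  keep <- nchar(seqs) >= nchar(pattern)
  st <- rep(NA_integer_, length(seqs))
  if (any(keep)) {
    m <- Biostrings::vmatchPattern(pattern, Biostrings::DNAStringSet(seqs[keep]),
                                   max.mismatch = max_mismatch, fixed = TRUE)
    first <- vapply(BiocGenerics::start(m), function(s) {
      if (length(s) == 0L) NA_integer_ else s[[1L]]
    }, integer(1))
    st[keep] <- first
  }
  st
}

# longest prefix of `adapter` matching the end of `x`; the mismatch budget
# scales with the matched length (exact below 8 nt) so chance overlaps of
# real sequence cost at most a base or two of genuine insert
trim_partial_suffix <- function(x, adapter, max_mismatch) {
  nx <- nchar(x)
  hi <- min(nchar(adapter) - 1L, nx)
  if (hi < 1L) return(x)
  for (L in seq(hi, 1L)) {
    allowed <- if (L >= 12L) max_mismatch else if (L >= 8L) 1L else 0L
    mm <- sum(charToRaw(substr(x, nx - L + 1L, nx)) !=
                charToRaw(substr(adapter, 1L, L)))
    if (mm <= allowed) return(substr(x, 1L, nx - L))
  }
  x
}

#' Filter read pairs and extract all insert quads
#'
#' Convenience wrapper running \code{\link{filter_target_pairs}} then the
#' insert extraction over every retained pair.
#'
#' @inheritParams filter_target_pairs
#' @return list with \code{quads} (data.frame \code{name, a, b, c, d}) and
#'   \code{rejects} (named counts: \code{no_adapter, ambiguous,
#'   incomplete_quad}).
#' @export
extract_quads <- function(fastq_r1, fastq_r2, adapters = hairpin_adapters(),
                          max_mismatch = 2L) {
  f <- filter_target_pairs(fastq_r1, fastq_r2, adapters, max_mismatch)
  q <- extract_from_hits(f$r1, f$r2, f$hit1, f$hit2, adapters, max_mismatch)
  complete <- nchar(q$a) > 0L & nchar(q$b) > 0L & nchar(q$c) > 0L &
    nchar(q$d) > 0L
  list(quads = q[complete, , drop = FALSE],
       rejects = c(f$rejects, incomplete_quad = sum(!complete)))
}

#' Write an insert-quad table and its rejection summary
#'
#' @param x result of \code{\link{extract_quads}}.
#' @param quads_tsv path for the quad TSV (\code{name, a, b, c, d}).
#' @param rejects_json optional path for a JSON rejection summary.
#' @return invisibly, the TSV path.
#' @export
write_quads <- function(x, quads_tsv, rejects_json = NULL) {
  write_tsv(x$quads, quads_tsv)
  if (!is.null(rejects_json)) {
    jsonlite::write_json(as.list(x$rejects), rejects_json, auto_unbox = TRUE)
  }
  invisible(quads_tsv)
}

#' @rdname write_quads
#' @param quads_tsv path to a quad TSV written by \code{write_quads}.
#' @export
read_quads <- function(quads_tsv) {
  read_tsv(quads_tsv, colClasses = "character")
}
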