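#' Draw random duplex fragments from a methylome
#'
#' Fragment lengths follow a normal distribution truncated to
#' \code{[40, 2 * mean_len]} (sonication + size selection); start positions
#' are uniform within the contig. Contigs shorter than \code{mean_len} are
#' skipped with a warning. Lengths are additionally capped at the contig
#' length.
#'
#' @param methylome a \code{duplex_methylome} (or \code{spikein_panel}).
#' @param n_fragments number of fragments.
#' @param mean_len,sd_len fragment length distribution (bp); \code{mean_len
#'   >= 40}.
#' @param seed integer seed.
#' @return data.frame with columns \code{contig, start, end} (0-based
#'   half-open).
#' @export
fragmentize <- function(methylome, n_fragments, mean_len = 100, sd_len = 10,
                        seed = NULL) {
  stopifnot(mean_len >= 40)
  ref <- as_ref_chars(methylome)
  w <- nchar(ref)
  ok <- w >= mean_len
  if (any(!ok)) {
    warning("skipping contig(s) shorter than mean_len: ",
            paste(names(ref)[!ok], collapse = ", "))
  }
  ref <- ref[ok]
  w <- w[ok]
  empty <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (length(ref) == 0L || n_fragments == 0L) return(empty)
  with_seed(seed, {
    ci <- sample.int(length(ref), n_fragments, replace = TRUE, prob = w)
    len <- round(rnorm(n_fragments, mean_len, sd_len))
    len <- pmin(pmax(len, 40L), 2L * mean_len, w[ci])
    start <- floor(runif(n_fragments, 0, w[ci] - len + 1))
    data.frame(contig = names(ref)[ci], start = as.integer(start),
               end = as.integer(start + len), stringsAsFactors = FALSE)
  })
}

# per-contig site lookup used by the construct builder
prep_sites <- function(methylome) {
  st <- methylome$states
  split(st[c("pos0", "state")], st$contig)
}

#' Build the deaminated four-insert construct for one fragment
#'
#' Forward model of the library chemistry for a single duplex fragment: the
#' original plus/minus strands (inserts a, b) and their copy strands
#' (inserts d, c) in deaminated space, plus the pre-sequencing-error truth
#' call quad at every CpG dyad fully inside the fragment.
#'
#' Per CpG dyad and strand: the original call is 1 when the mark survives
#' protection (mC unless \code{p_overdeam_m}; hmC unless \code{p_overdeam_h};
#' unmodified C only when deamination fails, \code{p_fail_deam}); the copy
#' call is 1 when copy-methylation occurred (mark M and not
#' \code{p_copy_fail}, or spuriously with \code{p_copy_spurious}) and the
#' methylated copy C itself survives protection (not \code{p_overdeam_m};
#' protection acts after copy-methylation, so copy-strand mC shares the
#' original mC's over-deamination risk).
#' Non-CpG cytosines on all four strands deaminate to T unless
#' \code{p_fail_deam} fires. Uses the current RNG stream.
#'
#' @param fragment list or one-row data.frame with \code{contig, start, end}.
#' @param methylome a \code{duplex_methylome}.
#' @param errors a \code{\link{chemistry_errors}} model.
#' @return list with inserts \code{a, b, c, d} (character) and \code{truth}
#'   (data.frame \code{pos0, state, a, d, b, c}).
#' @export
build_construct <- function(fragment, methylome, errors = chemistry_errors()) {
  ref <- as_ref_chars(methylome)
  sites <- prep_sites(methylome)
  build_construct_impl(ref[[fragment$contig]],
                       as.integer(fragment$start), as.integer(fragment$end),
                       sites[[fragment$contig]], errors)
}

build_construct_impl <- function(contig_seq, start, end, csites, errors) {
  L <- end - start
  stopifnot(L >= 2L, start >= 0L, end <= nchar(contig_seq))
  plus <- substr(contig_seq, start + 1L, end)
  minus <- revcomp(plus)

  if (is.null(csites)) {
    pos <- integer(0)
    state <- character(0)
  } else {
    inside <- csites$pos0 >= start & csites$pos0 + 1L <= end - 1L
    pos <- csites$pos0[inside]
    state <- csites$state[inside]
  }
  n <- length(pos)
  mark_p <- substr(state, 1L, 1L)
  mark_m <- substr(state, 2L, 2L)

  draw_orig <- function(mark) {
    p <- ifelse(mark == "M", 1 - errors$p_overdeam_m,
                ifelse(mark == "H", 1 - errors$p_overdeam_h,
                       errors$p_fail_deam))
    rbinom(length(mark), 1L, p)
  }
  draw_copy <- function(mark) {
    # a methylated copy C is itself protected downstream, so it is subject
    # to the same over-deamination risk as an original mC
    p <- (1 - errors$p_overdeam_m) *
      ifelse(mark == "M", 1 - errors$p_copy_fail, errors$p_copy_spurious)
    rbinom(length(mark), 1L, p)
  }
  a_call <- draw_orig(mark_p)
  d_call <- draw_copy(mark_p)
  b_call <- draw_orig(mark_m)
  c_call <- draw_copy(mark_m)

  # 1-based offsets of the dyad C in plus-oriented and minus-oriented inserts
  off_p <- pos - start + 1L        # a, c carry the dyad C here
  off_m <- end - pos - 1L          # b, d carry it here (plus position pos+1)

  deaminate <- function(base_seq, dyad_off, call) {
    y <- set_chars(chartr("C", "T", base_seq), dyad_off[call == 1L], "C")
    if (errors$p_fail_deam > 0) {
      cpos <- setdiff(char_positions(base_seq, "C"), dyad_off)
      esc <- cpos[runif(length(cpos)) < errors$p_fail_deam]
      y <- set_chars(y, esc, "C")
    }
    y
  }
  list(a = deaminate(plus, off_p, a_call),
       b = deaminate(minus, off_m, b_call),
       c = deaminate(plus, off_p, c_call),
       d = deaminate(minus, off_m, d_call),
       truth = data.frame(pos0 = pos, state = state, a = a_call, d = d_call,
                          b = b_call, c = c_call, stringsAsFactors = FALSE))
}

#' Simulate a full sequencing run
#'
#' Draws fragments, runs the chemistry forward model, and assembles paired
#' reads with the fixed layout: Read 1 = insert a, the intact hairpin
#' adapter, insert b, then the trailing cleavage remnant; Read 2 = insert c,
#' the cleavage remnant, insert d, then the trailing intact adapter. Both
#' reads are truncated at \code{read_len}. Adapters appear in deaminated
#' read space.
#'
#' A fraction \code{side_product_rate} of pairs are ligation side products
#' (both adapters of the same type, only the original strands, no copy
#' strands); read pairs are duplicated with probability \code{dup_rate};
#' uniform substitution errors are applied at \code{p_seq_err} per base.
#' Quality strings are constant Phred 37.
#'
#' @param methylome a \code{duplex_methylome} or \code{spikein_panel}.
#' @param n_pairs number of primary read pairs (duplicates are appended on
#'   top of these).
#' @param errors a \code{\link{chemistry_errors}} model.
#' @param adapters a \code{\link{hairpin_adapters}} configuration.
#' @param read_len read length in bp.
#' @param mean_len,sd_len fragment length distribution.
#' @param seed integer seed.
#' @return an object of class \code{sim_reads}: list with \code{r1, r2}
#'   (named character vectors), \code{truth} (per emitted pair: \code{name,
#'   side_product, contig, start, end}) and \code{truth_calls} (per target
#'   pair and covered CpG: \code{name, contig, pos0, state, a, d, b, c},
#'   the pre-sequencing-error calls).
#' @export
simulate_reads <- function(methylome, n_pairs,
                           errors = chemistry_errors(),
                           adapters = hairpin_adapters(),
                           read_len = 250L, mean_len = 100, sd_len = 10,
                           seed = NULL) {
  with_seed(seed, {
    frags <- fragmentize(methylome, n_pairs, mean_len, sd_len, seed = NULL)
    n <- nrow(frags)
    ref <- as_ref_chars(methylome)
    sites <- prep_sites(methylome)
    side <- runif(n) < errors$side_product_rate

    r1 <- character(n)
    r2 <- character(n)
    calls <- vector("list", n)
    for (i in seq_len(n)) {
      ct <- frags$contig[i]
      cons <- build_construct_impl(ref[[ct]], frags$start[i], frags$end[i],
                                   sites[[ct]], errors)
      if (side[i]) {
        ad <- if (runif(1) < 0.5) adapters$intact_rs else adapters$cleavable_rs
        s1 <- paste0(cons$a, ad, cons$b)
        r1[i] <- substr(s1, 1L, read_len)
        r2[i] <- substr(revcomp(s1), 1L, read_len)
      } else {
        r1[i] <- substr(paste0(cons$a, adapters$intact_rs, cons$b,
                               adapters$remnant_rs), 1L, read_len)
        r2[i] <- substr(paste0(cons$c, adapters$remnant_rs, cons$d,
                               adapters$intact_rs), 1L, read_len)
        if (nrow(cons$truth) > 0L) calls[[i]] <- cons$truth
      }
    }
    names(r1) <- names(r2) <- sprintf("frag%07d", seq_len(n))

    truth <- data.frame(name = names(r1), side_product = side,
                        contig = frags$contig, start = frags$start,
                        end = frags$end, stringsAsFactors = FALSE)
    has_calls <- !vapply(calls, is.null, logical(1))
    truth_calls <- if (any(has_calls)) {
      tc <- do.call(rbind, calls[has_calls])
      reps <- vapply(calls[has_calls], nrow, integer(1))
      data.frame(name = rep(names(r1)[has_calls], reps),
                 contig = rep(frags$contig[has_calls], reps),
                 tc, stringsAsFactors = FALSE)
    } else {
      data.frame(name = character(0), contig = character(0),
                 pos0 = integer(0), state = character(0), a = integer(0),
                 d = integer(0), b = integer(0), c = integer(0))
    }

    # PCR/cluster duplicates: same molecule re-observed under a new name
    if (errors$dup_rate > 0) {
      dup <- which(runif(n) < errors$dup_rate)
      if (length(dup) > 0L) {
        dn <- paste0(names(r1)[dup], "_dup")
        r1 <- c(r1, setNames(r1[dup], dn))
        r2 <- c(r2, setNames(r2[dup], dn))
        td <- truth[dup, , drop = FALSE]
        td$name <- dn
        truth <- rbind(truth, td)
        cd <- truth_calls[truth_calls$name %in% names(r1)[dup], , drop = FALSE]
        if (nrow(cd) > 0L) {
          cd$name <- paste0(cd$name, "_dup")
          truth_calls <- rbind(truth_calls, cd)
        }
      }
    }

    if (errors$p_seq_err > 0) {
      r1 <- add_seq_errors(r1, errors$p_seq_err)
      r2 <- add_seq_errors(r2, errors$p_seq_err)
    }
    rownames(truth) <- rownames(truth_calls) <- NULL
    structure(list(r1 = r1, r2 = r2, truth = truth,
                   truth_calls = truth_calls),
              class = "sim_reads")
  })
}

# which dyads of a fragment are covered by all four inserts under the fixed
# read layout: a and c are read first and cover the whole fragment (up to
# read_len); b and d sit after an adapter and may be 3'-truncated, losing
# coverage of the fragment-start side
covered_by_quad <- function(pos0, start, end, read_len, adapters) {
  len <- end - start
  lb <- pmax(0L, pmin(len, read_len - len - nchar(adapters$intact_rs)))
  ld <- pmax(0L, pmin(len, read_len - len - nchar(adapters$remnant_rs)))
  la <- pmin(len, read_len)
  inside <- pos0 >= start & pos0 + 1L <= end - 1L
  inside & (pos0 - start + 1L) <= la & (end - pos0 - 1L) <= pmin(lb, ld)
}

# uniform substitutions at rate p; errors replace the base with one of the
# three other bases uniformly (current RNG stream)
add_seq_errors <- function(seqs, p) {
  nerr <- rbinom(length(seqs), nchar(seqs), p)
  for (i in which(nerr > 0L)) {
    r <- charToRaw(seqs[[i]])
    pos <- sample.int(length(r), nerr[i])
    for (j in pos) {
      alt <- setdiff(charToRaw("ACGT"), r[j])
      r[j] <- alt[[sample.int(length(alt), 1L)]]
    }
    seqs[[i]] <- rawToChar(r)
  }
  seqs
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf(
    "sim_reads: %d read pairs (%d side products, %.1f%%), %d truth calls\n",
    length(x$r1), sum(x$truth$side_product),
    100 * mean(x$truth$side_product), nrow(x$truth_calls)))
  invisible(x)
}

#' Write simulated reads to paired FASTQ plus truth TSVs
#'
#' @param sim a \code{sim_reads} object.
#' @param prefix output path prefix; writes \code{<prefix>_R1.fastq.gz},
#'   \code{<prefix>_R2.fastq.gz}, \code{<prefix>_truth.tsv} and
#'   \code{<prefix>_truth_calls.tsv}.
#' @return invisibly, the four paths.
#' @export
write_sim_reads <- function(sim, prefix) {
  p <- c(r1 = paste0(prefix, "_R1.fastq.gz"),
         r2 = paste0(prefix, "_R2.fastq.gz"),
         truth = paste0(prefix, "_truth.tsv"),
         truth_calls = paste0(prefix, "_truth_calls.tsv"))
  write_fastq(sim$r1, p[["r1"]])
  write_fastq(sim$r2, p[["r2"]])
  write_tsv(sim$truth, p[["truth"]])
  write_tsv(sim$truth_calls, p[["truth_calls"]])
  invisible(p)
}

# constant Phred 37 qualities; the pipeline never consumes qualities
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(strrep("F", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", sub("/[12]$", "", names(x)))
  out
}
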