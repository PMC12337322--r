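#' Generate a random reference with a controlled CpG dyad density
#'
#' Draws i.i.d. background sequence, removes accidental CpG dyads, then
#' plants non-overlapping CpG dyads at randomly chosen positions so that the
#' realized dyad density matches \code{cpg_density}. All dyads in the output
#' are planted, which gives the downstream methylome generator full control
#' over every site.
#'
#' @param n_contigs number of contigs.
#' @param length length of each contig in bp (>= 200).
#' @param cpg_density target CpG dyads per bp, in (0, 0.25).
#' @param seed integer seed; the output is deterministic given the seed.
#' @return a \link[Biostrings]{DNAStringSet} with contigs named
#'   \code{contig1, contig2, ...}
#' @export
generate_reference <- function(n_contigs = 1L, length = 10000L,
                               cpg_density = 0.02, seed = NULL) {
  if (length < 200L) stop("contig length must be >= 200 bp")
  if (cpg_density <= 0 || cpg_density >= 0.25) {
    stop("cpg_density must be in (0, 0.25)")
  }
  with_seed(seed, {
    seqs <- vapply(seq_len(n_contigs), function(i) {
      random_cpg_sequence(length, cpg_density)
    }, character(1))
    names(seqs) <- paste0("contig", seq_len(n_contigs))
    Biostrings::DNAStringSet(seqs)
  })
}

# one contig: CG-free background + planted dyads at even offsets (uses the
# current RNG stream)
random_cpg_sequence <- function(length, cpg_density) {
  s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  # break accidental CG dyads; replacing G with A/T can never create a new CG
  cg <- which(s[-length] == "C" & s[-1L] == "G")
  if (length(cg) > 0L) {
    s[cg + 1L] <- sample(c("A", "T"), length(cg), replace = TRUE)
  }
  n_cpg <- round(length * cpg_density)
  candidates <- seq(1L, length - 1L, by = 2L)  # non-overlapping by spacing
  pos <- sort(sample(candidates, min(n_cpg, length(candidates))))
  s[pos] <- "C"
  s[pos + 1L] <- "G"
  paste(s, collapse = "")
}

#' Locate all CpG dyads in a reference
#'
#' @param reference a \link[Biostrings]{DNAStringSet} or named character
#'   vector of contigs.
#' @return data.frame with columns \code{contig}, \code{pos0} (0-based
#'   position of the plus-strand C).
#' @export
cpg_sites <- function(reference) {
  ref <- as_ref_chars(reference)
  out <- lapply(names(ref), function(ct) {
    m <- gregexpr("CG", ref[[ct]], fixed = TRUE)[[1L]]
    p <- as.integer(m)
    if (length(p) == 1L && p[1L] == -1L) p <- integer(0)
    data.frame(contig = rep(ct, length(p)), pos0 = p - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# normalize reference input to a named character vector
as_ref_chars <- function(reference) {
  if (is(reference, "DNAStringSet")) {
    setNames(as.character(reference), names(reference))
  } else if (is.character(reference)) {
    if (is.null(names(reference))) stop("reference contigs must be named")
    reference
  } else if (inherits(reference, "duplex_methylome")) {
    as_ref_chars(reference$reference)
  } else {
    stop("reference must be a DNAStringSet or a named character vector")
  }
}

#' Assign a duplex state to every CpG site of a reference
#'
#' States are drawn i.i.d. from \code{fractions}; the empirical composition
#' converges to the requested one as the number of sites grows. The result
#' is the simulator's ground truth.
#'
#' @param reference \link[Biostrings]{DNAStringSet} or named character vector.
#' @param fractions a proper distribution over the nine states (see
#'   \code{\link{state_fractions}}).
#' @param seed integer seed.
#' @return an object of class \code{duplex_methylome}: list with
#'   \code{reference} (DNAStringSet) and \code{states} (data.frame
#'   \code{contig, pos0, state}).
#' @export
assign_states <- function(reference, fractions, seed = NULL) {
  fractions <- state_fractions(fractions)
  sites <- cpg_sites(reference)
  sites$state <- with_seed(seed, {
    if (nrow(sites) == 0L) character(0)
    else sample(CPG_STATES, nrow(sites), replace = TRUE, prob = fractions)
  })
  duplex_methylome(reference, sites)
}

#' Build a duplex methylome from a reference and a per-site state table
#'
#' @param reference \link[Biostrings]{DNAStringSet} or named character vector.
#' @param states data.frame with columns \code{contig, pos0, state}; must
#'   cover every CpG dyad of the reference exactly once, each keyed by the
#'   0-based plus-strand C position.
#' @return a \code{duplex_methylome} object.
#' @export
duplex_methylome <- function(reference, states) {
  ref <- as_ref_chars(reference)
  stopifnot(all(c("contig", "pos0", "state") %in% names(states)))
  if (nrow(states) > 0 && !all(states$state %in% CPG_STATES)) {
    stop("unknown state name in methylome table")
  }
  expected <- cpg_sites(ref)
  key <- function(d) paste(d$contig, d$pos0)
  if (!identical(sort(key(expected)), sort(key(states)))) {
    stop("state table must cover every CpG dyad of the reference exactly once")
  }
  states <- states[order(states$contig, states$pos0), , drop = FALSE]
  rownames(states) <- NULL
  structure(list(reference = Biostrings::DNAStringSet(ref), states = states),
            class = "duplex_methylome")
}

#' @export
print.duplex_methylome <- function(x, ...) {
  cat(sprintf("duplex_methylome: %d contig(s), %d bp, %d CpG site(s)\n",
              length(x$reference), sum(Biostrings::width(x$reference)),
              nrow(x$states)))
  if (nrow(x$states) > 0) {
    tab <- table(factor(x$states$state, levels = CPG_STATES))
    cat("state counts:\n")
    print(tab)
  }
  invisible(x)
}

#' Write / read a duplex methylome (FASTA + TSV sidecar)
#'
#' The sidecar is a tab-separated table \code{contig, pos0, state} with
#' 0-based positions (BED-compatible convention). The pair round-trips
#' losslessly.
#'
#' @param methylome a \code{duplex_methylome}.
#' @param fasta,tsv file paths.
#' @return \code{write_methylome}: invisibly, the paths;
#'   \code{read_methylome}: the \code{duplex_methylome}.
#' @export
write_methylome <- function(methylome, fasta, tsv) {
  Biostrings::writeXStringSet(methylome$reference, fasta)
  write_tsv(methylome$states, tsv)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' @rdname write_methylome
#' @export
read_methylome <- function(fasta, tsv) {
  ref <- Biostrings::readDNAStringSet(fasta)
  names(ref) <- sub("\\s.*$", "", names(ref))
  states <- read_tsv(tsv, colClasses = c("character", "integer", "character"))
  duplex_methylome(ref, states)
}
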