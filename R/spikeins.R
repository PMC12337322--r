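#' Build a synthetic spike-in control panel covering all nine states
#'
#' One control duplex per duplex CpG state (nine in total), each carrying
#' several CpG dyads all set to that state. The panel plays the role of the
#' synthetic oligonucleotide controls of known state that are spiked into a
#' library to estimate the call-rate (confusion) matrix. Sequences are
#' generated free of the hairpin-adapter read-space sequences so insert
#' parsing can never be confounded.
#'
#' @param seed integer seed.
#' @param n_cpg CpG dyads per control duplex.
#' @param length duplex length in bp.
#' @param adapters \code{\link{hairpin_adapters}} whose sequences must not
#'   occur inside the controls.
#' @return an object of class \code{spikein_panel}; also a valid
#'   \code{duplex_methylome} (contigs named \code{spike_<STATE>}), so it can
#'   be passed directly to the simulator and aligner.
#' @export
build_spikein_panel <- function(seed = NULL, n_cpg = 4L, length = 150L,
                                adapters = hairpin_adapters()) {
  stopifnot(n_cpg >= 1L, length >= 60L)
  with_seed(seed, {
    seqs <- character(0)
    states <- list()
    # dyads evenly spread through the middle so typical fragments cover them
    anchor <- as.integer(round(seq(length * 0.2, length * 0.8,
                                   length.out = n_cpg)))
    forbidden <- c(adapters$intact_rs, adapters$remnant_rs,
                   adapters$cleavable_rs)
    for (s in CPG_STATES) {
      repeat {
        x <- random_cpg_sequence_at(length, anchor)
        hits <- vapply(forbidden, function(f) {
          grepl(f, collapse3(x), fixed = TRUE)
        }, logical(1))
        if (!any(hits)) break
      }
      nm <- paste0("spike_", s)
      seqs[[nm]] <- x
      states[[nm]] <- data.frame(contig = nm, pos0 = anchor - 1L, state = s,
                                 stringsAsFactors = FALSE)
    }
    mm <- duplex_methylome(Biostrings::DNAStringSet(seqs),
                           do.call(rbind, states))
    class(mm) <- c("spikein_panel", class(mm))
    mm
  })
}

# CG-free background with dyads planted exactly at `anchor` (1-based C pos)
random_cpg_sequence_at <- function(length, anchor) {
  s <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  cg <- which(s[-length] == "C" & s[-1L] == "G")
  if (length(cg) > 0L) s[cg + 1L] <- sample(c("A", "T"), length(cg), TRUE)
  # planting C,G at the anchor cannot create a dyad elsewhere: a new dyad
  # would need a G gained at anchor (it gains C) or a C gained at anchor+1
  s[anchor] <- "C"
  s[anchor + 1L] <- "G"
  paste(s, collapse = "")
}

#' Write / read a spike-in panel (FASTA + known-state sidecar TSV)
#'
#' @param panel a \code{spikein_panel}.
#' @param fasta,tsv file paths.
#' @return \code{read_spikein_panel}: the panel, reconstructed losslessly.
#' @export
write_spikein_panel <- function(panel, fasta, tsv) {
  write_methylome(panel, fasta, tsv)
}

#' @rdname write_spikein_panel
#' @export
read_spikein_panel <- function(fasta, tsv) {
  mm <- read_methylome(fasta, tsv)
  class(mm) <- c("spikein_panel", class(mm))
  mm
}
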