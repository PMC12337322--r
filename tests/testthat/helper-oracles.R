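# Independent oracles used across the suite. These re-derive expected
# behavior from first principles (chemistry rules, exhaustive scans) without
# touching the implementation paths they check.

# --- chemistry oracle -------------------------------------------------------
# Error-free chemistry for one strand, written directly from the protocol:
# the original cytosine survives deamination iff it carries a mark (mC is
# protected by oxidation/glucosylation, hmC by glucosylation); the copy
# strand is methylated iff the original carries mC (maintenance
# methyltransferase), since glucosylated hmC blocks copying and unmodified C
# gives the enzyme nothing to maintain.
chem_strand_calls <- function(mark) {
  c(original = as.integer(mark == "M" || mark == "H"),
    copy = as.integer(mark == "M"))
}

# quad (a, d, b, c) induced by a duplex state under error-free chemistry
chem_quad <- function(state) {
  p <- chem_strand_calls(substr(state, 1, 1))
  m <- chem_strand_calls(substr(state, 2, 2))
  c(a = p[["original"]], d = p[["copy"]],
    b = m[["original"]], c = m[["copy"]])
}

# --- brute-force converted-space aligner ------------------------------------
# Exhaustive scan over every contig and offset; per-position rule spelled
# out explicitly (read T matches reference C or T, read C only reference C,
# A/G exact). Returns NA coordinates on no acceptable or tied best match.
brute_char_mismatch <- function(read, ref) {
  rs <- strsplit(read, NULL)[[1]]
  fs <- strsplit(ref, NULL)[[1]]
  if (length(rs) != length(fs)) return(NA_integer_)
  ok <- mapply(function(r, f) {
    (r == f) || (r == "T" && f == "C")
  }, rs, fs)
  sum(!ok)
}

brute_align <- function(quad, ref, max_mismatch_rate = 0.1) {
  ref <- duplexCpG:::as_ref_chars(ref)
  a <- quad$a; b <- quad$b; cc <- quad$c; d <- quad$d
  la <- nchar(a); lb <- nchar(b); lc <- nchar(cc); ld <- nchar(d)
  budget <- floor(max_mismatch_rate * (la + lb + lc + ld))
  hits <- list()
  for (ct in names(ref)) {
    L <- nchar(ref[[ct]])
    rc <- duplexCpG:::revcomp(ref[[ct]])
    if (L < la) next
    for (s0 in 0:(L - la)) {
      e0 <- s0 + la
      sc <- brute_char_mismatch(a, substr(ref[[ct]], s0 + 1, e0)) +
        brute_char_mismatch(b, substr(rc, L - e0 + 1, L - e0 + lb)) +
        brute_char_mismatch(cc, substr(ref[[ct]], s0 + 1, s0 + lc)) +
        brute_char_mismatch(d, substr(rc, L - e0 + 1, L - e0 + ld))
      if (!is.na(sc) && sc <= budget) {
        hits[[length(hits) + 1]] <- list(contig = ct, start = s0, end = e0,
                                         score = sc)
      }
    }
  }
  if (length(hits) == 0) {
    return(list(contig = NA_character_, start = NA_integer_,
                end = NA_integer_, aligned = FALSE))
  }
  scores <- vapply(hits, `[[`, numeric(1), "score")
  best <- which(scores == min(scores))
  if (length(best) > 1) {
    return(list(contig = NA_character_, start = NA_integer_,
                end = NA_integer_, aligned = FALSE))
  }
  c(hits[[best]], aligned = TRUE)
}

# --- shared small fixtures --------------------------------------------------
# built once per test run; deliberately small so the whole suite stays fast
tiny_genome <- function() {
  generate_reference(n_contigs = 1L, length = 8000L, cpg_density = 0.02,
                     seed = 101L)
}

tiny_methylome <- function() {
  assign_states(tiny_genome(), default_genome_fractions(), seed = 102L)
}
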