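#' Chemistry and sequencing error model
#'
#' Collects the per-step failure probabilities of the library chemistry and
#' sequencing. All probabilities are per event and independent.
#'
#' @param p_fail_deam probability an unmodified C escapes deamination (read
#'   as C instead of T); applies to non-CpG cytosines on all four strands.
#' @param p_overdeam_m,p_overdeam_h probability a protected mC / hmC on an
#'   original strand is deaminated anyway (read as T).
#' @param p_copy_fail probability maintenance copy-methylation fails
#'   opposite an mC (copy call 0 instead of 1).
#' @param p_copy_spurious probability a copy-strand CpG cytosine is
#'   methylated despite the original strand carrying C or hmC.
#' @param p_seq_err per-base substitution rate applied to the final reads.
#' @param dup_rate probability a read pair is emitted a second time
#'   (PCR/cluster duplication). Default 0.122, the duplication rate typical
#'   of the assay.
#' @param side_product_rate fraction of emitted read pairs that are
#'   non-target ligation side products (two adapters of the same type,
#'   carrying only single-stranded information). Default 0.165: side
#'   products average 16.5\% of raw reads.
#' @return an object of class \code{chemistry_errors}.
#' @seealso \code{\link{zero_errors}} for the error-free limit.
#' @export
chemistry_errors <- function(p_fail_deam = 0.002,
                             p_overdeam_m = 0.005,
                             p_overdeam_h = 0.01,
                             p_copy_fail = 0.01,
                             p_copy_spurious = 0.002,
                             p_seq_err = 0.001,
                             dup_rate = 0.122,
                             side_product_rate = 0.165) {
  e <- list(p_fail_deam = p_fail_deam, p_overdeam_m = p_overdeam_m,
            p_overdeam_h = p_overdeam_h, p_copy_fail = p_copy_fail,
            p_copy_spurious = p_copy_spurious, p_seq_err = p_seq_err,
            dup_rate = dup_rate, side_product_rate = side_product_rate)
  bad <- vapply(e, function(p) !is.numeric(p) || length(p) != 1L ||
                  is.na(p) || p < 0 || p > 1, logical(1))
  if (any(bad)) {
    stop("error probabilities must be single values in [0, 1]: ",
         paste(names(e)[bad], collapse = ", "))
  }
  structure(e, class = "chemistry_errors")
}

#' Error-free chemistry
#'
#' All chemistry, duplication, side-product and sequencing error
#' probabilities set to zero; under this model the pipeline must recover the
#' true state at every called site.
#' @return a \code{chemistry_errors} object.
#' @export
zero_errors <- function() {
  chemistry_errors(0, 0, 0, 0, 0, 0, 0, 0)
}

#' @export
print.chemistry_errors <- function(x, ...) {
  cat("chemistry_errors:\n")
  for (n in names(x)) cat(sprintf("  %-18s %g\n", n, x[[n]]))
  invisible(x)
}

# analytic per-strand call-pair distribution for a given true mark: rows are
# the call pairs (original, copy) in order 11, 10, 00, 01. Used by tests and
# by the confusion-consistency checks; mirrors build_construct exactly.
strand_call_probs <- function(mark, errors) {
  p_orig1 <- switch(mark,
                    M = 1 - errors$p_overdeam_m,
                    H = 1 - errors$p_overdeam_h,
                    C = errors$p_fail_deam)
  # copy-strand mC is protected like original mC and can over-deaminate
  p_copy1 <- (1 - errors$p_overdeam_m) *
    (if (mark == "M") 1 - errors$p_copy_fail else errors$p_copy_spurious)
  c(`11` = p_orig1 * p_copy1,
    `10` = p_orig1 * (1 - p_copy1),
    `00` = (1 - p_orig1) * (1 - p_copy1),
    `01` = (1 - p_orig1) * p_copy1)
}

# analytic quad distribution for a duplex state; names are "adbc" strings
state_quad_probs <- function(state, errors) {
  pp <- strand_call_probs(substr(state, 1, 1), errors)
  pm <- strand_call_probs(substr(state, 2, 2), errors)
  out <- outer(pp, pm)
  nm <- outer(names(pp), names(pm), paste0)
  setNames(as.vector(out), as.vector(nm))
}

# analytic 9x9 confusion matrix (+ implausible row) implied by an error
# model; columns = true states, rows = called states
analytic_confusion <- function(errors) {
  P <- matrix(0, 10, 9, dimnames = list(c(CPG_STATES, "implausible"),
                                        CPG_STATES))
  quads <- all_call_quads()
  qname <- paste0(quads$a, quads$d, quads$b, quads$c)
  called <- ifelse(is.na(quads$state), "implausible", quads$state)
  for (s in CPG_STATES) {
    pq <- state_quad_probs(s, errors)
    P[, s] <- vapply(rownames(P), function(cs) {
      sum(pq[qname[called == cs]])
    }, numeric(1))
  }
  P
}

#' Hairpin adapter configuration
#'
#' The library uses a 1:1 mix of two hairpin adapters: a cleavable one
#' (contains dU; excised to form the self-priming construct, leaving a short
#' remnant) and an intact (non-cleavable) one that survives in the middle of
#' Read 1. Target read pairs carry the intact adapter in Read 1 and the
#' cleavage remnant in Read 2; side products do not, which is how they are
#' filtered out.
#'
#' Adapters are matched in deaminated read space (any C deaminates to T), so
#' both are stored alongside their converted forms. The remnant is modeled
#' as a fixed-length suffix of the cleavable adapter; 20 nt keeps chance
#' matches in the three-letter read alphabet negligible.
#'
#' @param intact,cleavable adapter sequences, 20-30 nt.
#' @param remnant_len length of the cleavage remnant (suffix of
#'   \code{cleavable}).
#' @return an object of class \code{hairpin_adapters} with elements
#'   \code{intact}, \code{cleavable}, \code{remnant} and their read-space
#'   (C-to-T converted) forms \code{intact_rs}, \code{remnant_rs},
#'   \code{cleavable_rs}.
#' @export
hairpin_adapters <- function(intact = "AGTTAGGTTGAAGGATGTTAGGATTG",
                             cleavable = "TGAAGTGGAATGTTGGAGAGTTGGTA",
                             remnant_len = 20L) {
  for (s in c(intact, cleavable)) {
    if (!grepl("^[ACGT]+$", s)) stop("adapters must be ACGT sequences")
    if (nchar(s) < 20L || nchar(s) > 30L) {
      stop("adapter length must be 20-30 nt")
    }
  }
  if (remnant_len < 8L || remnant_len > nchar(cleavable)) {
    stop("remnant_len must be in [8, nchar(cleavable)]")
  }
  remnant <- substr(cleavable, nchar(cleavable) - remnant_len + 1L,
                    nchar(cleavable))
  ad <- structure(list(intact = intact, cleavable = cleavable,
                       remnant = remnant,
                       intact_rs = collapse3(intact),
                       cleavable_rs = collapse3(cleavable),
                       remnant_rs = collapse3(remnant)),
                  class = "hairpin_adapters")
  validate_adapters(ad)
  ad
}

# ambiguity guard: the intact adapter and the remnant must not share a long
# substring in read space, or insert boundaries cannot be parsed
validate_adapters <- function(ad, min_shared = 12L) {
  if (shared_substring(ad$intact_rs, ad$cleavable_rs) >= min_shared ||
      shared_substring(ad$intact_rs, ad$remnant_rs) >= min_shared) {
    stop("adapter sequences share a substring of length >= ", min_shared,
         " in read space; parsing would be ambiguous")
  }
  invisible(ad)
}

# length of the longest common substring of two strings (small inputs only)
shared_substring <- function(x, y) {
  nx <- nchar(x)
  for (L in seq(min(nx, nchar(y)), 1L)) {
    subs <- unique(substring(x, seq_len(nx - L + 1L), seq_len(nx - L + 1L) + L - 1L))
    if (any(vapply(subs, function(s) grepl(s, y, fixed = TRUE), logical(1)))) {
      return(L)
    }
  }
  0L
}

#' @export
print.hairpin_adapters <- function(x, ...) {
  cat("hairpin_adapters:\n")
  cat("  intact    ", x$intact, "\n")
  cat("  cleavable ", x$cleavable, "\n")
  cat("  remnant   ", x$remnant, "\n")
  invisible(x)
}
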