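#' @title Duplex CpG states and the four-call decode table
#'
#' @description
#' A CpG dyad carries a cytosine on each strand, and each cytosine is in one
#' of three statuses: unmodified (\code{C}), 5-methylcytosine (\code{M}) or
#' 5-hydroxymethylcytosine (\code{H}). The ordered pair (plus strand first)
#' gives nine duplex states, named by two letters: \code{MM, CC, MC, CM, HC,
#' CH, HM, MH, HH}. \code{HC} has hmC on the plus strand, \code{CH} on the
#' minus strand.
#'
#' Sequencing reads out each strand twice: the original strand and its
#' enzymatically synthesized copy strand. After maintenance copy-methylation
#' (only opposite mC; glucosylated hmC blocks it) and deamination of
#' unmodified C, each of the four cytosines yields a binary methylation call
#' (1 = C retained, 0 = read as T). The calls are ordered \code{(a, d, b, c)}:
#' original plus, copy of plus, original minus, copy of minus; \code{a} pairs
#' with \code{d} and \code{b} with \code{c}.
#'
#' @name cpg-states
NULL

#' The nine duplex CpG state names, in canonical order
#'
#' First letter is the plus-strand mark, second the minus-strand mark.
#' @export
CPG_STATES <- c("MM", "CC", "MC", "CM", "HC", "CH", "HM", "MH", "HH")

#' The three per-strand cytosine marks
#'
#' \code{C} unmodified, \code{M} 5-methylcytosine, \code{H}
#' 5-hydroxymethylcytosine.
#' @export
STRAND_MARKS <- c("C", "M", "H")

#' Decode one strand's mark from its (original, copy) call pair
#'
#' The chemistry admits three call pairs per strand: mC is protected on the
#' original and copy-methylated, giving (1,1); hmC is protected but
#' glucosylation blocks copying, giving (1,0); unmodified C is deaminated on
#' both, giving (0,0). A methylated copy over an unmodified original, (0,1),
#' cannot arise and decodes to \code{NA} (implausible).
#'
#' @param original_call,copy_call integer vectors of 0/1 calls.
#' @return character vector of \code{"C"}, \code{"M"}, \code{"H"} or
#'   \code{NA} for implausible pairs.
#' @examples
#' decode_strand(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
decode_strand <- function(original_call, copy_call) {
  stopifnot(length(original_call) == length(copy_call))
  o <- as.integer(original_call)
  k <- as.integer(copy_call)
  if (any(!(o %in% 0:1) | !(k %in% 0:1))) {
    stop("calls must be binary (0/1)")
  }
  out <- rep(NA_character_, length(o))
  out[o == 1L & k == 1L] <- "M"
  out[o == 1L & k == 0L] <- "H"
  out[o == 0L & k == 0L] <- "C"
  out
}

#' Decode a four-call quad into a duplex CpG state
#'
#' Calls are ordered (a, d, b, c): a/d are the plus strand's original/copy
#' calls, b/c the minus strand's. Of the 16 possible quads exactly 9 decode
#' to a state; the other 7 are implausible (they require a methylated copy
#' over an unmodified original on at least one strand) and return \code{NA}.
#'
#' @param a,d,b,c integer vectors of 0/1 calls (recycled to common length
#'   not supported; all must have equal length).
#' @return character vector of state names or \code{NA} (implausible).
#' @examples
#' decode_state(1, 1, 1, 1)  # "MM"
#' decode_state(1, 0, 0, 0)  # "HC"
#' decode_state(0, 1, 0, 0)  # NA: implausible
#' @export
decode_state <- function(a, d, b, c) {
  plus <- decode_strand(a, d)
  minus <- decode_strand(b, c)
  ifelse(is.na(plus) | is.na(minus), NA_character_, paste0(plus, minus))
}

# per-strand inverse: mark -> c(original, copy)
encode_strand <- function(mark) {
  stopifnot(all(mark %in% STRAND_MARKS))
  cbind(original = as.integer(mark %in% c("M", "H")),
        copy = as.integer(mark == "M"))
}

#' Encode a duplex CpG state as its four-call quad
#'
#' Inverse of \code{\link{decode_state}} under error-free chemistry; used by
#' the read simulator to derive truth calls.
#'
#' @param state character vector of state names (see \code{\link{CPG_STATES}}).
#' @return integer matrix with columns \code{a, d, b, c}, one row per state.
#' @examples
#' encode_calls("MM")  # 1 1 1 1
#' encode_calls("HH")  # 1 0 1 0
#' @export
encode_calls <- function(state) {
  stopifnot(all(state %in% CPG_STATES))
  plus <- encode_strand(substr(state, 1L, 1L))
  minus <- encode_strand(substr(state, 2L, 2L))
  m <- cbind(a = plus[, "original"], d = plus[, "copy"],
             b = minus[, "original"], c = minus[, "copy"])
  rownames(m) <- state
  m
}

#' Enumerate all 16 call quads and their decoded states
#'
#' @return data.frame with columns \code{a, d, b, c, state}; \code{state} is
#'   \code{NA} for the 7 implausible quads.
#' @export
all_call_quads <- function() {
  g <- expand.grid(c = 0:1, b = 0:1, d = 0:1, a = 0:1)[, 4:1]
  g$state <- decode_state(g$a, g$d, g$b, g$c)
  rownames(g) <- NULL
  g
}

#' Construct a vector of duplex state fractions
#'
#' A named numeric vector over the nine states, used both for the observed
#' genome-wide composition (O) and the true composition (T) of the linear
#' correction model, and as the generator's target composition.
#'
#' @param x numeric vector; either named by state or length 9 in canonical
#'   order.
#' @param normalized require entries to sum to 1 (tolerance 1e-9).
#' @return named numeric vector in canonical state order.
#' @export
state_fractions <- function(x, normalized = TRUE) {
  if (is.null(names(x))) {
    if (length(x) != 9L) stop("unnamed state fractions must have length 9")
    names(x) <- CPG_STATES
  }
  if (!setequal(names(x), CPG_STATES)) {
    stop("state fractions must be named by the nine states: ",
         paste(CPG_STATES, collapse = " "))
  }
  x <- x[CPG_STATES]
  if (any(x < 0)) stop("state fractions must be non-negative")
  if (normalized && abs(sum(x) - 1) > 1e-9) {
    stop("state fractions must sum to 1 (got ", format(sum(x)), ")")
  }
  x
}

#' Mirror a state across strands
#'
#' Swaps the plus- and minus-strand marks: \code{HC <-> CH}, \code{MC <->
#' CM}, \code{HM <-> MH}; symmetric states map to themselves.
#'
#' @param state character vector of state names.
#' @return character vector of mirrored state names.
#' @export
mirror_state <- function(state) {
  stopifnot(all(state %in% CPG_STATES))
  paste0(substr(state, 2L, 2L), substr(state, 1L, 1L))
}
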