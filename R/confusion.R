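#' Build the call-rate (confusion) matrix from spike-in calls
#'
#' Joins per-site decoded state counts on the spike-in controls with their
#' known true states and tallies, for every true state j, the rate at which
#' it was called as each state i. Entry (i, j) = count(called i | true j) /
#' count(valid calls | true j), so columns are stochastic over the nine
#' called states. Implausible quads are excluded from the matrix and
#' reported as a separate per-true-state rate.
#'
#' @param site_counts a \code{site_state_counts} table restricted to the
#'   spike-in contigs (see \code{\link{compile_sites}}).
#' @param truth data.frame \code{contig, pos0, state} with the known state
#'   of every spike-in CpG (the panel's \code{$states} table).
#' @return an object of class \code{confusion_matrix}: list with \code{P}
#'   (9 x 9, rows = called, columns = true), \code{implausible_rate} and
#'   \code{n_calls} (valid calls per true state).
#' @export
build_confusion <- function(site_counts, truth) {
  stopifnot(all(c("contig", "pos0", "state") %in% names(truth)))
  key_s <- paste(site_counts$contig, site_counts$pos0)
  key_t <- paste(truth$contig, truth$pos0)
  idx <- match(key_s, key_t)
  if (anyNA(idx)) {
    stop("site count table contains sites absent from the spike-in truth")
  }
  true_state <- truth$state[idx]
  P <- matrix(0, 9, 9, dimnames = list(called = CPG_STATES,
                                       true = CPG_STATES))
  impl <- setNames(numeric(9), CPG_STATES)
  ncalls <- setNames(numeric(9), CPG_STATES)
  cnt <- as.matrix(site_counts[, CPG_STATES, drop = FALSE])
  for (j in CPG_STATES) {
    rows <- true_state == j
    called <- colSums(cnt[rows, , drop = FALSE])
    valid <- sum(called)
    if (valid == 0) {
      stop("no valid calls for true state ", j,
           "; increase spike-in depth")
    }
    P[, j] <- called / valid
    n_impl <- sum(site_counts$implausible[rows])
    impl[j] <- n_impl / (valid + n_impl)
    ncalls[j] <- valid
  }
  structure(list(P = P, implausible_rate = impl, n_calls = ncalls),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 3, ...) {
  cat("confusion_matrix (rows = called state, columns = true state):\n")
  print(round(x$P, digits))
  cat(sprintf("min diagonal: %.4f; implausible rate: %.4g-%.4g\n",
              min(diag(x$P)), min(x$implausible_rate),
              max(x$implausible_rate)))
  invisible(x)
}

#' Write / read a confusion matrix (TSV: 9 x 9 plus implausible column)
#'
#' @param cm a \code{confusion_matrix}.
#' @param path TSV path.
#' @export
write_confusion <- function(cm, path) {
  df <- data.frame(true_state = colnames(cm$P), t(cm$P),
                   implausible = cm$implausible_rate,
                   n_calls = cm$n_calls, row.names = NULL)
  write_tsv(df, path)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path) {
  df <- read_tsv(path)
  P <- t(as.matrix(df[, CPG_STATES]))
  colnames(P) <- df$true_state
  P <- P[CPG_STATES, CPG_STATES]
  dimnames(P) <- list(called = CPG_STATES, true = CPG_STATES)
  structure(list(P = P,
                 implausible_rate = setNames(df$implausible, df$true_state)[CPG_STATES],
                 n_calls = setNames(df$n_calls, df$true_state)[CPG_STATES]),
            class = "confusion_matrix")
}

#' Observed genome-wide state fractions from a site table
#'
#' Sums valid state calls over all sites and normalizes; implausible calls
#' are excluded.
#'
#' @param site_counts a \code{site_state_counts} table.
#' @return a named state-fraction vector (sums to 1).
#' @export
observed_fractions <- function(site_counts) {
  tot <- colSums(as.matrix(site_counts[, CPG_STATES, drop = FALSE]))
  if (sum(tot) == 0) stop("no valid calls in site table")
  state_fractions(tot / sum(tot))
}

#' Correct observed state fractions with the spike-in confusion matrix
#'
#' Models the observed composition as O = P T (each observed state is the
#' additive contribution of all true states through their call rates) and
#' solves the 9-equation linear system for the true composition T with a
#' direct solve; any negative entries of the solution are then set to zero.
#' The clamped vector is deliberately not renormalized; its sum is reported
#' so the deficit is visible.
#'
#' @param observed named state-fraction vector (the observed composition O).
#' @param cm a \code{confusion_matrix} (or bare 9 x 9 matrix P).
#' @return an object of class \code{corrected_fractions}: list with
#'   \code{estimate} (clamped T), \code{raw} (pre-clamp solution),
#'   \code{residual} (P estimate - O), \code{condition} (estimated
#'   condition number of P) and \code{total} (sum of the estimate).
#' @export
correct_fractions <- function(observed, cm) {
  P <- if (inherits(cm, "confusion_matrix")) cm$P else cm
  stopifnot(is.matrix(P), all(dim(P) == c(9, 9)))
  o <- state_fractions(observed, normalized = FALSE)
  cond <- kappa(P, exact = TRUE)
  if (!is.finite(cond) || cond > 1e12) {
    stop("confusion matrix is (near-)singular; more spike-in depth is ",
         "needed to estimate the call rates")
  }
  raw <- drop(solve(P, o))
  names(raw) <- CPG_STATES
  est <- pmax(raw, 0)
  structure(list(estimate = est, raw = raw,
                 residual = drop(P %*% est) - o, condition = cond,
                 total = sum(est)),
            class = "corrected_fractions")
}

#' @export
print.corrected_fractions <- function(x, digits = 4, ...) {
  cat("corrected state fractions (negatives clamped to zero):\n")
  print(round(x$estimate, digits))
  cat(sprintf("sum = %.6f; condition number of P = %.3g\n",
              x$total, x$condition))
  if (any(x$raw < 0)) {
    cat("clamped states:", paste(CPG_STATES[x$raw < 0], collapse = " "), "\n")
  }
  invisible(x)
}

#' Write corrected fractions to TSV
#'
#' @param x a \code{corrected_fractions} object.
#' @param path TSV path.
#' @export
write_corrected_fractions <- function(x, path) {
  df <- data.frame(state = CPG_STATES, estimate = x$estimate, raw = x$raw,
                   residual = x$residual, row.names = NULL)
  write_tsv(df, path)
}
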