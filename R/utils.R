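# internal helpers: seeded RNG scoping, string ops on plain character
# sequences (Biostrings is used at the I/O boundary; the hot paths work on
# character vectors), and commented-TSV readers/writers.

#' @importFrom methods as is
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils read.table write.table packageVersion
NULL

# evaluate `code` under set.seed(seed), restoring the caller's RNG state;
# seed = NULL uses (and advances) the current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

# three-letter collapse: deaminated space ignores the C/T distinction on the
# read-out strand, so C is folded into T for seeding/equality
collapse3 <- function(x) chartr("C", "T", x)

# asymmetric converted-space mismatch count between a read segment and the
# reference segment it claims: read T matches ref C or T; read C matches only
# ref C; A/G exact. Equivalent to: mismatches after C->T collapse on both,
# plus positions where the read kept a C over a non-C reference base.
conv_mismatch <- function(read, ref) {
  if (nchar(read) != nchar(ref)) return(NA_integer_)
  r <- charToRaw(read)
  f <- charToRaw(ref)
  rc <- r
  rc[rc == charToRaw("C")] <- charToRaw("T")
  fc <- f
  fc[fc == charToRaw("C")] <- charToRaw("T")
  sum(rc != fc) + sum(r == charToRaw("C") & f != charToRaw("C"))
}

# positions (1-based) of `what` (single char) in a string; integer(0) if none
char_positions <- function(x, what) {
  which(charToRaw(x) == charToRaw(what))
}

# replace characters at 1-based positions with `what`
set_chars <- function(x, pos, what) {
  if (length(pos) == 0L) return(x)
  r <- charToRaw(x)
  r[pos] <- charToRaw(what)
  rawToChar(r)
}

pkg_header <- function(config_hash = NULL) {
  v <- as.character(utils::packageVersion("duplexCpG"))
  h <- if (is.null(config_hash)) "none" else config_hash
  sprintf("# duplexCpG v%s config=%s", v, h)
}

write_tsv <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pkg_header(config_hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             colClasses = colClasses, stringsAsFactors = FALSE)
}
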