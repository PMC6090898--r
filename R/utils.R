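# Internal helpers shared across modules.

#' Reverse-complement a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T/N, case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @export
#' @examples
#' revcomp("ATGAAAACGTTTTCAA")
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Encode a DNA string as integers 1..4 (A,C,G,T); anything else becomes NA.
dna_to_int <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  match(v, c("A", "C", "G", "T"))
}

DNA_BASES4 <- c("A", "C", "G", "T")

# stop() with a consistent prefix naming the offending field.
bail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Check x is a numeric interval c(lo, hi) with lo <= hi.
check_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] > x[2])
    bail("field '%s' must be a numeric interval c(min, max) with min <= max", name)
  invisible(x)
}

# Draw integers uniformly from an inclusive interval (single-valued allowed).
runif_int <- function(n, interval) {
  if (interval[1] == interval[2]) rep.int(as.integer(interval[1]), n)
  else sample(seq.int(interval[1], interval[2]), n, replace = TRUE)
}

# Format a double so that read-back is bit-exact.
fmt_num <- function(x) sprintf("%.17g", x)
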