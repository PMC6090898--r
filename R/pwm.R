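#' Position weight matrix
#'
#' A PWM holds per-position base probabilities and a background
#' distribution. Scores are log2 odds against the background, in bits.
#'
#' @param prob Numeric matrix, `width` rows by 4 columns (A, C, G, T); each
#'   row must sum to 1 (within 1e-9) and, after smoothing, contain no zeros
#'   if exact p-values are required over the full score range.
#' @param background Length-4 numeric vector of background base
#'   probabilities (A, C, G, T), summing to 1. Default uniform.
#' @param iupac Optional source IUPAC string for provenance.
#' @return A `pwm` object.
#' @export
pwm <- function(prob, background = rep(0.25, 4), iupac = NULL) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4) bail("PWM probability matrix must have 4 columns (A,C,G,T)")
  colnames(prob) <- DNA_BASES4
  if (any(abs(rowSums(prob) - 1) > 1e-9))
    bail("PWM rows must each sum to 1")
  if (abs(sum(background) - 1) > 1e-9)
    bail("background must sum to 1")
  structure(list(width = nrow(prob), prob = prob,
                 background = setNames(as.numeric(background), DNA_BASES4),
                 iupac = iupac),
            class = "pwm")
}

# IUPAC degenerate code -> allowed base sets.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Build a PWM from an IUPAC degenerate consensus
#'
#' Without a `consensus`, each position with `k` allowed bases assigns
#' probability `(1 - gamma)/k` to every allowed base and `gamma/(4 - k)` to
#' every disallowed base; a fully degenerate position (`N`) is uniform
#' regardless of `gamma`. The smoothing keeps all probabilities positive so
#' every window has a finite log-odds score.
#'
#' A degeneracy pattern alone makes all allowed bases of a position score
#' identically, which caps how small a p-value any window can reach. When
#' the motif's single-best consensus sequence is known (as it is for the
#' cre site), supplying it weights each position's allowed set the way a
#' binding-site count matrix would: the consensus base receives fraction
#' `consensus_weight` of the allowed mass and the remaining allowed bases
#' share the rest equally.
#'
#' @param pattern IUPAC string, e.g. the cre-site matrix
#'   `"HWNMHAHSVNDHNHHN"`.
#' @param background Background base probabilities (A, C, G, T).
#' @param gamma Smoothing mass given to disallowed bases (default 0.04).
#' @param consensus Optional consensus sequence of the same width; each
#'   consensus base must belong to its position's allowed set.
#' @param consensus_weight Fraction of the allowed probability mass given
#'   to the consensus base (default 0.7, a typical top-base frequency in
#'   bacterial binding-site count matrices).
#' @return A [pwm()].
#' @export
#' @examples
#' cre <- pwm_from_iupac("HWNMHAHSVNDHNHHN", consensus = "ATGAAAACGTTTTCAA")
pwm_from_iupac <- function(pattern, background = rep(0.25, 4), gamma = 0.04,
                           consensus = NULL, consensus_weight = 0.7) {
  codes <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- which(!codes %in% names(IUPAC_SETS))
  if (length(bad))
    bail("invalid IUPAC code '%s' at position %d", codes[bad[1]], bad[1])
  cons <- NULL
  if (!is.null(consensus)) {
    cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
    if (length(cons) != length(codes))
      bail("consensus length %d does not match pattern length %d",
           length(cons), length(codes))
  }
  prob <- t(vapply(seq_along(codes), function(i) {
    allowed <- IUPAC_SETS[[codes[i]]]
    k <- length(allowed)
    mass <- if (k == 4) 1 else 1 - gamma
    p <- rep(if (k == 4) 0 else gamma / (4 - k), 4)
    names(p) <- DNA_BASES4
    if (is.null(cons) || k == 1) {
      p[allowed] <- mass / k
    } else {
      if (!cons[i] %in% allowed)
        bail("consensus base '%s' at position %d not in allowed set '%s'",
             cons[i], i, codes[i])
      p[allowed] <- mass * (1 - consensus_weight) / (k - 1)
      p[cons[i]] <- mass * consensus_weight
    }
    p
  }, numeric(4)))
  rownames(prob) <- NULL
  pwm(prob, background, iupac = toupper(pattern))
}

#' The catabolite-responsive element (cre) weight matrix
#'
#' Convenience constructor for the cre-site PWM: degeneracy pattern
#' `HWNMHAHSVNDHNHHN` weighted toward the consensus `ATGAAAACGTTTTCAA`.
#'
#' @inheritParams pwm_from_iupac
#' @return A [pwm()].
#' @export
cre_pwm <- function(background = rep(0.25, 4), gamma = 0.04,
                    consensus_weight = 0.7) {
  pwm_from_iupac("HWNMHAHSVNDHNHHN", background, gamma,
                 consensus = "ATGAAAACGTTTTCAA",
                 consensus_weight = consensus_weight)
}

#' Read a motif from MEME minimal format
#'
#' Parses the first (or only) motif of a MEME minimal-format file over the
#' ACGT alphabet. Letter-probability rows are renormalized to sum exactly
#' to 1; rows whose raw sum falls outside [0.99, 1.01] are rejected.
#'
#' @param path MEME minimal motif file.
#' @param background Background probabilities for the returned PWM; when
#'   NULL, the file's `Background letter frequencies` line is used if
#'   present, else uniform.
#' @return A [pwm()].
#' @export
read_meme_motif <- function(path, background = NULL) {
  if (!file.exists(path)) bail("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(background)) {
    bi <- grep("^Background letter frequencies", lines)
    if (length(bi)) {
      tok <- strsplit(trimws(lines[bi[1] + 1]), "\\s+")[[1]]
      background <- as.numeric(tok[c(2, 4, 6, 8)])
    } else background <- rep(0.25, 4)
  }
  mi <- grep("^letter-probability matrix", lines)
  if (!length(mi)) bail("%s: no 'letter-probability matrix' section", path)
  start <- mi[1] + 1
  rows <- list()
  for (i in start:length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(vals) != 4 || anyNA(vals)) break
    if (abs(sum(vals) - 1) > 0.01)
      bail("%s:%d: probability row sums to %.4f, outside [0.99, 1.01]",
           path, i, sum(vals))
    rows[[length(rows) + 1]] <- vals / sum(vals)
  }
  if (!length(rows)) bail("%s: empty letter-probability matrix", path)
  pwm(do.call(rbind, rows), background)
}

#' Write a motif in MEME minimal format
#'
#' @param x A [pwm()].
#' @param path Output path.
#' @param name Motif name written in the file.
#' @return `path`, invisibly.
#' @export
write_meme_motif <- function(x, path, name = "motif1") {
  con <- file(path, "w")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       x$background[1], x$background[2],
                       x$background[3], x$background[4]), "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       x$width)), con)
  writeLines(apply(x$prob, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
             con)
  close(con)
  invisible(path)
}
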