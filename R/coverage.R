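#' Strand-specific per-base coverage track
#'
#' A coverage track stores one non-negative numeric vector per contig and
#' strand, with one value per base (0-based indexing internally: element `i`
#' of the vector is the coverage of base `i - 1`).
#'
#' @param contig_lengths Named integer vector of contig lengths.
#' @return An all-zero `coverage_track`: a named list (per contig) of lists
#'   with elements `plus` and `minus`.
#' @export
coverage_track <- function(contig_lengths) {
  stopifnot(length(contig_lengths) > 0, !is.null(names(contig_lengths)))
  trk <- lapply(contig_lengths, function(L) {
    list(plus = numeric(L), minus = numeric(L))
  })
  class(trk) <- "coverage_track"
  trk
}

track_strand <- function(strand) if (strand == "+") "plus" else "minus"

#' Read a strand-specific coverage track from a pair of bedGraph files
#'
#' bedGraph has no strand column, so coverage is stored as two files, one per
#' strand. Intervals are 0-based half-open; bases absent from the file have
#' coverage 0. Overlapping intervals, intervals beyond the contig end and
#' negative values are rejected.
#'
#' @param plus_path,minus_path bedGraph files for the + and - strand.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return A [coverage_track()].
#' @export
read_coverage <- function(plus_path, minus_path, contig_lengths) {
  trk <- coverage_track(contig_lengths)
  for (st in c("plus", "minus")) {
    path <- if (st == "plus") plus_path else minus_path
    if (!file.exists(path)) bail("file not found: %s", path)
    if (file.size(path) == 0) next
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0) next
    ct <- as.character(GenomicRanges::seqnames(gr))
    s0 <- GenomicRanges::start(gr) - 1L   # back to 0-based
    e0 <- GenomicRanges::end(gr)
    val <- gr$score
    if (any(val < 0)) bail("%s: negative coverage value", path)
    unknown <- setdiff(unique(ct), names(contig_lengths))
    if (length(unknown)) bail("%s: unknown contig '%s'", path, unknown[1])
    if (any(e0 > contig_lengths[ct]))
      bail("%s: interval beyond contig length", path)
    seen <- lapply(contig_lengths, logical)
    for (k in seq_along(gr)) {
      idx <- (s0[k] + 1L):e0[k]
      if (any(seen[[ct[k]]][idx]))
        bail("%s: overlapping intervals on contig '%s'", path, ct[k])
      seen[[ct[k]]][idx] <- TRUE
      trk[[ct[k]]][[st]][idx] <- val[k]
    }
  }
  trk
}

#' Write a coverage track as a pair of bedGraph files
#'
#' Runs of equal coverage are collapsed to single 0-based half-open
#' intervals; zero-coverage runs are omitted. Values are written with full
#' precision so that write/read round-trips are exact.
#'
#' @param trk A [coverage_track()].
#' @param plus_path,minus_path Output paths for the two strands.
#' @return Invisibly, `c(plus_path, minus_path)`.
#' @export
write_coverage <- function(trk, plus_path, minus_path) {
  for (st in c("plus", "minus")) {
    path <- if (st == "plus") plus_path else minus_path
    con <- file(path, "w")
    for (ct in names(trk)) {
      v <- trk[[ct]][[st]]
      if (length(v) == 0) next
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths  # 0-based
      keep <- r$values != 0
      if (any(keep))
        writeLines(paste(ct, starts[keep], ends[keep],
                         fmt_num(r$values[keep]), sep = "\t"), con)
    }
    close(con)
  }
  invisible(c(plus_path, minus_path))
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (!all(strsplit(paste(seqs, collapse = ""), "")[[1]] %in%
           c("A", "C", "G", "T", "N")))
    bail("%s: sequence contains letters outside A/C/G/T/N", path)
  seqs
}

#' Write a genome to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
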