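#' Count substitutions between two aligned sequences
#'
#' Columns where both residues are non-gap and different are substitutions;
#' columns containing a gap in either sequence are excluded from the count
#' and reported separately as gap columns (deletions/insertions).
#' Comparison is case-insensitive; ambiguity letters are treated as
#' ordinary residues.
#'
#' @param a,b Aligned sequences of equal length (gap character `-`).
#' @return A list: `n_substitutions`, `n_gap_columns`, `n_matches`, and
#'   `records` (data.frame `position` (1-based column), `residue_a`,
#'   `residue_b` for each substitution).
#' @export
count_substitutions <- function(a, b) {
  va <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(va) != length(vb))
    bail("aligned sequences differ in length (%d vs %d)",
         length(va), length(vb))
  if (any(va == "-" & vb == "-"))
    bail("alignment has a column that is gap in both sequences")
  gap <- va == "-" | vb == "-"
  sub <- !gap & va != vb
  list(n_substitutions = sum(sub),
       n_gap_columns = sum(gap),
       n_matches = sum(!gap & va == vb),
       records = data.frame(position = which(sub),
                            residue_a = va[sub], residue_b = vb[sub],
                            stringsAsFactors = FALSE))
}

#' List mismatches of aligned sequences against a reference
#'
#' For each non-reference sequence, reports every column whose residue
#' differs from the reference (gap columns included as records with a `-`
#' residue, but see [count_substitutions()] for substitution-only counts).
#'
#' @param alignment Named character vector of aligned sequences of equal
#'   length.
#' @param reference_id Name of the reference sequence.
#' @return A data.frame: `seq_id`, `position` (1-based column),
#'   `ref_residue`, `alt_residue`.
#' @export
list_mismatches <- function(alignment, reference_id) {
  if (!reference_id %in% names(alignment))
    bail("reference '%s' not found in alignment", reference_id)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1)
    bail("aligned sequences differ in length")
  ref <- strsplit(toupper(alignment[[reference_id]]), "", fixed = TRUE)[[1]]
  out <- list()
  for (id in setdiff(names(alignment), reference_id)) {
    v <- strsplit(toupper(alignment[[id]]), "", fixed = TRUE)[[1]]
    d <- which(v != ref)
    if (length(d))
      out[[id]] <- data.frame(seq_id = id, position = d,
                              ref_residue = ref[d], alt_residue = v[d],
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(seq_id = character(), position = integer(),
                      ref_residue = character(), alt_residue = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Render an alignment as a dot matrix against a reference
#'
#' Conserved positions are shown as dots, differences as the alternative
#' letter — the conventional display for comparing promoter regions across
#' strains.
#'
#' @inheritParams list_mismatches
#' @return Character vector, one line per sequence (reference first, shown
#'   in full).
#' @export
render_dot_matrix <- function(alignment, reference_id) {
  mm <- list_mismatches(alignment, reference_id)
  ref <- toupper(alignment[[reference_id]])
  lines <- c(setNames(ref, reference_id))
  for (id in setdiff(names(alignment), reference_id)) {
    v <- strsplit(strrep(".", nchar(ref)), "", fixed = TRUE)[[1]]
    d <- mm[mm$seq_id == id, , drop = FALSE]
    v[d$position] <- d$alt_residue
    lines[id] <- paste(v, collapse = "")
  }
  lines
}

#' Read an aligned FASTA file
#'
#' @param path Aligned FASTA (residues plus `-` gaps).
#' @return Named character vector of uppercase aligned sequences.
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}
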