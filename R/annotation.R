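#' Gene annotation table
#'
#' The central gene model shared by all stages. Coordinates are internal
#' 0-based half-open (`start` inclusive, `end` exclusive), so
#' `length_bp = end - start`. GFF3 input/output converts to and from the
#' 1-based inclusive convention at the file boundary.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param contig Character vector of contig names.
#' @param start,end Integer vectors, 0-based half-open span per gene.
#' @param strand Character vector, each "+" or "-".
#' @param category Optional character vector of functional category labels
#'   (NA when unannotated).
#' @return A `data.frame` with class `genome_annotation`, rows sorted by
#'   (contig, start), columns `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `length_bp`, `category`.
#' @export
genome_annotation <- function(gene_id, contig, start, end, strand,
                              category = NA_character_) {
  ann <- data.frame(
    gene_id = as.character(gene_id),
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  ann$length_bp <- ann$end - ann$start
  ann$category <- rep_len(as.character(category), nrow(ann))
  ann <- ann[order(ann$contig, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("genome_annotation", "data.frame")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  if (anyDuplicated(ann$gene_id))
    bail("duplicate gene_id: %s", ann$gene_id[duplicated(ann$gene_id)][1])
  if (any(ann$start >= ann$end))
    bail("gene '%s' has start >= end", ann$gene_id[ann$start >= ann$end][1])
  if (!all(ann$strand %in% c("+", "-")))
    bail("strand must be '+' or '-'")
  # same-strand genes must not overlap within a contig
  for (ct in unique(ann$contig)) {
    for (st in c("+", "-")) {
      a <- ann[ann$contig == ct & ann$strand == st, , drop = FALSE]
      if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)]))
        bail("overlapping same-strand genes on contig '%s'", ct)
    }
  }
  invisible(ann)
}

#' Read a gene annotation from GFF3
#'
#' Accepts `gene`/`CDS` features carrying an `ID` attribute and an optional
#' `category` attribute. GFF3 1-based inclusive coordinates are converted to
#' the internal 0-based half-open convention. Malformed records are rejected
#' with the file name and line number rather than silently repaired.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Feature types to keep (default `gene`).
#' @return A [genome_annotation()] table.
#' @export
read_annotation <- function(path, feature_types = "gene") {
  if (!file.exists(path)) bail("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  ids_seen <- character(0)
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      bail("%s:%d: expected 9 tab-separated columns", path, i)
    if (!(f[3] %in% feature_types)) next
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || s > e)
      bail("%s:%d: invalid coordinates (start > end or non-numeric)", path, i)
    m <- regmatches(f[9], regexec("(?:^|;)ID=([^;]+)", f[9]))[[1]]
    if (length(m) == 2) {
      if (m[2] %in% ids_seen) bail("%s:%d: duplicate ID '%s'", path, i, m[2])
      ids_seen <- c(ids_seen, m[2])
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_types]
  if (length(gr) == 0) bail("%s: no '%s' features found", path, feature_types[1])
  cat_col <- if ("category" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$category) else NA_character_
  genome_annotation(
    gene_id = as.character(gr$ID),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    category = cat_col
  )
}

#' Write a gene annotation to GFF3
#'
#' Inverse of [read_annotation()]: internal 0-based half-open coordinates are
#' written as 1-based inclusive. `category` is emitted as a GFF3 attribute
#' when present.
#'
#' @param ann A [genome_annotation()] table.
#' @param path Output file path.
#' @param feature_type Feature type column value (default `gene`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, feature_type = "gene") {
  attrs <- paste0("ID=", ann$gene_id)
  has_cat <- !is.na(ann$category)
  attrs[has_cat] <- paste0(attrs[has_cat], ";category=", ann$category[has_cat])
  lines <- paste(ann$contig, "bactx", feature_type,
                 ann$start + 1L, ann$end, ".", ann$strand, ".", attrs,
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
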