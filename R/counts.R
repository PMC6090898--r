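#' Gene-by-sample count matrix with library sizes
#'
#' Container for raw mapped-read counts per gene and sample, together with
#' each sample's library size (total mapped reads, the `N` of RPKM) and its
#' condition label.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param lib_size Numeric vector of library sizes, one per column. Must be
#'   at least the column sum of `counts`.
#' @param condition Character vector of condition labels, one per column.
#' @return A `count_matrix` object (list with `counts`, `lib_size`,
#'   `condition`).
#' @export
count_matrix <- function(counts, lib_size, condition) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    bail("counts must have gene rownames and sample colnames")
  if (any(counts < 0)) bail("counts must be non-negative")
  if (length(lib_size) != ncol(counts) || length(condition) != ncol(counts))
    bail("lib_size and condition must have one entry per sample")
  if (any(lib_size < colSums(counts)))
    bail("lib_size smaller than column sum of counts")
  structure(list(counts = counts, lib_size = as.numeric(lib_size),
                 condition = as.character(condition)),
            class = "count_matrix")
}

#' Read a count matrix from TSV
#'
#' The dialect is tab-separated UTF-8 without quoting: a `#lib_size` comment
#' line (tab-separated library sizes, aligned with the sample columns), an
#' optional `#condition` comment line, then a header row starting with
#' `gene_id` followed by sample ids, then one row per gene.
#'
#' @param path TSV file.
#' @param condition Condition labels per sample; overrides any `#condition`
#'   line in the file.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, condition = NULL) {
  if (!file.exists(path)) bail("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lib_line <- grep("^#lib_size\t", lines, value = TRUE)
  if (length(lib_line) != 1)
    bail("%s: expected exactly one '#lib_size' line", path)
  lib_size <- as.numeric(strsplit(lib_line, "\t", fixed = TRUE)[[1]][-1])
  cond_line <- grep("^#condition\t", lines, value = TRUE)
  if (is.null(condition) && length(cond_line) == 1)
    condition <- strsplit(cond_line, "\t", fixed = TRUE)[[1]][-1]
  tab <- read.delim(text = lines[!startsWith(lines, "#")], sep = "\t",
                    quote = "", check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id") bail("%s: first header column must be gene_id", path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  if (is.null(condition)) condition <- rep(NA_character_, ncol(m))
  count_matrix(m, lib_size, condition)
}

#' Write a count matrix to TSV
#'
#' @param cm A [count_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(paste(c("#lib_size", fmt_num(cm$lib_size)), collapse = "\t"), con)
  if (!all(is.na(cm$condition)))
    writeLines(paste(c("#condition", cm$condition), collapse = "\t"), con)
  writeLines(paste(c("gene_id", colnames(cm$counts)), collapse = "\t"), con)
  writeLines(paste(rownames(cm$counts),
                   apply(cm$counts, 1, paste, collapse = "\t"), sep = "\t"), con)
  close(con)
  invisible(path)
}
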