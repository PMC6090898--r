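#' Parameters for operon reconstruction and boundary detection
#'
#' @param edge_fraction Fraction of the flanking gene's mean coverage below
#'   which the transcript is considered ended when walking outward from an
#'   operon (default 0.5). Operationalizes "very rapid coverage reduction".
#' @param max_extension Maximum UTR length searched, in bp (default 500).
#' @param min_gene_coverage Genes with mean per-base coverage below this are
#'   excluded from reconstruction (default 2).
#' @param sd_multiplier Adjacent same-strand genes merge when the absolute
#'   log2 coverage ratio is below `sd_multiplier` times the standard
#'   deviation of the genome-wide ratio distribution (default 1).
#' @return A `boundary_params` list.
#' @export
boundary_params <- function(edge_fraction = 0.5, max_extension = 500L,
                            min_gene_coverage = 2, sd_multiplier = 1) {
  if (edge_fraction <= 0 || edge_fraction >= 1)
    bail("edge_fraction must be in (0, 1)")
  if (max_extension < 0) bail("max_extension must be >= 0")
  structure(list(edge_fraction = edge_fraction,
                 max_extension = as.integer(max_extension),
                 min_gene_coverage = min_gene_coverage,
                 sd_multiplier = sd_multiplier),
            class = "boundary_params")
}

#' Mean per-base coverage of every gene
#'
#' Arithmetic mean of strand-matched per-base coverage over each gene's
#' `[start, end)` span.
#'
#' @param trk A [coverage_track()].
#' @param ann A [genome_annotation()].
#' @return Named numeric vector, one value per gene.
#' @export
gene_mean_coverage <- function(trk, ann) {
  unknown <- setdiff(unique(ann$contig), names(trk))
  if (length(unknown)) bail("gene on unknown contig '%s'", unknown[1])
  out <- vapply(seq_len(nrow(ann)), function(i) {
    v <- trk[[ann$contig[i]]][[track_strand(ann$strand[i])]]
    mean(v[(ann$start[i] + 1L):ann$end[i]])
  }, numeric(1))
  setNames(out, ann$gene_id)
}

# Adjacent gene pairs: immediate neighbors in the full coordinate-sorted
# gene list of a contig. Genes below `min_coverage` are excluded and break
# adjacency: a pair only exists between directly consecutive genes, so two
# genes flanking an excluded one are never paired.
adjacent_pairs <- function(ann, cov = NULL, min_coverage = 0) {
  res <- list()
  for (ct in unique(ann$contig)) {
    g <- ann[ann$contig == ct, , drop = FALSE]
    if (nrow(g) < 2) next
    res[[ct]] <- data.frame(left = g$gene_id[-nrow(g)],
                            right = g$gene_id[-1],
                            same_strand = g$strand[-nrow(g)] == g$strand[-1],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(left = character(), right = character(),
                      same_strand = logical(), stringsAsFactors = FALSE)
  if (!is.null(cov) && min_coverage > 0) {
    ok <- cov[out$left] >= min_coverage & cov[out$right] >= min_coverage
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Log2 coverage ratios of neighboring same-strand genes
#'
#' One ratio `log2(cov_left / cov_right)` per pair of genes that are
#' immediate neighbors in genome order on the same contig and strand, with
#' both mean coverages positive. The standard deviation of this genome-wide
#' distribution is the operon merge threshold.
#'
#' @param cov Named coverage vector from [gene_mean_coverage()].
#' @param ann A [genome_annotation()].
#' @param min_coverage Genes below this mean coverage are dropped before
#'   pairing (they also break adjacency); default 0 keeps every gene.
#' @return A data.frame with `left`, `right`, `ratio`.
#' @export
neighbor_log_ratios <- function(cov, ann, min_coverage = 0) {
  pairs <- adjacent_pairs(ann, cov, min_coverage)
  pairs <- pairs[pairs$same_strand, , drop = FALSE]
  cl <- cov[pairs$left]; cr <- cov[pairs$right]
  ok <- cl > 0 & cr > 0
  data.frame(left = pairs$left[ok], right = pairs$right[ok],
             ratio = log2(cl[ok] / cr[ok]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# TRUE when any base of the intergenic span between two genes (on their
# shared strand) has zero coverage. Abutting or overlapping spans have no
# intergenic base, so the test is vacuously FALSE.
zero_gap_between <- function(trk, ann, left_id, right_id) {
  i <- match(left_id, ann$gene_id); j <- match(right_id, ann$gene_id)
  lo <- ann$end[i]; hi <- ann$start[j]  # 0-based half-open intergenic span
  if (hi <= lo) return(FALSE)
  v <- trk[[ann$contig[i]]][[track_strand(ann$strand[i])]]
  any(v[(lo + 1L):hi] == 0)
}

#' Reconstruct operons from gene coverage
#'
#' Implements the coverage-ratio rule set: genes with mean coverage below
#' `min_gene_coverage` are excluded (and break adjacency); each remaining
#' pair of immediately neighboring same-strand genes is merged into the
#' same operon when the absolute log2 ratio of their coverages is below
#' `sd_multiplier` times the standard deviation of the genome-wide ratio
#' distribution and no base of their intergenic span has zero coverage.
#' Merging is transitive over consecutive qualifying pairs; every retained
#' gene ends up in exactly one operon (singletons allowed).
#'
#' @param cov Named coverage vector from [gene_mean_coverage()].
#' @param ann A [genome_annotation()].
#' @param trk The [coverage_track()] the coverages came from (used for the
#'   zero-coverage intergenic rule).
#' @param params A [boundary_params()].
#' @param ratios Optional precomputed [neighbor_log_ratios()] table whose
#'   `ratio` column defines the threshold distribution; by default ratios
#'   are computed on the retained (coverage-filtered) genes.
#' @return A list of `operon` objects: each a list with `operon_id`,
#'   `genes` (ids in transcription order), `contig`, `strand`, `span`
#'   (0-based half-open gene-span before UTR extension), `tss`, `tts`,
#'   `utr5_len`, `utr3_len` (NA until [detect_transcript_boundaries()]).
#'   The list carries attributes `sigma_r` (the threshold SD) and
#'   `low_coverage_excluded` (data.frame of dropped genes).
#' @export
reconstruct_operons <- function(cov, ann, trk, params = boundary_params(),
                                ratios = NULL) {
  dropped <- ann$gene_id[cov[ann$gene_id] < params$min_gene_coverage]
  if (is.null(ratios))
    ratios <- neighbor_log_ratios(cov, ann, params$min_gene_coverage)
  n_r <- nrow(ratios)
  sigma_r <- if (n_r >= 1) sqrt(sum((ratios$ratio - mean(ratios$ratio))^2) / n_r)
  else NA_real_
  keep <- setdiff(ann$gene_id, dropped)
  a <- ann[ann$gene_id %in% keep, , drop = FALSE]
  full_idx <- match(a$gene_id, ann$gene_id)
  # decide merge per adjacent retained pair, then take runs
  operons <- list()
  for (ct in unique(a$contig)) {
    in_ct <- a$contig == ct
    g <- a[in_ct, , drop = FALSE]
    gi <- full_idx[in_ct]
    if (nrow(g) == 0) next
    merge_prev <- c(FALSE, vapply(seq_len(nrow(g))[-1], function(i) {
      # excluded genes break adjacency: members must be directly
      # consecutive in the full annotation order
      if (gi[i] != gi[i - 1] + 1L) return(FALSE)
      if (g$strand[i] != g$strand[i - 1]) return(FALSE)
      r <- log2(cov[g$gene_id[i - 1]] / cov[g$gene_id[i]])
      if (!is.finite(r)) return(FALSE)
      thr <- params$sd_multiplier * sigma_r
      ratio_ok <- if (is.na(sigma_r)) FALSE
      else if (sigma_r == 0) r == 0 else abs(r) < thr
      ratio_ok && !zero_gap_between(trk, ann, g$gene_id[i - 1], g$gene_id[i])
    }, logical(1)))
    grp <- cumsum(!merge_prev)
    for (k in unique(grp)) {
      gg <- g[grp == k, , drop = FALSE]
      ids <- gg$gene_id
      if (gg$strand[1] == "-") ids <- rev(ids)  # transcription order
      operons[[length(operons) + 1]] <- structure(list(
        operon_id = sprintf("operon_%04d", length(operons) + 1L),
        genes = ids, contig = ct, strand = gg$strand[1],
        span = c(min(gg$start), max(gg$end)),
        tss = NA_integer_, tts = NA_integer_,
        utr5_len = NA_integer_, utr3_len = NA_integer_),
        class = "operon")
    }
  }
  structure(operons,
            sigma_r = sigma_r,
            low_coverage_excluded = data.frame(
              gene_id = dropped, coverage = unname(cov[dropped]),
              stringsAsFactors = FALSE))
}

#' Locate transcription start and end sites of an operon
#'
#' Walks outward from the operon's gene span looking for the sharp coverage
#' reduction that marks the transcript edge: upstream of the first gene
#' (strand-aware) the transcript extends while per-base coverage stays at
#' least `edge_fraction` times the first gene's mean coverage and above
#' zero, up to `max_extension` bp; downstream of the last gene the walk is
#' mirrored against the last gene's mean coverage.
#'
#' @param trk A [coverage_track()].
#' @param operon One operon from [reconstruct_operons()].
#' @param cov Named coverage vector from [gene_mean_coverage()].
#' @param ann A [genome_annotation()].
#' @param params A [boundary_params()].
#' @return The operon with `tss`, `tts`, `utr5_len`, `utr3_len` filled in
#'   (0-based positions; `tss` is the first transcribed base in transcript
#'   orientation).
#' @export
detect_transcript_boundaries <- function(trk, operon, cov, ann,
                                         params = boundary_params()) {
  v <- trk[[operon$contig]][[track_strand(operon$strand)]]
  L <- length(v)
  first_gene <- operon$genes[1]
  last_gene <- operon$genes[length(operon$genes)]
  thr5 <- params$edge_fraction * cov[first_gene]
  thr3 <- params$edge_fraction * cov[last_gene]
  walk <- function(from, step, thr) {
    # count bases, starting at `from` (0-based), moving by `step`, with
    # coverage >= thr and > 0, stopping at max_extension or contig edge
    d <- 0L
    pos <- from
    while (d < params$max_extension && pos >= 0L && pos < L &&
           v[pos + 1L] >= thr && v[pos + 1L] > 0) {
      d <- d + 1L
      pos <- pos + step
    }
    d
  }
  i5 <- match(first_gene, ann$gene_id)
  i3 <- match(last_gene, ann$gene_id)
  if (operon$strand == "+") {
    utr5 <- walk(ann$start[i5] - 1L, -1L, thr5)
    utr3 <- walk(ann$end[i3], +1L, thr3)
    operon$tss <- ann$start[i5] - utr5
    operon$tts <- ann$end[i3] - 1L + utr3
  } else {
    utr5 <- walk(ann$end[i5], +1L, thr5)
    utr3 <- walk(ann$start[i3] - 1L, -1L, thr3)
    operon$tss <- ann$end[i5] - 1L + utr5
    operon$tts <- ann$start[i3] - utr3
  }
  operon$utr5_len <- utr5
  operon$utr3_len <- utr3
  operon
}

#' Reconstruct operons and their transcript boundaries in one call
#'
#' @inheritParams reconstruct_operons
#' @return As [reconstruct_operons()], with boundaries filled in.
#' @export
reconstruct_transcripts <- function(cov, ann, trk, params = boundary_params()) {
  ops <- reconstruct_operons(cov, ann, trk, params)
  res <- lapply(ops, detect_transcript_boundaries, trk = trk, cov = cov,
                ann = ann, params = params)
  attributes(res) <- attributes(ops)
  res
}

#' Summarize operons as a data.frame
#'
#' @param operons Result of [reconstruct_operons()] or
#'   [reconstruct_transcripts()].
#' @return A data.frame: `operon_id`, `contig`, `strand`, `genes`
#'   (comma-separated, transcription order), `n_genes`, `tss`, `tts`,
#'   `utr5_len`, `utr3_len`.
#' @export
operon_table <- function(operons) {
  data.frame(
    operon_id = vapply(operons, `[[`, "", "operon_id"),
    contig = vapply(operons, `[[`, "", "contig"),
    strand = vapply(operons, `[[`, "", "strand"),
    genes = vapply(operons, function(o) paste(o$genes, collapse = ","), ""),
    n_genes = vapply(operons, function(o) length(o$genes), 1L),
    tss = vapply(operons, function(o) as.integer(o$tss), 1L),
    tts = vapply(operons, function(o) as.integer(o$tts), 1L),
    utr5_len = vapply(operons, function(o) as.integer(o$utr5_len), 1L),
    utr3_len = vapply(operons, function(o) as.integer(o$utr3_len), 1L),
    stringsAsFactors = FALSE)
}
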