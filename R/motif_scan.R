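#' Scan configuration
#'
#' Parameters for genome-wide PWM scanning and promoter assignment.
#'
#' @param p_threshold Report windows with p-value strictly below this
#'   (default 1e-6). A value of 1 or larger disables filtering entirely and
#'   reports every scorable window.
#' @param lattice_bins Resolution of the discretized score lattice used for
#'   exact p-values (default 1000).
#' @param promoter_window Maximum distance (bp) from a hit's downstream edge
#'   to a regulated gene's 5' end (default 300).
#' @param gamma IUPAC smoothing mass (default 0.04), used when the motif is
#'   given as a degenerate string.
#' @return A `scan_config` list.
#' @export
scan_config <- function(p_threshold = 1e-6, lattice_bins = 1000L,
                        promoter_window = 300L, gamma = 0.04) {
  if (p_threshold <= 0) bail("p_threshold must be positive")
  if (lattice_bins < 100) bail("lattice_bins must be >= 100")
  structure(list(p_threshold = p_threshold,
                 lattice_bins = as.integer(lattice_bins),
                 promoter_window = as.integer(promoter_window),
                 gamma = gamma),
            class = "scan_config")
}

# log2 odds matrix (width x 4) of a pwm
pwm_logodds <- function(x) {
  lo <- log2(sweep(x$prob, 2, x$background, "/"))
  if (any(!is.finite(lo)))
    bail("PWM contains zero probabilities; apply smoothing before scanning")
  lo
}

#' Log-odds scores of every window on both strands
#'
#' The plus-strand score at window start `pos` (0-based) is the sum over
#' motif positions of `log2(p[i][base]/q[base])`; the minus-strand score at
#' the same window is the plus-strand score of the reverse complement of
#' that window. Windows containing `N` score `NA` and can never become hits.
#'
#' @param x A [pwm()].
#' @param seqs Named character vector of contig sequences.
#' @return Named list per contig with numeric vectors `plus` and `minus` of
#'   length `L - width + 1` (window start positions, 0-based offset `i-1`).
#' @export
logodds_scores <- function(x, seqs) {
  lo <- pwm_logodds(x)
  w <- x$width
  lo_rc <- lo[w:1, 4:1, drop = FALSE]  # minus strand via reverse complement
  lapply(seqs, function(s) {
    code <- dna_to_int(s)
    L <- length(code)
    if (L < w) return(list(plus = numeric(0), minus = numeric(0)))
    n <- L - w + 1L
    sp <- numeric(n); sm <- numeric(n)
    for (i in seq_len(w)) {
      b <- code[i:(n + i - 1L)]
      sp <- sp + lo[i, ][b]
      sm <- sm + lo_rc[i, ][b]
    }
    list(plus = unname(sp), minus = unname(sm))
  })
}

#' Exact null distribution of PWM scores
#'
#' Discretizes each motif position's scores onto an integer lattice spanning
#' the full score range with `lattice_bins` steps, then convolves positions
#' under the background to obtain the exact tail probability
#' `P(score >= s)` for a random background window. Distribution scores are
#' rounded up to lattice points and query scores down, so the tail lookup
#' never underestimates a p-value (it is conservative by at most the
#' lattice resolution times the motif width).
#'
#' @param x A [pwm()].
#' @param lattice_bins Lattice resolution (default 1000).
#' @return A `pwm_score_dist` object usable with [pwm_pvalue()].
#' @export
score_distribution <- function(x, lattice_bins = 1000L) {
  lo <- pwm_logodds(x)
  col_min <- apply(lo, 1, min)
  col_max <- apply(lo, 1, max)
  min_total <- sum(col_min)
  max_total <- sum(col_max)
  rng <- max_total - min_total
  if (rng <= 0) {
    # degenerate PWM: every window has the same score
    out <- list(min_total = min_total, max_total = max_total, scale = NA_real_,
                tail = c(1, 0))
    class(out) <- "pwm_score_dist"
    return(out)
  }
  scale <- lattice_bins / rng
  int_s <- ceiling((lo - col_min) * scale)  # width x 4, integer lattice
  maxint <- sum(apply(int_s, 1, max))
  p <- c(1, numeric(maxint))  # p[j+1] = P(partial score == j)
  q <- x$background
  for (i in seq_len(nrow(lo))) {
    np <- numeric(maxint + 1L)
    for (b in 1:4) {
      sft <- int_s[i, b]
      idx <- which(p > 0)
      np[idx + sft] <- np[idx + sft] + p[idx] * q[b]
    }
    p <- np
  }
  out <- list(min_total = min_total, max_total = max_total, scale = scale,
              col_min = col_min, tail = rev(cumsum(rev(p))))
  class(out) <- "pwm_score_dist"
  out
}

#' Tail p-value of a PWM score
#'
#' @param dist A [score_distribution()].
#' @param s Numeric vector of log-odds scores (bits).
#' @return `P(score >= s)` under the background model, per element.
#' @export
pwm_pvalue <- function(dist, s) {
  if (is.na(dist$scale))
    return(ifelse(s <= dist$min_total + 1e-12, 1, 0))
  na <- is.na(s)
  s[na] <- dist$min_total
  idx <- pmax(0, floor((s - dist$min_total) * dist$scale))
  n <- length(dist$tail)
  # query scores round down while the lattice rounded up, so any
  # attainable score stays inside; beyond the maximum is impossible (p = 0)
  inside <- s <= dist$max_total + 1e-9
  idx <- pmin(idx, n - 1L)
  out <- numeric(length(s))
  out[inside] <- dist$tail[idx[inside] + 1L]
  out[!inside] <- 0
  out[na] <- NA_real_
  out
}

#' Scan a genome for motif hits on both strands
#'
#' Scores every window on both strands, converts scores to exact background
#' p-values and reports windows below the threshold. Overlapping hits and
#' both strands of a palindromic site are all reported.
#'
#' @param x A [pwm()].
#' @param seqs Named character vector of contig sequences.
#' @param config A [scan_config()].
#' @param background Either `"genome"` (0-order mononucleotide frequencies
#'   of the scanned sequence, the default) or `"uniform"`, or a length-4
#'   numeric vector. Overrides the PWM's stored background.
#' @return A data.frame with columns `contig`, `start` (0-based), `end`
#'   (half-open), `strand`, `seq` (plus-strand letters of the window),
#'   `score` (bits), `pvalue`, sorted by (contig, start, strand).
#' @export
scan_motifs <- function(x, seqs, config = scan_config(),
                        background = "genome") {
  if (is.numeric(background)) {
    bg <- background / sum(background)
  } else if (identical(background, "genome")) {
    all_code <- unlist(lapply(seqs, dna_to_int), use.names = FALSE)
    tab <- tabulate(all_code, nbins = 4)
    bg <- if (sum(tab) == 0) rep(0.25, 4) else tab / sum(tab)
    if (any(bg == 0)) bg <- (tab + 1) / sum(tab + 1)  # avoid log(0)
  } else {
    bg <- rep(0.25, 4)
  }
  x <- pwm(x$prob, bg, iupac = x$iupac)
  dist <- score_distribution(x, config$lattice_bins)
  sc <- logodds_scores(x, seqs)
  w <- x$width
  res <- lapply(names(seqs), function(ct) {
    rows <- lapply(c("+", "-"), function(st) {
      s <- sc[[ct]][[track_strand(st)]]
      if (!length(s)) return(NULL)
      p <- pwm_pvalue(dist, s)
      keep <- if (config$p_threshold >= 1) !is.na(p) else !is.na(p) & p < config$p_threshold
      if (!any(keep)) return(NULL)
      pos <- which(keep) - 1L
      data.frame(contig = ct, start = pos, end = pos + w, strand = st,
                 seq = substring(seqs[[ct]], pos + 1L, pos + w),
                 score = s[keep], pvalue = p[keep],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), seq = character(),
                      score = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign motif hits to putatively regulated genes
#'
#' A hit is assigned to the nearest gene on each strand whose 5' end lies at
#' most `promoter_window` bp downstream of the hit's downstream edge on that
#' strand (the gene may also overlap the hit by up to the motif width). A
#' hit between divergently oriented genes can be assigned to one gene on
#' each strand.
#'
#' @param hits Hit table from [scan_motifs()].
#' @param ann A [genome_annotation()].
#' @param config A [scan_config()] (only `promoter_window` is used).
#' @return A data.frame with one row per (hit, assigned gene): hit columns
#'   plus `gene_id` and `distance` (bp from hit's downstream edge to gene
#'   start; negative when overlapping). Hits with no assignable gene get a
#'   single row with `gene_id = NA`.
#' @export
assign_hits_to_genes <- function(hits, ann, config = scan_config()) {
  U <- config$promoter_window
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    assigned <- list()
    a <- ann[ann$contig == h$contig, , drop = FALSE]
    # plus-strand genes: first gene start >= hit_end - w within U of hit_end
    ap <- a[a$strand == "+" & a$start >= h$start, , drop = FALSE]
    if (nrow(ap)) {
      g <- ap[which.min(ap$start), ]
      d <- g$start - h$end
      if (d <= U) assigned[[length(assigned) + 1]] <-
          data.frame(gene_id = g$gene_id, distance = d)
    }
    # minus-strand genes: 5' end is `end`; nearest gene end <= hit_start + w
    am <- a[a$strand == "-" & a$end <= h$end, , drop = FALSE]
    if (nrow(am)) {
      g <- am[which.max(am$end), ]
      d <- h$start - g$end
      if (d <= U) assigned[[length(assigned) + 1]] <-
          data.frame(gene_id = g$gene_id, distance = d)
    }
    if (!length(assigned))
      assigned <- list(data.frame(gene_id = NA_character_, distance = NA_real_))
    for (as_ in assigned)
      out[[length(out) + 1]] <- cbind(h, as_, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- cbind(hits[0, ], data.frame(gene_id = character(), distance = numeric()))
  rownames(res) <- NULL
  res
}

#' Write motif hits as a BED file
#'
#' BED columns: chrom, start, end, name, score (bits times 100, rounded),
#' strand.
#'
#' @param hits Hit table from [scan_motifs()].
#' @param path Output path.
#' @param name Feature name (default "motif").
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path, name = "motif") {
  lines <- paste(hits$contig, hits$start, hits$end, name,
                 round(hits$score * 100), hits$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
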