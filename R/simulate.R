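#' Simulation configuration
#'
#' Defines the synthetic study: a bacterial genome of polycistronic operons
#' with UTRs, plateau-shaped strand-specific coverage with multiplicative
#' noise, negative-binomial gene counts for two conditions with planted
#' differential-expression effects, two-level functional categories with
#' one enriched category, and cre sites planted in operon promoters.
#' Defaults emulate a ~1,900-gene *Streptococcus thermophilus*-like genome
#' profiled in 2 conditions with 3 replicates each.
#'
#' @param n_genes Number of genes (default 1900).
#' @param operon_size_weights Probability weights over operon sizes 1..K
#'   (default favors singletons with a tail up to 6 genes).
#' @param gene_length_range Gene length interval in bp (default 300-2400).
#' @param intergenic_within_operon Intra-operon gap interval in bp
#'   (default 5-40; transcribed, never zero coverage).
#' @param intergenic_between_operons Inter-operon gap interval in bp
#'   (default 150-400; its minimum must exceed `utr5_len + utr3_len` so a
#'   zero-coverage gap always separates consecutive transcripts).
#' @param utr5_len,utr3_len UTR extents in bp (default 50 each).
#' @param gc_content GC fraction of the random genome (default 0.39,
#'   typical of *S. thermophilus*).
#' @param expression_level_range Per-operon mean level (per-base coverage
#'   and per-replicate count scale), drawn log-uniformly (default 5-500).
#' @param coverage_noise_cv Per-base multiplicative lognormal noise CV on
#'   coverage plateaus (default 0.1).
#' @param nb_dispersion NB dispersion phi of simulated counts (default 0.1).
#' @param n_replicates Replicates per condition (default 3).
#' @param de_fraction Fraction of genes with a planted effect (default
#'   0.07, roughly the DE rate reported for comparable strain pairs).
#' @param de_fold_range Magnitude interval of planted folds (default 2-9).
#' @param n_categories Number of functional categories including the
#'   "hypothetical proteins" group (default 10).
#' @param enriched_category_boost Multiplier on the DE odds of genes in the
#'   designated enriched category (default 10).
#' @param motif_plant_fraction Fraction of operon promoters receiving a
#'   planted cre site (default 0.2).
#' @param motif_offset_range Distance (bp) between a planted site's
#'   downstream edge and the first gene's start (default 20-80).
#' @param contig_flank Untranscribed bp at each contig edge (default 500).
#' @param total_lib_size Target total mapped reads per sample (default 2e6).
#' @param lib_size_cv CV of lognormal library-size factors (default 0.1).
#' @param n_contigs Number of contigs (default 1).
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 1900L,
                       operon_size_weights = c(0.45, 0.2, 0.15, 0.1, 0.06, 0.04),
                       gene_length_range = c(300, 2400),
                       intergenic_within_operon = c(5, 40),
                       intergenic_between_operons = c(150, 400),
                       utr5_len = 50L, utr3_len = 50L,
                       gc_content = 0.39,
                       expression_level_range = c(5, 500),
                       coverage_noise_cv = 0.1,
                       nb_dispersion = 0.1,
                       n_replicates = 3L,
                       de_fraction = 0.07,
                       de_fold_range = c(2, 9),
                       n_categories = 10L,
                       enriched_category_boost = 10,
                       motif_plant_fraction = 0.2,
                       motif_offset_range = c(20, 80),
                       contig_flank = 500L,
                       total_lib_size = 2e6,
                       lib_size_cv = 0.1,
                       n_contigs = 1L,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 1) bail("field 'n_genes' must be a positive integer")
  if (any(cfg$operon_size_weights < 0) || sum(cfg$operon_size_weights) <= 0)
    bail("field 'operon_size_weights' must be non-negative with positive sum")
  check_interval(cfg$gene_length_range, "gene_length_range")
  check_interval(cfg$intergenic_within_operon, "intergenic_within_operon")
  check_interval(cfg$intergenic_between_operons, "intergenic_between_operons")
  check_interval(cfg$expression_level_range, "expression_level_range")
  check_interval(cfg$de_fold_range, "de_fold_range")
  check_interval(cfg$motif_offset_range, "motif_offset_range")
  if (cfg$de_fold_range[1] < 1) bail("field 'de_fold_range' minimum must be >= 1")
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1)
    bail("field 'gc_content' must be in (0, 1)")
  if (cfg$coverage_noise_cv < 0) bail("field 'coverage_noise_cv' must be >= 0")
  if (cfg$nb_dispersion < 0) bail("field 'nb_dispersion' must be >= 0")
  if (cfg$de_fraction < 0 || cfg$de_fraction >= 1)
    bail("field 'de_fraction' must be in [0, 1)")
  if (cfg$n_categories < 2) bail("field 'n_categories' must be >= 2")
  if (cfg$motif_plant_fraction < 0 || cfg$motif_plant_fraction > 1)
    bail("field 'motif_plant_fraction' must be in [0, 1]")
  if (cfg$utr5_len < 0 || cfg$utr3_len < 0)
    bail("field 'utr5_len'/'utr3_len' must be >= 0")
  if (cfg$intergenic_between_operons[1] <= cfg$utr5_len + cfg$utr3_len)
    bail(paste("field 'intergenic_between_operons' minimum must exceed",
               "utr5_len + utr3_len so transcripts stay separated"))
  structure(cfg, class = "sim_config")
}

# SEED-like first-level category names used by the generator.
SEED_LIKE_CATEGORIES <- c(
  "Carbohydrates", "Amino Acids and Derivatives", "Protein Metabolism",
  "DNA Metabolism", "Stress Response", "Cell Wall and Capsule",
  "Cofactors and Vitamins", "Membrane Transport", "RNA Metabolism",
  "Nucleosides and Nucleotides", "Fatty Acids and Lipids", "Respiration",
  "Regulation and Cell Signaling", "Virulence and Defense")

#' Generate a random annotated genome with known operon structure
#'
#' Lays out operons (sizes drawn from `operon_size_weights`, strands
#' independent per operon) along one or more linear contigs, draws gene and
#' intergenic lengths from the configured intervals and fills the sequence
#' with random bases at the configured GC content. Expression levels are
#' drawn log-uniformly per operon and shared by its genes.
#'
#' @param config A [sim_config()].
#' @return A list with `seqs` (named character vector), `ann`
#'   (a [genome_annotation()]) and `truth` (a `ground_truth` list with
#'   `operons`, `gene_level`, and empty slots for categories, DE genes and
#'   planted sites).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sizes <- integer(0)
  while (sum(sizes) < config$n_genes) {
    k <- sample.int(length(config$operon_size_weights), 1,
                    prob = config$operon_size_weights)
    sizes <- c(sizes, k)
  }
  sizes[length(sizes)] <- sizes[length(sizes)] -
    (sum(sizes) - config$n_genes)
  sizes <- sizes[sizes > 0]
  n_op <- length(sizes)
  op_contig <- sort(rep_len(seq_len(config$n_contigs), n_op))
  strands <- sample(c("+", "-"), n_op, replace = TRUE)
  gene_rows <- list()
  operons <- list()
  gene_level <- numeric(0)
  gidx <- 0L
  seqs <- character(0)
  lr <- log(config$expression_level_range)
  for (ctg in seq_len(config$n_contigs)) {
    pos <- config$contig_flank
    ops_here <- which(op_contig == ctg)
    for (oi in ops_here) {
      if (oi != ops_here[1])
        pos <- pos + runif_int(1, config$intergenic_between_operons)
      st <- strands[oi]
      ids <- character(sizes[oi])
      op_start <- pos
      for (j in seq_len(sizes[oi])) {
        if (j > 1) pos <- pos + runif_int(1, config$intergenic_within_operon)
        len <- runif_int(1, config$gene_length_range)
        gidx <- gidx + 1L
        ids[j] <- sprintf("gene_%04d", gidx)
        gene_rows[[gidx]] <- data.frame(
          gene_id = ids[j], contig = sprintf("contig_%d", ctg),
          start = pos, end = pos + len, strand = st,
          stringsAsFactors = FALSE)
        pos <- pos + len
      }
      level <- exp(runif(1, lr[1], lr[2]))
      gene_level[ids] <- level
      tx_ids <- if (st == "+") ids else rev(ids)
      operons[[oi]] <- list(
        operon_id = sprintf("true_operon_%04d", oi),
        genes = tx_ids, contig = sprintf("contig_%d", ctg), strand = st,
        span = c(op_start, pos), level = level)
    }
    L <- pos + config$contig_flank
    gc <- config$gc_content
    seqs[sprintf("contig_%d", ctg)] <- paste(
      sample(DNA_BASES4, L, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
      collapse = "")
  }
  ann <- do.call(rbind, gene_rows)
  ann <- genome_annotation(ann$gene_id, ann$contig, ann$start, ann$end,
                           ann$strand)
  truth <- structure(list(
    operons = operons,
    gene_level = gene_level,
    category_map = NULL, enriched_category = NULL,
    de_genes = NULL, planted_sites = NULL), class = "ground_truth")
  list(seqs = seqs, ann = ann, truth = truth)
}

# transcribed span of a truth operon, 0-based half-open, strand-aware UTRs
operon_tx_span <- function(op, config) {
  if (op$strand == "+")
    c(op$span[1] - config$utr5_len, op$span[2] + config$utr3_len)
  else
    c(op$span[1] - config$utr3_len, op$span[2] + config$utr5_len)
}

#' Assign functional categories and planted DE status
#'
#' Every gene receives exactly one category; a configured share of genes is
#' unannotated and falls into the "hypothetical proteins" group. The first
#' regular category is designated enriched: the DE odds of its genes are
#' multiplied by `enriched_category_boost`. DE genes get fold magnitudes
#' drawn uniformly from `de_fold_range` with random sign (negative = lower
#' in the first condition).
#'
#' @param ann A [genome_annotation()].
#' @param truth Ground truth from [generate_genome()].
#' @param config A [sim_config()].
#' @return The truth with `category_map` (named vector), `enriched_category`
#'   and `de_genes` (data.frame `gene_id`, `fold`) filled in.
#' @export
assign_categories <- function(ann, truth, config) {
  set.seed(config$seed + 1L)
  n_named <- config$n_categories - 1L
  cats <- c(rep_len(SEED_LIKE_CATEGORIES, n_named), "hypothetical proteins")
  w <- c(rep(0.9 / n_named, n_named), 0.1)
  category_map <- setNames(sample(cats, nrow(ann), replace = TRUE, prob = w),
                           ann$gene_id)
  enriched <- cats[1]
  p <- config$de_fraction
  if (p > 0) {
    odds <- p / (1 - p) *
      ifelse(category_map == enriched, config$enriched_category_boost, 1)
    pg <- odds / (1 + odds)
    is_de <- runif(nrow(ann)) < pg
    mag <- runif(sum(is_de), config$de_fold_range[1], config$de_fold_range[2])
    sign <- sample(c(1, -1), sum(is_de), replace = TRUE)
    de <- data.frame(gene_id = ann$gene_id[is_de], fold = mag * sign,
                     stringsAsFactors = FALSE)
  } else {
    de <- data.frame(gene_id = character(), fold = numeric(),
                     stringsAsFactors = FALSE)
  }
  truth$category_map <- category_map
  truth$enriched_category <- enriched
  truth$de_genes <- de
  truth
}

#' Plant motif sites in operon promoters
#'
#' Inserts the given site sequence upstream of the first gene of a random
#' subset of operons (fraction `motif_plant_fraction`), at a distance drawn
#' from `motif_offset_range` between the site's downstream edge and the
#' gene start. Minus-strand operons receive the reverse complement on the
#' plus strand. Promoters too short for the site are skipped with a
#' warning and no site is recorded.
#'
#' @param seqs Named character vector of contig sequences.
#' @param ann A [genome_annotation()].
#' @param truth Ground truth from [generate_genome()].
#' @param config A [sim_config()].
#' @param site Site sequence planted on the operon's strand; defaults to
#'   the canonical cre consensus.
#' @return A list with modified `seqs` and `truth` whose `planted_sites`
#'   data.frame records (contig, start, strand, operon_id).
#' @export
plant_motifs <- function(seqs, ann, truth, config,
                         site = "ATGAAAACGTTTTCAA") {
  set.seed(config$seed + 4L)
  w <- nchar(site)
  sites <- list()
  n_op <- length(truth$operons)
  chosen <- which(runif(n_op) < config$motif_plant_fraction)
  for (oi in chosen) {
    op <- truth$operons[[oi]]
    first <- op$genes[1]
    i <- match(first, ann$gene_id)
    offset <- runif_int(1, config$motif_offset_range)
    if (op$strand == "+") s0 <- ann$start[i] - offset - w
    else s0 <- ann$end[i] + offset
    L <- nchar(seqs[[op$contig]])
    # promoter must fully contain the site inside the contig and clear of
    # the neighboring gene
    a_ct <- ann[ann$contig == op$contig, , drop = FALSE]
    if (op$strand == "+") {
      prev_end <- max(0L, a_ct$end[a_ct$end <= ann$start[i]])
      ok <- s0 >= prev_end && s0 >= 0
    } else {
      next_start <- min(L, a_ct$start[a_ct$start >= ann$end[i]])
      ok <- s0 + w <= next_start && s0 + w <= L
    }
    if (!ok) {
      warning(sprintf("promoter of %s too short for a %d bp site; skipped",
                      op$operon_id, w))
      next
    }
    ins <- if (op$strand == "+") toupper(site) else revcomp(site)
    substr(seqs[[op$contig]], s0 + 1L, s0 + w) <- ins
    sites[[length(sites) + 1]] <- data.frame(
      contig = op$contig, start = s0, strand = op$strand,
      operon_id = op$operon_id, stringsAsFactors = FALSE)
  }
  truth$planted_sites <- if (length(sites)) do.call(rbind, sites)
  else data.frame(contig = character(), start = integer(),
                  strand = character(), operon_id = character(),
                  stringsAsFactors = FALSE)
  list(seqs = seqs, truth = truth)
}

#' Simulate a strand-specific coverage track
#'
#' Each operon's transcript (genes, internal intergenic spans and the
#' configured UTR extensions) gets a plateau at the operon's expression
#' level with independent per-base multiplicative lognormal noise of the
#' configured CV; bases outside every transcribed span have coverage
#' exactly 0.
#'
#' @param ann A [genome_annotation()].
#' @param truth Ground truth from [generate_genome()].
#' @param config A [sim_config()].
#' @param contig_lengths Named contig lengths; inferred from the annotation
#'   plus `contig_flank` when omitted and no sequence is at hand.
#' @return A [coverage_track()].
#' @export
simulate_coverage <- function(ann, truth, config, contig_lengths = NULL) {
  set.seed(config$seed + 2L)
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(split(ann$end, ann$contig), max, 1L) +
      config$contig_flank
  }
  trk <- coverage_track(contig_lengths)
  sdlog <- sqrt(log(1 + config$coverage_noise_cv^2))
  for (op in truth$operons) {
    span <- operon_tx_span(op, config)
    span[1] <- max(span[1], 0L)
    span[2] <- min(span[2], contig_lengths[[op$contig]])
    n <- span[2] - span[1]
    noise <- if (config$coverage_noise_cv == 0) rep(1, n)
    else rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    st <- track_strand(op$strand)
    trk[[op$contig]][[st]][(span[1] + 1L):span[2]] <- op$level * noise
  }
  trk
}

#' Simulate a two-condition count matrix
#'
#' Per-gene, per-sample counts are negative-binomial with mean
#' `level_g * lib_factor_s * fold`, where the signed planted fold from the
#' ground truth raises the first condition (positive sign) or the second
#' (negative sign), and dispersion `nb_dispersion` (Poisson when 0).
#' Library factors are lognormal around 1 with CV `lib_size_cv`; reported
#' library sizes are `total_lib_size` scaled by the factors.
#'
#' @param ann A [genome_annotation()].
#' @param truth Ground truth; when its `de_genes` slot is NULL (i.e.
#'   [assign_categories()] was not run) DE genes are drawn here uniformly
#'   at rate `de_fraction`.
#' @param config A [sim_config()].
#' @return A list with `counts` (a [count_matrix()], conditions "A" and
#'   "B") and the possibly updated `truth`.
#' @export
simulate_counts <- function(ann, truth, config) {
  set.seed(config$seed + 3L)
  if (is.null(truth$de_genes)) {
    if (config$de_fraction > 0) {
      is_de <- runif(nrow(ann)) < config$de_fraction
      mag <- runif(sum(is_de), config$de_fold_range[1], config$de_fold_range[2])
      sgn <- sample(c(1, -1), sum(is_de), replace = TRUE)
      truth$de_genes <- data.frame(gene_id = ann$gene_id[is_de],
                                   fold = mag * sgn, stringsAsFactors = FALSE)
    } else {
      truth$de_genes <- data.frame(gene_id = character(), fold = numeric(),
                                   stringsAsFactors = FALSE)
    }
  }
  n_rep <- config$n_replicates
  n_s <- 2L * n_rep
  condition <- rep(c("A", "B"), each = n_rep)
  sample_ids <- paste0(condition, "_", rep(seq_len(n_rep), 2))
  sdlog <- sqrt(log(1 + config$lib_size_cv^2))
  lib_factor <- rlnorm(n_s, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  lib_size <- round(config$total_lib_size * lib_factor)
  level <- truth$gene_level[ann$gene_id]
  foldA <- rep(1, nrow(ann)); foldB <- rep(1, nrow(ann))
  if (nrow(truth$de_genes)) {
    idx <- match(truth$de_genes$gene_id, ann$gene_id)
    up <- truth$de_genes$fold > 0
    foldA[idx[up]] <- truth$de_genes$fold[up]
    foldB[idx[!up]] <- -truth$de_genes$fold[!up]
  }
  counts <- matrix(0L, nrow(ann), n_s,
                   dimnames = list(ann$gene_id, sample_ids))
  for (s in seq_len(n_s)) {
    mu <- level * lib_factor[s] * (if (condition[s] == "A") foldA else foldB)
    counts[, s] <- if (config$nb_dispersion == 0) rpois(nrow(ann), mu)
    else rnbinom(nrow(ann), size = 1 / config$nb_dispersion, mu = mu)
  }
  list(counts = count_matrix(counts, lib_size, condition), truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_genome()], [assign_categories()], [plant_motifs()],
#' [simulate_coverage()] and [simulate_counts()] in order and collects the
#' results. Fully deterministic given the config's seed.
#'
#' @param config A [sim_config()].
#' @param site Planted site sequence (see [plant_motifs()]); NULL disables
#'   planting.
#' @return A list: `seqs`, `ann` (with categories filled in), `truth`,
#'   `track`, `counts`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             site = "ATGAAAACGTTTTCAA") {
  g <- generate_genome(config)
  truth <- assign_categories(g$ann, g$truth, config)
  seqs <- g$seqs
  if (!is.null(site) && config$motif_plant_fraction > 0) {
    pm <- plant_motifs(seqs, g$ann, truth, config, site = site)
    seqs <- pm$seqs; truth <- pm$truth
  } else {
    truth$planted_sites <- data.frame(contig = character(), start = integer(),
                                      strand = character(),
                                      operon_id = character(),
                                      stringsAsFactors = FALSE)
  }
  track <- simulate_coverage(g$ann, truth, config,
                             setNames(nchar(seqs), names(seqs)))
  sc <- simulate_counts(g$ann, truth, config)
  ann <- g$ann
  ann$category <- unname(truth$category_map[ann$gene_id])
  list(seqs = seqs, ann = ann, truth = sc$truth, track = track,
       counts = sc$counts, config = config)
}

#' Write ground truth to a YAML file
#'
#' @param truth A `ground_truth` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- list(
    operons = lapply(truth$operons, function(o)
      list(operon_id = o$operon_id, genes = as.list(o$genes),
           contig = o$contig, strand = o$strand,
           span = as.list(o$span), level = o$level)),
    gene_level = as.list(truth$gene_level),
    category_map = as.list(truth$category_map),
    enriched_category = truth$enriched_category,
    de_genes = if (!is.null(truth$de_genes))
      list(gene_id = as.list(truth$de_genes$gene_id),
           fold = as.list(truth$de_genes$fold)),
    planted_sites = if (!is.null(truth$planted_sites))
      lapply(seq_len(nrow(truth$planted_sites)), function(i)
        as.list(truth$planted_sites[i, ])))
  yaml::write_yaml(out, path)
  invisible(path)
}
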