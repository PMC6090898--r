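small_cfg <- function(...) sim_config(n_genes = 60L, seed = 42L, ...)

test_that("generated genomes have the requested gene count and layout", {
  ds <- generate_genome(small_cfg())
  expect_equal(nrow(ds$ann), 60)
  expect_true(all(diff(ds$ann$start) > 0))
  expect_true(all(ds$ann$end > ds$ann$start))
  # operon partition covers all genes exactly once
  genes <- sort(unlist(lapply(ds$truth$operons, `[[`, "genes")))
  expect_identical(genes, sort(ds$ann$gene_id))
  # gene order inside sequence bounds
  expect_true(max(ds$ann$end) <= nchar(ds$seqs[[1]]))
})

test_that("the generator is byte-deterministic under a fixed seed", {
  a <- simulate_dataset(small_cfg())
  b <- simulate_dataset(small_cfg())
  expect_identical(a$seqs, b$seqs)
  expect_identical(a$ann, b$ann)
  expect_identical(a$truth, b$truth)
  expect_identical(a$track, b$track)
  expect_identical(a$counts$counts, b$counts$counts)
})

test_that("genome GC content matches the configured fraction", {
  ds <- generate_genome(sim_config(n_genes = 120, gc_content = 0.4, seed = 3))
  s <- ds$seqs[[1]]
  expect_gt(nchar(s), 50000)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
  expect_lt(abs(gc - 0.4), 0.02)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(gene_length_range = c(100, 50)), "gene_length_range")
  expect_error(sim_config(gc_content = 1.2), "gc_content")
  expect_error(sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(sim_config(de_fold_range = c(0.5, 3)), "de_fold_range")
})

test_that("motif planting writes the site at the recorded coordinates", {
  cfg <- small_cfg(motif_plant_fraction = 1)
  g <- generate_genome(cfg)
  pm <- plant_motifs(g$seqs, g$ann, g$truth, cfg)
  sites <- pm$truth$planted_sites
  expect_gt(nrow(sites), 0)
  for (i in seq_len(nrow(sites))) {
    sub <- substring(pm$seqs[[sites$contig[i]]],
                     sites$start[i] + 1, sites$start[i] + 16)
    if (sites$strand[i] == "+") expect_identical(sub, "ATGAAAACGTTTTCAA")
    else expect_identical(sub, revcomp("ATGAAAACGTTTTCAA"))
  }
  # reverse complement spelled out: the minus-strand insert
  expect_identical(revcomp("ATGAAAACGTTTTCAA"), "TTGAAAACGTTTTCAT")
  # sequence differs from the input only at planted spans
  diffpos <- which(strsplit(pm$seqs[[1]], "")[[1]] !=
                   strsplit(g$seqs[[1]], "")[[1]])
  inside <- unlist(lapply(seq_len(nrow(sites)), function(i)
    (sites$start[i] + 1):(sites$start[i] + 16)))
  expect_true(all(diffpos %in% inside))
})

test_that("plant_fraction 0 leaves the sequence untouched", {
  cfg <- small_cfg(motif_plant_fraction = 0)
  g <- generate_genome(cfg)
  pm <- plant_motifs(g$seqs, g$ann, g$truth, cfg)
  expect_identical(pm$seqs, g$seqs)
  expect_equal(nrow(pm$truth$planted_sites), 0)
})

test_that("noiseless coverage is an exact plateau with strand-aware UTRs", {
  cfg <- small_cfg(coverage_noise_cv = 0, utr5_len = 50L, utr3_len = 20L)
  g <- generate_genome(cfg)
  trk <- simulate_coverage(g$ann, g$truth, cfg)
  for (op in g$truth$operons[1:5]) {
    first <- op$genes[1]
    i <- match(first, g$ann$gene_id)
    v <- trk[[op$contig]][[if (op$strand == "+") "plus" else "minus"]]
    if (op$strand == "+") {
      expect_equal(v[(g$ann$start[i] - 49):(g$ann$start[i])],
                   rep(op$level, 50))
      expect_equal(v[g$ann$start[i] - 50], 0)
    } else {
      expect_equal(v[(g$ann$end[i] + 1):(g$ann$end[i] + 50)],
                   rep(op$level, 50))
      expect_equal(v[g$ann$end[i] + 51], 0)
    }
  }
  # zero outside union of transcribed spans
  spans <- lapply(g$truth$operons, function(op) {
    s <- if (op$strand == "+") c(op$span[1] - 50, op$span[2] + 20)
    else c(op$span[1] - 20, op$span[2] + 50)
    cbind(s[1], s[2], op$strand)
  })
  v <- trk[[1]]$plus + trk[[1]]$minus
  covered <- rep(FALSE, length(v))
  for (sp in spans) covered[(as.numeric(sp[1]) + 1):as.numeric(sp[2])] <- TRUE
  expect_true(all(v[!covered] == 0))
  expect_true(all(v[covered] > 0))
})

test_that("coverage noise attains the configured coefficient of variation", {
  cfg <- sim_config(n_genes = 12, gene_length_range = c(5000, 5000),
                    operon_size_weights = c(0, 1), coverage_noise_cv = 0.1,
                    seed = 5)
  g <- generate_genome(cfg)
  trk <- simulate_coverage(g$ann, g$truth, cfg)
  op <- g$truth$operons[[1]]
  v <- trk[[op$contig]][[if (op$strand == "+") "plus" else "minus"]]
  x <- v[(op$span[1] + 1):op$span[2]]
  cv <- sd(x) / mean(x)
  expect_gt(cv, 0.08); expect_lt(cv, 0.12)
  expect_equal(mean(x), op$level, tolerance = 0.02)
})

test_that("counts follow the Poisson limit when dispersion is zero", {
  cfg <- sim_config(n_genes = 10000, nb_dispersion = 0, de_fraction = 0,
                    expression_level_range = c(100, 100), lib_size_cv = 0,
                    seed = 8)
  g <- generate_genome(cfg)
  sc <- simulate_counts(g$ann, g$truth, cfg)
  expect_equal(nrow(sc$truth$de_genes), 0)
  x <- sc$counts$counts[, 1]
  expect_gt(var(x) / mean(x), 0.95)
  expect_lt(var(x) / mean(x), 1.05)
  expect_true(all(sc$counts$counts >= 0))
})

test_that("category assignment partitions genes and boosts DE odds", {
  cfg <- small_cfg(n_categories = 5)
  g <- generate_genome(cfg)
  truth <- assign_categories(g$ann, g$truth, cfg)
  expect_equal(length(truth$category_map), 60)
  expect_equal(sum(table(truth$category_map)), 60)
  expect_true(all(g$ann$gene_id %in% names(truth$category_map)))
  # boosted enriched category has a higher DE rate than the rest in
  # nearly all seeded runs
  hits <- 0
  for (s in 1:40) {
    cfg2 <- sim_config(n_genes = 400, seed = s, de_fraction = 0.1,
                       enriched_category_boost = 10)
    gg <- generate_genome(cfg2)
    tt <- assign_categories(gg$ann, gg$truth, cfg2)
    enr <- names(tt$category_map)[tt$category_map == tt$enriched_category]
    rate_in <- mean(enr %in% tt$de_genes$gene_id)
    rate_all <- nrow(tt$de_genes) / 400
    hits <- hits + (rate_in > rate_all)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("non-DE genes have equal expected counts across conditions", {
  cfg <- sim_config(n_genes = 200, n_replicates = 50, de_fraction = 0.1,
                    lib_size_cv = 0, seed = 13)
  g <- generate_genome(cfg)
  sc <- simulate_counts(g$ann, g$truth, cfg)
  cm <- sc$counts
  non_de <- setdiff(rownames(cm$counts), sc$truth$de_genes$gene_id)
  A <- cm$counts[non_de, cm$condition == "A", drop = FALSE]
  B <- cm$counts[non_de, cm$condition == "B", drop = FALSE]
  dm <- rowMeans(A) - rowMeans(B)
  se <- sqrt(apply(A, 1, var) / 50 + apply(B, 1, var) / 50)
  expect_gt(mean(abs(dm) < 3 * se), 0.98)
})
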