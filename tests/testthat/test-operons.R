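test_that("gene mean coverage equals the per-base arithmetic mean", {
  ann <- genome_annotation(c("a", "b"), "c1", c(0, 10), c(4, 12), c("+", "-"))
  trk <- tiny_track(plus = c(7, 7, 7, 7, rep(0, 16)),
                    minus = c(rep(0, 10), 2, 4, rep(0, 8)))
  cov <- gene_mean_coverage(trk, ann)
  expect_equal(cov[["a"]], 7)
  expect_equal(cov[["b"]], 3)
  # random genes against direct summation
  withr::local_seed(2)
  L <- 2000L
  trk2 <- tiny_track(plus = runif(L) * 10, minus = runif(L) * 10)
  starts <- seq(0, 1900, by = 38)[1:50]
  ann2 <- genome_annotation(sprintf("r%02d", 1:50), "c1", starts,
                            starts + 30L, sample(c("+", "-"), 50, TRUE))
  cov2 <- gene_mean_coverage(trk2, ann2)
  for (i in 1:50) {
    v <- trk2$c1[[if (ann2$strand[i] == "+") "plus" else "minus"]]
    expect_equal(cov2[[ann2$gene_id[i]]],
                 sum(v[(ann2$start[i] + 1):ann2$end[i]]) / 30,
                 tolerance = 1e-12)
  }
})

test_that("neighbor log ratios cover adjacent same-strand pairs", {
  ann <- grid_ann(4)
  cov <- setNames(c(100, 100, 25, 0), ann$gene_id)
  r <- neighbor_log_ratios(cov, ann)
  expect_equal(nrow(r), 2)  # pair with zero coverage omitted
  expect_equal(r$ratio, c(0, 2))
  # mixed strands: count equals adjacent same-strand positive pairs
  withr::local_seed(6)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    ann2 <- grid_ann(n, strand = sample(c("+", "-"), n, TRUE))
    cov2 <- setNames(sample(c(0, 5, 50, 500), n, TRUE), ann2$gene_id)
    expected <- sum(vapply(seq_len(n - 1), function(i)
      ann2$strand[i] == ann2$strand[i + 1] &&
        cov2[i] > 0 && cov2[i + 1] > 0, logical(1)))
    expect_equal(nrow(neighbor_log_ratios(cov2, ann2)), expected)
  }
})

test_that("simple merge and singleton cases behave as published rules", {
  # single gene -> one singleton operon
  ann1 <- grid_ann(1)
  trk1 <- plateau_track(ann1, 10)
  ops1 <- reconstruct_operons(gene_mean_coverage(trk1, ann1), ann1, trk1)
  expect_length(ops1, 1)
  expect_equal(ops1[[1]]$genes, "g01")
  # two equal-coverage adjacent genes with covered gap merge (r = 0 < sd)
  ann <- grid_ann(6)
  lev <- c(100, 100, 10, 300, 40, 7)
  trk <- plateau_track(ann, lev)
  # break coverage between genes 2 and 3 so sd comes from ratios but the
  # first pair merges
  trk$c1$plus[(ann$end[2] + 1):ann$start[3]] <- 0
  cov <- gene_mean_coverage(trk, ann)
  ops <- reconstruct_operons(cov, ann, trk)
  first <- ops[[which(vapply(ops, function(o) "g01" %in% o$genes, TRUE))]]
  expect_true(all(c("g01", "g02") %in% first$genes))
})

test_that("planted operon layouts are recovered exactly without noise", {
  cfg <- sim_config(n_genes = 60, coverage_noise_cv = 0, seed = 21)
  ds <- simulate_dataset(cfg)
  cov <- gene_mean_coverage(ds$track, ds$ann)
  ops <- reconstruct_operons(cov, ds$ann, ds$track)
  rec <- canon_partition(lapply(ops, `[[`, "genes"))
  tru <- canon_partition(lapply(ds$truth$operons, `[[`, "genes"))
  expect_identical(rec, tru)
})

test_that("reconstruction matches the brute-force rule oracle", {
  withr::local_seed(31)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    strand <- sample(c("+", "-"), n, TRUE)
    ann <- grid_ann(n, strand = strand)
    lev <- round(exp(runif(n, log(0.5), log(400))), 2)
    trk <- plateau_track(ann, lev)
    # randomly zero some intergenic spans
    for (i in seq_len(n - 1)) {
      if (runif(1) < 0.4) {
        st <- if (ann$strand[i] == "+") "plus" else "minus"
        trk$c1[[st]][(ann$end[i] + 1):ann$start[i + 1]] <- 0
      }
    }
    cov <- gene_mean_coverage(trk, ann)
    ops <- reconstruct_operons(cov, ann, trk)
    rec <- canon_partition(lapply(ops, `[[`, "genes"))
    orc <- canon_partition(oracle_operon_partition(cov, ann, trk))
    expect_identical(rec, orc)
  }
})

test_that("low-coverage genes are excluded and break adjacency", {
  ann <- grid_ann(3)
  trk <- plateau_track(ann, c(100, 1.5, 100))
  cov <- gene_mean_coverage(trk, ann)
  ops <- reconstruct_operons(cov, ann, trk)
  members <- unlist(lapply(ops, `[[`, "genes"))
  expect_false("g02" %in% members)
  excl <- attr(ops, "low_coverage_excluded")
  expect_equal(excl$gene_id, "g02")
  # flanking genes do not merge across the excluded one
  expect_true(all(vapply(ops, function(o) length(o$genes) == 1, TRUE)))
})

test_that("raising the sd multiplier never shrinks operons", {
  withr::local_seed(17)
  for (rep in 1:10) {
    n <- 8
    ann <- grid_ann(n)
    lev <- round(exp(runif(n, log(3), log(300))), 2)
    trk <- plateau_track(ann, lev)
    cov <- gene_mean_coverage(trk, ann)
    sizes <- function(m) {
      ops <- reconstruct_operons(cov, ann, trk,
                                 boundary_params(sd_multiplier = m))
      sort(vapply(ops, function(o) length(o$genes), 1L))
    }
    expect_lte(length(sizes(2)), length(sizes(1)))
    expect_lte(length(sizes(5)), length(sizes(2)))
  }
})

test_that("transcript boundaries follow the coverage plateau edges", {
  # noiseless plateau extending 50 bp upstream
  ann <- grid_ann(1, offset = 100L)
  trk <- plateau_track(ann, 80)
  trk$c1$plus[(ann$start[1] - 50 + 1):ann$start[1]] <- 80
  cov <- gene_mean_coverage(trk, ann)
  op <- reconstruct_operons(cov, ann, trk)[[1]]
  op <- detect_transcript_boundaries(trk, op, cov, ann)
  expect_equal(op$utr5_len, 50)
  expect_equal(op$tss, ann$start[1] - 50)
  expect_equal(op$utr3_len, 0)
  expect_equal(op$tts, ann$end[1] - 1)
  # zero coverage immediately upstream -> utr5 = 0
  trk2 <- plateau_track(ann, 80)
  op2 <- reconstruct_operons(cov, ann, trk2)[[1]]
  op2 <- detect_transcript_boundaries(trk2, op2, cov, ann)
  expect_equal(op2$utr5_len, 0)
  expect_equal(op2$tss, ann$start[1])
})

test_that("UTR lengths are recovered within 5 bp under mild noise", {
  # the merge rule calibrates sigma_r on genome-wide neighbor ratios, so the
  # genome must hold enough cross-operon pairs for the population to be
  # representative; very small genomes split true operons spuriously
  ok <- 0; total <- 0
  for (s in 1:8) {
    cfg <- sim_config(n_genes = 40, coverage_noise_cv = 0.05,
                      utr5_len = 50L, utr3_len = 50L, seed = 100 + s)
    ds <- simulate_dataset(cfg, site = NULL)
    cov <- gene_mean_coverage(ds$track, ds$ann)
    ops <- reconstruct_transcripts(cov, ds$ann, ds$track)
    for (o in ops) {
      total <- total + 2
      ok <- ok + (abs(o$utr5_len - 50) <= 5) + (abs(o$utr3_len - 50) <= 5)
    }
  }
  expect_gte(ok / total, 0.95)
})
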