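test_that("IUPAC columns follow the smoothing formula", {
  expect_equal(unname(pwm_from_iupac("A", gamma = 0)$prob[1, ]),
               c(1, 0, 0, 0))
  expect_equal(unname(pwm_from_iupac("N", gamma = 0.5)$prob[1, ]),
               rep(0.25, 4))
  expect_equal(unname(pwm_from_iupac("W", gamma = 0.04)$prob[1, ]),
               c(0.48, 0.02, 0.02, 0.48))
  expect_error(pwm_from_iupac("AXT"), "invalid IUPAC code 'X' at position 2")
  # consensus weighting keeps the simplex and favors the consensus base
  x <- pwm_from_iupac("W", consensus = "T", consensus_weight = 0.7)
  expect_equal(unname(x$prob[1, ]), c(0.96 * 0.3, 0.02, 0.02, 0.96 * 0.7))
  expect_error(pwm_from_iupac("W", consensus = "G"), "not in allowed set")
})

test_that("log-odds scoring matches the formula and skips N windows", {
  x <- pwm_from_iupac("A", gamma = 0.04)
  sc <- logodds_scores(x, c(s = "ATNA"))
  expect_equal(sc$s$plus[1], log2(0.96 / 0.25), tolerance = 1e-12)
  expect_true(is.na(sc$s$plus[3]))  # window on N
  # uniform PWM scores 0 everywhere
  u <- pwm(matrix(0.25, 3, 4))
  expect_equal(logodds_scores(u, c(s = "ACGTT"))$s$plus, rep(0, 3))
})

test_that("minus-strand scores equal plus-strand scores of the reverse complement", {
  withr::local_seed(12)
  for (rep in 1:10) {
    x <- random_pwm(4)
    s <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    sc <- logodds_scores(x, c(fwd = s))
    sc_rc <- logodds_scores(x, c(rc = revcomp(s)))
    expect_equal(sc$fwd$minus, rev(sc_rc$rc$plus), tolerance = 1e-9)
  }
})

test_that("the score-distribution DP matches exhaustive enumeration", {
  withr::local_seed(33)
  for (w in c(3, 5, 8)) {
    x <- random_pwm(w)
    dist <- score_distribution(x, lattice_bins = 20000)
    oracle <- oracle_pwm_tail(x)
    # attained scores (order statistics): the queries scanning performs
    qs <- quantile(oracle$scores, c(0.05, 0.25, 0.5, 0.75, 0.9, 0.99, 1),
                   type = 1)
    for (s in qs) {
      p_true <- oracle$tail(s)
      p_dp <- pwm_pvalue(dist, s)
      expect_gte(p_dp, p_true * (1 - 1e-9))  # conservative, never below
      if (p_true >= 1e-5)
        expect_lt(abs(p_dp - p_true) / p_true, 0.01)
    }
  }
})

test_that("the null score tail is a proper non-increasing survival curve", {
  withr::local_seed(44)
  for (rep in 1:20) {
    x <- random_pwm(sample(2:10, 1))
    d <- score_distribution(x, 500)
    expect_true(all(diff(d$tail) <= 1e-12))
    expect_equal(d$tail[1], 1, tolerance = 1e-9)
    expect_equal(pwm_pvalue(d, d$min_total - 1), 1)
    expect_equal(pwm_pvalue(d, d$max_total + 1), 0)
  }
  # width-1 "A" motif: only A attains the maximum
  xa <- pwm_from_iupac("A", gamma = 0.04)
  da <- score_distribution(xa)
  expect_equal(pwm_pvalue(da, log2(0.96 / 0.25)), 0.25, tolerance = 1e-9)
})

test_that("scanning reports all windows when the threshold is disabled", {
  withr::local_seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  x <- random_pwm(6)
  hits <- scan_motifs(x, c(c1 = s), scan_config(p_threshold = 1),
                      background = "uniform")
  expect_equal(nrow(hits), 2 * (300 - 6 + 1))
  # all-N sequence gives no hit
  hits_n <- scan_motifs(x, c(c1 = strrep("N", 100)),
                        scan_config(p_threshold = 1), background = "uniform")
  expect_equal(nrow(hits_n), 0)
})

test_that("hit sets grow monotonically with the p-value threshold", {
  withr::local_seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  x <- cre_pwm()
  key <- function(h) paste(h$contig, h$start, h$strand)
  h1 <- scan_motifs(x, c(c1 = s), scan_config(p_threshold = 1e-4))
  h2 <- scan_motifs(x, c(c1 = s), scan_config(p_threshold = 1e-2))
  expect_true(all(key(h1) %in% key(h2)))
})

test_that("a planted cre consensus is recovered from random background", {
  withr::local_seed(55)
  x <- cre_pwm()
  for (rep in 1:5) {
    bgs <- paste(sample(c("A", "C", "G", "T"), 50000, TRUE), collapse = "")
    pos <- sample(1000:48000, 1)
    substr(bgs, pos, pos + 15) <- "ATGAAAACGTTTTCAA"
    hits <- scan_motifs(x, c(c1 = bgs))
    expect_true(any(hits$start == pos - 1 & hits$strand == "+"))
    expect_true(all(hits$pvalue < 1e-6))
  }
})

test_that("scanning the reverse-complemented genome mirrors hits", {
  withr::local_seed(66)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  x <- random_pwm(5)
  cfgr <- scan_config(p_threshold = 1e-2)
  h1 <- scan_motifs(x, c(c1 = s), cfgr, background = "uniform")
  h2 <- scan_motifs(x, c(c1 = revcomp(s)), cfgr, background = "uniform")
  L <- 2000
  mirrored <- data.frame(start = L - h2$end, strand = ifelse(h2$strand == "+", "-", "+"))
  k1 <- sort(paste(h1$start, h1$strand))
  k2 <- sort(paste(mirrored$start, mirrored$strand))
  expect_identical(k1, k2)
})

test_that("hits are assigned to promoters within the window rule", {
  ann <- genome_annotation(c("gp", "gm"), "c1", c(500, 40), c(800, 140),
                           c("+", "-"))
  hit <- function(st0) data.frame(contig = "c1", start = st0, end = st0 + 16,
                                  strand = "+", seq = "X", score = 1,
                                  pvalue = 1e-8, stringsAsFactors = FALSE)
  # 100 bp upstream of plus gene start (gene start 500, hit end 400)
  a1 <- assign_hits_to_genes(hit(384), ann, scan_config(promoter_window = 300))
  expect_true("gp" %in% a1$gene_id)
  expect_equal(a1$distance[a1$gene_id == "gp"], 100)
  # 400 bp upstream: outside the window
  a2 <- assign_hits_to_genes(hit(84), ann, scan_config(promoter_window = 300))
  expect_false("gp" %in% a2$gene_id)
  # between divergent genes: assigned to both
  a3 <- assign_hits_to_genes(hit(250), ann, scan_config(promoter_window = 300))
  expect_setequal(na.omit(a3$gene_id), c("gp", "gm"))
})

test_that("expected false-positive counts track the threshold on random DNA", {
  withr::local_seed(77)
  x <- cre_pwm()
  L <- 3e5
  s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  thr <- 1e-4
  hits <- scan_motifs(x, c(c1 = s), scan_config(p_threshold = thr),
                      background = "uniform")
  expected <- 2 * L * thr
  expect_gt(nrow(hits), expected / 2)
  expect_lt(nrow(hits), expected * 2)
})
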