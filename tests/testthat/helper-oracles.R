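# Independent reference implementations used as oracles. Each deliberately
# recomputes its quantity by a different route than the package.

# Brute-force operon partition: enumerate every segmentation of the
# coverage-retained genes of a contig (2^(n-1) boundary vectors) and keep
# the one consistent with the three rules applied pairwise:
#   merge iff same strand, directly adjacent in full gene order,
#   |log2 ratio| < sd_mult * sigma, and no zero-coverage intergenic base.
oracle_operon_partition <- function(cov, ann, trk, min_cov = 2,
                                    sd_mult = 1) {
  ord <- order(ann$contig, ann$start)
  ann <- ann[ord, , drop = FALSE]
  # sigma from all adjacent same-strand retained pairs with positive coverage
  ratios <- c()
  for (ct in unique(ann$contig)) {
    g <- ann[ann$contig == ct, , drop = FALSE]
    if (nrow(g) < 2) next
    for (i in 2:nrow(g)) {
      a <- g$gene_id[i - 1]; b <- g$gene_id[i]
      if (g$strand[i - 1] != g$strand[i]) next
      if (cov[a] < min_cov || cov[b] < min_cov) next
      if (cov[a] <= 0 || cov[b] <= 0) next
      ratios <- c(ratios, log2(cov[a] / cov[b]))
    }
  }
  n_r <- length(ratios)
  sigma <- if (n_r >= 1) sqrt(mean((ratios - mean(ratios))^2)) else NA
  pair_merge <- function(g, i) {
    # may genes i-1 and i of contig table g share an operon?
    a <- g$gene_id[i - 1]; b <- g$gene_id[i]
    if (g$strand[i - 1] != g$strand[i]) return(FALSE)
    if (cov[a] < min_cov || cov[b] < min_cov) return(FALSE)
    if (cov[a] <= 0 || cov[b] <= 0) return(FALSE)
    r <- log2(cov[a] / cov[b])
    ok <- if (is.na(sigma)) FALSE
    else if (sigma == 0) r == 0 else abs(r) < sd_mult * sigma
    if (!ok) return(FALSE)
    lo <- g$end[i - 1]; hi <- g$start[i]
    if (hi > lo) {
      v <- trk[[g$contig[i]]][[if (g$strand[i] == "+") "plus" else "minus"]]
      if (any(v[(lo + 1):hi] == 0)) return(FALSE)
    }
    TRUE
  }
  parts <- list()
  for (ct in unique(ann$contig)) {
    g <- ann[ann$contig == ct, , drop = FALSE]
    keep <- cov[g$gene_id] >= min_cov
    gk <- g[keep, , drop = FALSE]
    n <- nrow(gk)
    if (n == 0) next
    if (n == 1) { parts[[length(parts) + 1]] <- gk$gene_id; next }
    # merge decision between retained genes k and k+1 (in retained order):
    # they must be directly adjacent in the full order too
    idx_full <- match(gk$gene_id, g$gene_id)
    can <- vapply(seq_len(n - 1), function(k) {
      idx_full[k + 1] == idx_full[k] + 1 && pair_merge(g, idx_full[k + 1])
    }, logical(1))
    # enumerate all boundary vectors; valid iff boundary at k <=> !can[k]
    best <- NULL
    for (mask in 0:(2^(n - 1) - 1)) {
      bnd <- as.logical(bitwAnd(mask, 2^(0:(n - 2))) > 0)
      if (all(bnd == !can)) { best <- bnd; break }
    }
    grp <- cumsum(c(TRUE, best))
    for (k in unique(grp))
      parts[[length(parts) + 1]] <- gk$gene_id[grp == k]
  }
  lapply(parts, sort)
}

# canonical form of a partition (list of sorted gene-id vectors)
canon_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, `[`, "", 1))]
}

# Exact conditional NB test by direct convolution of per-replicate pmfs.
oracle_nb_exact_p <- function(yA_reps, yB_reps, phi) {
  T <- sum(yA_reps) + sum(yB_reps)
  mu <- T / (length(yA_reps) + length(yB_reps))
  rep_pmf <- function() {
    if (phi < 1e-12) dpois(0:T, mu) else dnbinom(0:T, size = 1 / phi, mu = mu)
  }
  conv_n <- function(n) {
    p <- c(1, rep(0, T))
    single <- rep_pmf()
    for (i in seq_len(n)) {
      np <- rep(0, T + 1)
      for (y in 0:T) if (p[y + 1] > 0)
        np[(y + 1):(T + 1)] <- np[(y + 1):(T + 1)] +
          p[y + 1] * single[1:(T + 1 - y)]
      p <- np
    }
    p
  }
  pA <- conv_n(length(yA_reps)); pB <- conv_n(length(yB_reps))
  joint <- pA * rev(pB)  # P(YA = y) * P(YB = T - y)
  joint <- joint / sum(joint)
  pobs <- joint[sum(yA_reps) + 1]
  sum(joint[joint <= pobs * (1 + 1e-12)])
}

# Exhaustive PWM score tail: enumerate all 4^w sequences.
oracle_pwm_tail <- function(x) {
  lo <- log2(sweep(x$prob, 2, x$background, "/"))
  scores <- 0; probs <- 1
  for (i in seq_len(nrow(lo))) {
    scores <- as.vector(outer(scores, lo[i, ], "+"))
    probs <- as.vector(outer(probs, x$background, "*"))
  }
  list(scores = scores, probs = probs,
       tail = function(s) sum(probs[scores >= s - 1e-12]))
}

# random PWM with strictly positive entries
random_pwm <- function(w, conc = 1) {
  m <- matrix(rgamma(4 * w, conc) + 1e-3, nrow = w)
  pwm(m / rowSums(m))
}

# small hand-built coverage track from per-base vectors
tiny_track <- function(plus, minus = NULL, contig = "c1") {
  if (is.null(minus)) minus <- numeric(length(plus))
  trk <- coverage_track(setNames(length(plus), contig))
  trk[[contig]]$plus <- as.numeric(plus)
  trk[[contig]]$minus <- as.numeric(minus)
  trk
}
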