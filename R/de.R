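#' RPKM normalization
#'
#' Reads per kilobase of gene per million mapped reads:
#' `RPKM = c * 1e9 / (L * N)` with `c` the mapped read count, `L` the gene
#' length in bp and `N` the sample library size.
#'
#' @param cm A [count_matrix()].
#' @param ann A [genome_annotation()] providing gene lengths.
#' @return Numeric matrix of RPKM values, same dimnames as the counts.
#' @export
compute_rpkm <- function(cm, ann) {
  genes <- rownames(cm$counts)
  missing <- setdiff(genes, ann$gene_id)
  if (length(missing)) bail("gene '%s' has no annotated length", missing[1])
  L <- ann$length_bp[match(genes, ann$gene_id)]
  if (any(L <= 0)) bail("non-positive gene length")
  if (any(cm$lib_size <= 0)) bail("library size must be positive")
  sweep(cm$counts * 1e9 / L, 2, cm$lib_size, "/")
}

row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Estimate negative-binomial dispersions
#'
#' Per-gene method-of-moments dispersion on library-size-normalized counts
#' within each condition, `phi_hat = max(0, (s^2 - m) / m^2)` (conditions
#' pooled by residual degrees of freedom), a common dispersion as the
#' 10%-per-tail trimmed mean of the per-gene estimates, and tagwise values
#' shrunk toward the common one:
#' `phi_g = (prior_df * phi0 + df_g * phi_hat_g) / (prior_df + df_g)`.
#'
#' @param cm A [count_matrix()].
#' @param prior_df Shrinkage weight of the common dispersion (default 10);
#'   as `prior_df` grows every tagwise value approaches the common one.
#' @param trim Fraction trimmed from each tail of the per-gene estimates
#'   when forming the common dispersion (default 0.1).
#' @param fallback Common dispersion returned (with a warning) when no
#'   condition has replication (default 0.1).
#' @return A list with `common` (phi0), `tagwise` (named per-gene vector),
#'   `per_gene` (unshrunk estimates), `prior_df`, `residual_df`.
#' @export
estimate_dispersions <- function(cm, prior_df = 10, trim = 0.1,
                                 fallback = 0.1) {
  conds <- unique(cm$condition)
  f <- cm$lib_size / exp(mean(log(cm$lib_size)))
  z <- sweep(cm$counts, 2, f, "/")
  num <- rep(0, nrow(z)); df_tot <- 0
  any_rep <- FALSE
  for (cc in conds) {
    zc <- z[, cm$condition == cc, drop = FALSE]
    nc <- ncol(zc)
    if (nc < 2) next
    any_rep <- TRUE
    m <- rowMeans(zc); v <- row_vars(zc)
    phi_c <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    num <- num + ifelse(is.na(phi_c), 0, phi_c) * (nc - 1)
    df_tot <- df_tot + (nc - 1)
  }
  genes <- rownames(cm$counts)
  expressed <- rowSums(cm$counts) > 0
  if (!any_rep) {
    warning("no condition has >= 2 replicates; using fallback common dispersion")
    phi0 <- fallback
    tagwise <- setNames(rep(phi0, length(genes)), genes)
    return(list(common = phi0, tagwise = tagwise,
                per_gene = setNames(rep(NA_real_, length(genes)), genes),
                prior_df = prior_df, residual_df = 0))
  }
  phi_hat <- pmax(0, num / df_tot)
  phi0 <- mean(phi_hat[expressed], trim = trim, na.rm = TRUE)
  tagwise <- (prior_df * phi0 + df_tot * phi_hat) / (prior_df + df_tot)
  tagwise[!expressed] <- phi0
  names(tagwise) <- names(phi_hat) <- genes
  list(common = phi0, tagwise = tagwise, per_gene = phi_hat,
       prior_df = prior_df, residual_df = df_tot)
}

# Conditional null pmf of the first group's sum given the total, for group
# sums of nA and nB negative-binomial replicates with common dispersion phi.
# In the phi -> 0 (Poisson) limit this is Binomial(T, nA/(nA+nB)).
nb_conditional_pmf <- function(T, nA, nB, phi) {
  y <- 0:T
  if (phi < 1e-12) {
    p <- stats::dbinom(y, T, nA / (nA + nB))
  } else {
    mu <- T / (nA + nB)
    la <- stats::dnbinom(y, size = nA / phi, mu = nA * mu, log = TRUE) +
      stats::dnbinom(T - y, size = nB / phi, mu = nB * mu, log = TRUE)
    p <- exp(la - max(la))
    p <- p / sum(p)
  }
  p
}

#' Negative-binomial exact test for two conditions
#'
#' For each gene, counts are scaled to a common effective library size (the
#' geometric mean of the library sizes) and rounded to integers; the two
#' group sums are then compared conditionally on their total. Under the
#' null the conditional law of the first group's sum follows from the
#' convolution of negative-binomial replicates with the gene's dispersion,
#' and the two-sided p-value is the total probability of all outcomes no
#' more likely than the observed one (ties included with a 1e-12 relative
#' tolerance). Genes with total 0 get p = 1.
#'
#' @param cm A [count_matrix()] whose `condition` has exactly two levels.
#' @param disp Dispersions from [estimate_dispersions()], or a single
#'   number used for every gene.
#' @return Named numeric vector of p-values in (0, 1].
#' @export
nb_exact_test <- function(cm, disp) {
  conds <- sort(unique(cm$condition))
  if (length(conds) != 2) bail("exactly two conditions required")
  phi <- if (is.numeric(disp) && length(disp) == 1)
    setNames(rep(disp, nrow(cm$counts)), rownames(cm$counts))
  else disp$tagwise[rownames(cm$counts)]
  ref <- exp(mean(log(cm$lib_size)))
  scaled <- round(sweep(cm$counts, 2, ref / cm$lib_size, "*"))
  gA <- cm$condition == conds[1]
  yA <- rowSums(scaled[, gA, drop = FALSE])
  yB <- rowSums(scaled[, !gA, drop = FALSE])
  nA <- sum(gA); nB <- sum(!gA)
  pvals <- vapply(seq_along(yA), function(g) {
    T <- yA[g] + yB[g]
    if (T == 0) return(1)
    p <- nb_conditional_pmf(T, nA, nB, phi[g])
    pobs <- p[yA[g] + 1]
    min(1, sum(p[p <= pobs * (1 + 1e-12)]))
  }, numeric(1))
  setNames(pvals, rownames(cm$counts))
}

#' Signed fold changes between two conditions
#'
#' Group means `m1`, `m2` of pseudo-count-augmented RPKM, where group 1 is
#' the lexicographically first condition label; the fold change is `+m1/m2`
#' when the first condition is at least as high and `-m2/m1` otherwise, so
#' `|FC| >= 1` always and a negative sign marks lower expression in the
#' first condition. Swapping the two labels therefore negates every fold
#' change.
#'
#' @param rpkm RPKM matrix from [compute_rpkm()].
#' @param condition Condition label per column (two levels).
#' @param pseudo Pseudo-RPKM added to every value before averaging
#'   (default 0.1); keeps fold changes finite for zero-count genes.
#' @return Named numeric vector of signed fold changes.
#' @export
fold_changes <- function(rpkm, condition, pseudo = 0.1) {
  conds <- sort(unique(condition))
  if (length(conds) != 2) bail("exactly two conditions required")
  m1 <- rowMeans(rpkm[, condition == conds[1], drop = FALSE]) + pseudo
  m2 <- rowMeans(rpkm[, condition == conds[2], drop = FALSE]) + pseudo
  fc <- ifelse(m1 >= m2, m1 / m2, -m2 / m1)
  setNames(fc, rownames(rpkm))
}

#' Call differentially expressed genes
#'
#' A gene is differentially expressed when `|FC| >= fc_threshold` and
#' `p < alpha`; no multiple-testing correction is applied.
#'
#' @param fc Signed fold changes from [fold_changes()].
#' @param pvals P-values from [nb_exact_test()], same genes.
#' @param fc_threshold Minimum absolute fold change (default 2).
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @return A data.frame with `gene_id`, `fc`, `pvalue`, `is_de`,
#'   `direction` ("up"/"down"/"none").
#' @export
call_de <- function(fc, pvals, fc_threshold = 2, alpha = 0.05) {
  stopifnot(identical(names(fc), names(pvals)))
  is_de <- abs(fc) >= fc_threshold & pvals < alpha
  direction <- ifelse(!is_de, "none", ifelse(fc > 0, "up", "down"))
  data.frame(gene_id = names(fc), fc = unname(fc), pvalue = unname(pvals),
             is_de = unname(is_de), direction = direction,
             stringsAsFactors = FALSE)
}

#' Full differential-expression analysis of a count matrix
#'
#' Convenience wrapper: RPKM, dispersion estimation, exact test, fold
#' changes and DE calling in one step.
#'
#' @inheritParams compute_rpkm
#' @inheritParams call_de
#' @param pseudo Pseudo-RPKM for fold changes (default 0.1).
#' @param prior_df Dispersion shrinkage weight (default 10).
#' @return The [call_de()] table with an `rpkm` attribute.
#' @export
de_analysis <- function(cm, ann, fc_threshold = 2, alpha = 0.05,
                        pseudo = 0.1, prior_df = 10) {
  rpkm <- compute_rpkm(cm, ann)
  disp <- estimate_dispersions(cm, prior_df = prior_df)
  pvals <- nb_exact_test(cm, disp)
  fc <- fold_changes(rpkm, cm$condition, pseudo = pseudo)
  res <- call_de(fc, pvals, fc_threshold = fc_threshold, alpha = alpha)
  attr(res, "rpkm") <- rpkm
  attr(res, "dispersion") <- disp
  res
}
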