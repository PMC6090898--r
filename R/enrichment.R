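#' Observed DE counts per functional category
#'
#' @param category_map Named character vector: gene id -> category label
#'   (the universe is `names(category_map)`).
#' @param de_set Character vector of differentially expressed gene ids,
#'   a subset of the universe.
#' @return Named integer vector: category -> number of DE genes in it.
#' @export
observed_counts <- function(category_map, de_set) {
  missing <- setdiff(de_set, names(category_map))
  if (length(missing)) bail("DE gene '%s' absent from universe", missing[1])
  cats <- sort(unique(category_map))
  k <- table(factor(category_map[de_set], levels = cats))
  setNames(as.integer(k), cats)
}

#' Resampling test for category enrichment of DE genes
#'
#' Draws `n_resamples` random gene sets of size `|de_set|` uniformly
#' without replacement from the whole universe of protein-coding genes.
#' For each category the reported fraction is the proportion of resamples
#' in which the number of randomly sampled genes falling in the category
#' (RS) is greater than or equal to the observed DE count; the category is
#' called significantly enriched when that fraction is below `alpha`. All
#' categories are evaluated against the same set of resamples. A fraction
#' of 0 means the empirical p-value is below `1/n_resamples`.
#'
#' @param category_map Named character vector: gene id -> category.
#' @param de_set Character vector of DE gene ids.
#' @param n_resamples Number of random samplings (default 10000).
#' @param alpha Significance level (default 0.05).
#' @return A data.frame with one row per category: `category`, `N`
#'   (universe size), `K` (category size), `n` (DE set size), `k` (observed
#'   DE in category), `fraction` (empirical p-value), `significant`.
#' @export
resample_enrichment <- function(category_map, de_set, n_resamples = 10000L,
                                alpha = 0.05) {
  if (n_resamples < 1) bail("n_resamples must be >= 1")
  if (alpha <= 0 || alpha >= 1) bail("alpha must be in (0, 1)")
  k_obs <- observed_counts(category_map, de_set)
  cats <- names(k_obs)
  N <- length(category_map)
  n <- length(de_set)
  cat_f <- factor(unname(category_map), levels = cats)
  ge_count <- setNames(integer(length(cats)), cats)
  for (r in seq_len(n_resamples)) {
    idx <- sample.int(N, n)
    rs <- tabulate(cat_f[idx], nbins = length(cats))
    ge_count <- ge_count + (rs >= k_obs)
  }
  fraction <- ge_count / n_resamples
  data.frame(category = cats, N = N,
             K = as.integer(table(cat_f)), n = n,
             k = unname(k_obs), fraction = unname(fraction),
             significant = unname(fraction < alpha),
             stringsAsFactors = FALSE)
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (drawing `n` items from a
#' universe of `N` containing `K` marked ones), computed by direct
#' summation of exact binomial-coefficient ratios. Serves as the analytic
#' reference for [resample_enrichment()].
#'
#' @param N Universe size.
#' @param K Category size (`K <= N`).
#' @param n Sample size (`n <= N`).
#' @param k Observed count (`>= 0`; values beyond the support give 0).
#' @return The tail probability.
#' @export
#' @examples
#' hypergeometric_tail(20, 5, 4, 4)  # 5/4845
hypergeometric_tail <- function(N, K, n, k) {
  if (K > N || n > N || k < 0 || N < 0)
    bail("invalid hypergeometric arguments (need 0 <= k, n <= N, K <= N)")
  hi <- min(K, n)
  if (k > hi) return(0)
  j <- max(k, max(0, n - (N - K))):hi
  min(1, sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n))
}
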