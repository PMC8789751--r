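.check_hg_args <- function(k, K, n, N) {
  if (any(K < 0 | K > N | n < 0 | n > N | k < 0 | N < 0)) {
    stop("hypergeometric arguments must satisfy 0 <= K <= N, 0 <= n <= N, k >= 0",
         call. = FALSE)
  }
  if (any(c(k, K, n, N) != round(c(k, K, n, N)))) {
    stop("hypergeometric arguments must be integers", call. = FALSE)
  }
}

# log pmf of Hypergeometric(N, K, n) at x, via log-gamma; vectorized over x
.hg_log_pmf <- function(x, K, n, N) {
  lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
}

# stable sum of exp(logs)
.logsumexp <- function(logs) {
  m <- max(logs)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(logs - m)))
}

.hg_tail_one <- function(k, K, n, N, upper) {
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  xs <- if (upper) seq.int(max(k, lo), hi) else seq.int(lo, min(k, hi))
  if (upper && k > hi) return(0)
  if (!upper && k < lo) return(0)
  min(1, exp(.logsumexp(.hg_log_pmf(xs, K, n, N))))
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Exact enrichment p-value for drawing `k` or more category members in a
#' sample of `n` from a population of `N` containing `K` category members,
#' computed by log-space summation of the hypergeometric pmf over
#' `x = k..min(n, K)` (numerically stable for large counts). The observed
#' point mass P(X = k) is included, as is standard.
#'
#' @param k Observed overlap count(s).
#' @param K Category total in the background.
#' @param n Sample (cluster) size.
#' @param N Background total.
#' @return P(X >= k); vectorized over `k` (with scalar K, n, N) or over
#'   all four arguments elementwise.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  .check_hg_args(k, K, n, N)
  m <- max(length(k), length(K), length(n), length(N))
  vapply(seq_len(m), function(i) {
    ii <- function(v) v[[(i - 1L) %% length(v) + 1L]]
    .hg_tail_one(ii(k), ii(K), ii(n), ii(N), upper = TRUE)
  }, numeric(1))
}

#' Lower-tail hypergeometric probability P(X <= k)
#'
#' Exact depletion p-value, the mirror of [hypergeom_upper_tail()]; the
#' two tails share the point mass at `k`, so
#' `upper(k) + lower(k - 1) = 1`.
#'
#' @inheritParams hypergeom_upper_tail
#' @return P(X <= k), vectorized as in [hypergeom_upper_tail()].
#' @export
hypergeom_lower_tail <- function(k, K, n, N) {
  .check_hg_args(k, K, n, N)
  m <- max(length(k), length(K), length(n), length(N))
  vapply(seq_len(m), function(i) {
    ii <- function(v) v[[(i - 1L) %% length(v) + 1L]]
    .hg_tail_one(ii(k), ii(K), ii(n), ii(N), upper = FALSE)
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; q-values are returned in input
#' order, are monotone in p, and are clipped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Per-cluster enrichment and depletion of a categorical cell property
#'
#' For every (cluster, category) pair, tests whether the category is over-
#' or under-represented in the cluster relative to the pooled background of
#' all cells, using exact hypergeometric tails: enrichment p = P(X >= k),
#' depletion p = P(X <= k) with k the observed count, n the cluster size,
#' K the category total and N the background total. Benjamini-Hochberg
#' correction is applied separately to the enrichment family and the
#' depletion family, each spanning all cluster x category tests of the run
#' (`family = "global"`, default) or each category's tests
#' (`family = "per-category"`). Pairs are flagged at `q <= alpha`.
#'
#' @param cells Paired-cell tibble with a `cluster` column.
#' @param category_of Name of the categorical cell column to test,
#'   typically `"identity_bin"` or `"isotype_class"`.
#' @param alpha Flagging threshold on q (default 0.05).
#' @param family BH family scope, `"global"` or `"per-category"`.
#' @return List with `enrichment`, a tibble of one row per
#'   cluster x category (`cluster`, `category`, `k`, `n`, `K`, `N`,
#'   `pct_of_cluster`, `p_enrich`, `p_deplete`, `q_enrich`, `q_deplete`,
#'   `flag`), and `composition`, the percent-of-cluster composition table
#'   in wide form (rows sum to 100).
#' @export
categorical_enrichment_by_cluster <- function(cells, category_of,
                                              alpha = 0.05,
                                              family = c("global", "per-category")) {
  family <- match.arg(family)
  stopifnot(category_of %in% names(cells), "cluster" %in% names(cells))
  cl <- as.character(cells$cluster)
  cat_v <- as.character(cells[[category_of]])
  if (anyNA(cl) || anyNA(cat_v)) {
    stop("every cell needs a cluster label and a defined category", call. = FALSE)
  }
  clusters <- unique(cl)
  cats <- if (is.factor(cells[[category_of]])) levels(cells[[category_of]])
          else sort(unique(cat_v))
  N <- length(cl)
  Ktab <- table(factor(cat_v, levels = cats))
  ntab <- table(factor(cl, levels = clusters))
  ktab <- table(factor(cl, levels = clusters), factor(cat_v, levels = cats))

  rec <- expand.grid(cluster = clusters, category = cats,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec$k <- as.integer(ktab[cbind(rec$cluster, rec$category)])
  rec$n <- as.integer(ntab[rec$cluster])
  rec$K <- as.integer(Ktab[rec$category])
  rec$N <- N
  rec$pct_of_cluster <- ifelse(rec$n > 0, 100 * rec$k / rec$n, NA_real_)
  rec$p_enrich <- hypergeom_upper_tail(rec$k, rec$K, rec$n, rec$N)
  rec$p_deplete <- hypergeom_lower_tail(rec$k, rec$K, rec$n, rec$N)
  rec$p_enrich[rec$n == 0] <- 1
  rec$p_deplete[rec$n == 0] <- 1

  if (family == "global") {
    rec$q_enrich <- bh_adjust(rec$p_enrich)
    rec$q_deplete <- bh_adjust(rec$p_deplete)
  } else {
    rec$q_enrich <- stats::ave(rec$p_enrich, rec$category, FUN = bh_adjust)
    rec$q_deplete <- stats::ave(rec$p_deplete, rec$category, FUN = bh_adjust)
  }
  rec$flag <- ifelse(rec$q_enrich <= alpha, "enriched",
              ifelse(rec$q_deplete <= alpha, "depleted", "none"))
  rec$flag[rec$n == 0] <- "none"

  composition <- tibble::as_tibble(rec[, c("cluster", "category", "pct_of_cluster")]) |>
    tidyr::pivot_wider(names_from = "category", values_from = "pct_of_cluster")
  list(enrichment = tibble::as_tibble(rec), composition = composition)
}

#' Gene-set over-representation analysis
#'
#' Tests each gene set of a collection for over-representation in a gene
#' signature by the hypergeometric upper tail: with a universe of N genes,
#' a set covering K of them and a signature of n, the p-value is
#' P(X >= overlap). Signature and sets are intersected with the universe
#' first; Benjamini-Hochberg correction is applied across all sets of the
#' collection.
#'
#' @param signature Character vector of signature gene symbols.
#' @param collection Gene-set collection from [read_gene_sets()].
#' @param universe Character vector of background gene symbols.
#' @param alpha Significance threshold on q (default 0.05).
#' @return Tibble with one row per set: `set`, `overlap`, `set_size`
#'   (within the universe), `signature_size`, `universe_size`, `p_value`,
#'   `q_value`, `significant`.
#' @export
pathway_enrichment <- function(signature, collection, universe, alpha = 0.05) {
  universe <- unique(universe)
  signature <- intersect(unique(signature), universe)
  if (length(universe) == 0 || length(signature) == 0) {
    stop("signature and universe must be non-empty after intersection", call. = FALSE)
  }
  N <- length(universe)
  n <- length(signature)
  sets <- lapply(collection$sets, intersect, universe)
  K <- vapply(sets, length, integer(1))
  k <- vapply(sets, function(s) length(intersect(s, signature)), integer(1))
  p <- hypergeom_upper_tail(k, K, rep(n, length(k)), rep(N, length(k)))
  q <- bh_adjust(p)
  tibble::tibble(
    set = names(sets), overlap = unname(k), set_size = unname(K),
    signature_size = n, universe_size = N,
    p_value = unname(p), q_value = unname(q), significant = unname(q < alpha)
  )
}
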