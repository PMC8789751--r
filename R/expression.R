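#' Library-size normalization of UMI counts
#'
#' Scales each cell's counts to a common library size: counts are divided
#' by the cell total and multiplied by `scale`. Cells with zero total
#' counts are removed first (their number is recorded in the
#' `n_zero_cells_removed` attribute). Log transformation is applied on
#' demand by downstream summaries, never stored.
#'
#' @param counts Cells x genes sparse count matrix (see
#'   [read_expression_matrix()]).
#' @param scale Target library size (default 10000).
#' @return Normalized sparse matrix, same orientation; every row sums to
#'   `scale`.
#' @export
normalize_counts <- function(counts, scale = 10000) {
  stopifnot(scale > 0)
  totals <- Matrix::rowSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    counts <- counts[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  norm <- Matrix::Diagonal(x = scale / totals) %*% counts
  dimnames(norm) <- dimnames(counts)
  norm <- methods::as(norm, "CsparseMatrix")
  attr(norm, "n_zero_cells_removed") <- sum(zero)
  attr(norm, "scale") <- scale
  norm
}

#' Rank-based differential expression between two cell groups
#'
#' For each gene, compares normalized expression between two disjoint cell
#' groups with a two-sided Wilcoxon rank-sum test on log2(1 + normalized)
#' values, followed by Benjamini-Hochberg correction across tested genes.
#' Fold change is the linear-scale ratio of normalized group means with a
#' pseudocount of `scale / 1000` added to both means. A gene passes the
#' reporting filters when |fold change| >= `fc_min` in either direction,
#' it is detected (count > 0) in at least `pct_min` of the cells of either
#' group, and q <= `q_max`.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param cells_a,cells_b Barcode vectors of the two groups (disjoint,
#'   each at least `min_cells`).
#' @param min_cells Minimum group size (default 10).
#' @param fc_min Fold-change reporting threshold (default 1.2).
#' @param pct_min Detection-fraction reporting threshold (default 0.25).
#' @param q_max FDR reporting threshold (default 0.05).
#' @return Tibble with one row per gene: `gene`, `group_a_mean`,
#'   `group_b_mean` (mean log2(1+normalized)), `fold_change` (linear
#'   scale, a/b), `pct_a`, `pct_b`, `p_value`, `q_value`,
#'   `passes_filters`.
#' @export
differential_expression <- function(norm, cells_a, cells_b,
                                    min_cells = 10L, fc_min = 1.2,
                                    pct_min = 0.25, q_max = 0.05) {
  if (length(intersect(cells_a, cells_b)) > 0) {
    stop("groups must be disjoint", call. = FALSE)
  }
  a <- norm[rownames(norm) %in% cells_a, , drop = FALSE]
  b <- norm[rownames(norm) %in% cells_b, , drop = FALSE]
  if (nrow(a) < min_cells || nrow(b) < min_cells) {
    stop(sprintf("each group needs at least %d cells (got %d and %d)",
                 min_cells, nrow(a), nrow(b)), call. = FALSE)
  }
  scale <- attr(norm, "scale")
  if (is.null(scale)) scale <- 10000
  pc <- scale / 1000

  la <- log2(1 + as.matrix(a))
  lb <- log2(1 + as.matrix(b))
  mean_lin_a <- Matrix::colMeans(a)
  mean_lin_b <- Matrix::colMeans(b)
  pct_a <- Matrix::colMeans(a > 0)
  pct_b <- Matrix::colMeans(b > 0)

  p <- vapply(seq_len(ncol(norm)), function(j) {
    xa <- la[, j]
    xb <- lb[, j]
    if (all(xa == xa[1]) && all(xb == xb[1]) && xa[1] == xb[1]) return(1)
    suppressWarnings(wilcox.test(xa, xb, exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  q <- bh_adjust(p)
  fc <- (mean_lin_a + pc) / (mean_lin_b + pc)

  tibble::tibble(
    gene = colnames(norm),
    group_a_mean = colMeans(la),
    group_b_mean = colMeans(lb),
    fold_change = unname(fc),
    pct_a = unname(pct_a),
    pct_b = unname(pct_b),
    p_value = p,
    q_value = q,
    passes_filters = (fc >= fc_min | fc <= 1 / fc_min) &
      (pct_a >= pct_min | pct_b >= pct_min) & q <= q_max
  )
}

#' Dot-plot summary statistics for a gene panel across clusters
#'
#' For each (gene, cluster) pair computes the fraction of cluster cells
#' with detectable expression (count > 0) and the mean log2(1+normalized)
#' expression, then z-scores the per-cluster means across the clusters of
#' the call, per gene. Genes with zero variance across clusters get
#' z-scores of 0; genes absent from the matrix are reported in the
#' `missing_genes` attribute and skipped.
#'
#' @param norm Normalized matrix from [normalize_counts()].
#' @param gene_panel Character vector of gene symbols.
#' @param cluster_labels Character vector of cluster labels parallel to
#'   `rownames(norm)`.
#' @return Tibble with columns `gene`, `cluster`, `pct_detected`,
#'   `mean_log_expr`, `z_score`.
#' @export
dotplot_summary <- function(norm, gene_panel, cluster_labels) {
  stopifnot(length(cluster_labels) == nrow(norm))
  present <- gene_panel[gene_panel %in% colnames(norm)]
  missing <- setdiff(gene_panel, present)
  clusters <- unique(as.character(cluster_labels))
  sub <- norm[, present, drop = FALSE]
  lsub <- log2(1 + as.matrix(sub))
  out <- lapply(clusters, function(cl) {
    idx <- which(cluster_labels == cl)
    tibble::tibble(
      gene = present,
      cluster = cl,
      pct_detected = unname(Matrix::colMeans(sub[idx, , drop = FALSE] > 0)),
      mean_log_expr = unname(colMeans(lsub[idx, , drop = FALSE]))
    )
  })
  out <- dplyr::bind_rows(out)
  out <- out |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(z_score = {
      s <- sd(.data$mean_log_expr)
      if (length(.data$mean_log_expr) < 2 || is.na(s) || s == 0) {
        rep(0, length(.data$mean_log_expr))
      } else {
        (.data$mean_log_expr - mean(.data$mean_log_expr)) / s
      }
    }) |>
    dplyr::ungroup()
  attr(out, "missing_genes") <- missing
  out
}
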