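# In-code fixtures shared across test files.

# one well-formed contig row; override fields as needed
make_contig <- function(barcode = "bc1", donor = "d1", chain = "IGH",
                        v_gene = "IGHV3-23", d_gene = "IGHD3-10",
                        j_gene = "IGHJ4", c_gene = "IGHG1",
                        cdr3_nt = "TGTGCGAGAGATTAC", productive = TRUE,
                        full_length = TRUE, high_confidence = TRUE,
                        umis = 10L, v_identity_pct = 95.8) {
  tibble::tibble(barcode = barcode, donor = donor, chain = chain,
                 v_gene = v_gene, d_gene = d_gene, j_gene = j_gene,
                 c_gene = c_gene, cdr3_nt = cdr3_nt, productive = productive,
                 full_length = full_length, high_confidence = high_confidence,
                 umis = as.integer(umis), v_identity_pct = v_identity_pct)
}

# a heavy+light pair for one barcode
make_pair <- function(barcode, donor = "d1", c_gene = "IGHG1",
                      heavy_identity = 96, light_identity = 96,
                      cdr3_h = "TGTGCGAGAGATTAC", cdr3_l = "TGTCAACAGTAT",
                      heavy_umis = 10L, light_umis = 8L, ...) {
  dplyr::bind_rows(
    make_contig(barcode = barcode, donor = donor, c_gene = c_gene,
                cdr3_nt = cdr3_h, umis = heavy_umis,
                v_identity_pct = heavy_identity, ...),
    make_contig(barcode = barcode, donor = donor, chain = "IGK",
                v_gene = "IGKV1-39", d_gene = "", j_gene = "IGKJ2",
                c_gene = "IGKC", cdr3_nt = cdr3_l, umis = light_umis,
                v_identity_pct = light_identity)
  )
}

# scaled-down profile for fast unit tests
small_profile <- function(n_cells = 2000L, n_genes = 60L) {
  p <- default_profile()
  p$n_cells <- as.integer(n_cells)
  p$expression_model$n_genes <- as.integer(n_genes)
  p
}

# adjusted Rand index between two label vectors, by sparse pair counting
# (avoids the dense contingency table, which is quadratic in label count)
adjusted_rand_index <- function(a, b) {
  n <- length(a)
  nij <- as.integer(table(paste(a, b, sep = "\r")))
  ai <- as.integer(table(a))
  bj <- as.integer(table(b))
  sum_ij <- sum(choose(nij, 2))
  sum_a <- sum(choose(ai, 2))
  sum_b <- sum(choose(bj, 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# brute-force hypergeometric tail by direct combinatorial enumeration
brute_upper_tail <- function(k, K, n, N) {
  xs <- k:min(n, K)
  xs <- xs[xs >= 0 & xs >= n - (N - K)]
  if (k > min(n, K)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

brute_lower_tail <- function(k, K, n, N) {
  lo <- max(0, n - (N - K))
  if (k < lo) return(0)
  xs <- lo:min(k, min(n, K))
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}
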