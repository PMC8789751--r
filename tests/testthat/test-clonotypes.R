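# two QC-passed cells for clonotype tests, sharing or varying key fields
cells_from_pairs <- function(...) {
  contigs <- dplyr::bind_rows(...)
  filter_paired_cells(contigs, unique(contigs$barcode))
}

test_that("cells with identical V(D)J genes and CDR3s form one clonotype", {
  cells <- cells_from_pairs(make_pair("a"), make_pair("b"))
  cl <- call_clonotypes(cells)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 2L)
  expect_setequal(cl$members[[1]], c("a", "b"))
})

test_that("a single CDR3 nucleotide difference separates clonotypes", {
  cells <- cells_from_pairs(
    make_pair("a", cdr3_h = "TGTGCGAGAGATTAC"),
    make_pair("b", cdr3_h = "TGTGCGAGAGATTAT"))
  cl <- call_clonotypes(cells)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$size, c(1L, 1L))
})

test_that("identical keys in different donors never merge", {
  contigs <- dplyr::bind_rows(make_pair("a", donor = "d1"),
                              make_pair("a2", donor = "d2"))
  cells <- filter_paired_cells(contigs, c("a", "a2"))
  cl <- call_clonotypes(cells)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$donor, c("d1", "d2"))
})

test_that("clonotype calling is deterministic under input permutation", {
  co <- generate_cohort(small_profile(1200), seed = 5, expression = FALSE)
  cells <- filter_paired_cells(co$contigs, co$truth$barcode)
  cl1 <- call_clonotypes(cells)
  set.seed(99)
  perm <- sample(nrow(cells))
  cl2 <- call_clonotypes(cells[perm, ])
  expect_equal(cl1[, setdiff(names(cl1), "members")],
               cl2[, setdiff(names(cl2), "members")],
               ignore_attr = "cell_clones")
  expect_equal(lapply(cl1$members, sort), lapply(cl2$members, sort))
  # per-cell assignments are the same partition, just permuted with the input
  expect_equal(cell_clone_ids(cl2), cell_clone_ids(cl1)[perm])
  # ids follow descending size then lexicographic key, per donor
  by_donor <- split(cl1, cl1$donor)
  for (d in by_donor) {
    expect_true(all(diff(d$size) <= 0))
  }
})

test_that("clone sizes partition the cells of each donor", {
  co <- generate_cohort(small_profile(1500), seed = 8, expression = FALSE)
  cells <- filter_paired_cells(co$contigs, co$truth$barcode)
  cl <- call_clonotypes(cells)
  per_donor_cells <- table(cells$donor)
  per_donor_clone <- tapply(cl$size, cl$donor, sum)
  expect_equal(as.integer(per_donor_clone[names(per_donor_cells)]),
               as.integer(per_donor_cells))
  assign <- cell_clone_ids(cl)
  expect_equal(length(assign), nrow(cells))
  expect_false(anyNA(assign))
})

test_that("singleton-cell fractions follow hand-counted examples", {
  # clones of sizes {1, 1, 3}: 2 of 5 cells are in singletons
  cells <- cells_from_pairs(
    make_pair("s1", cdr3_h = "TGTAAAAAAGCGGCG"),
    make_pair("s2", cdr3_h = "TGTCCCCCCGCGGCG"),
    make_pair("c1"), make_pair("c2"), make_pair("c3"))
  s <- clone_size_summary(call_clonotypes(cells))
  expect_equal(s$singleton_cell_fraction, 0.4)
  expect_equal(s$n_clonotypes, 3L)
  expect_equal(s$max_clone_size, 3L)

  all_single <- cells_from_pairs(
    make_pair("x1", cdr3_h = "TGTAAAAAAGCGGCG"),
    make_pair("x2", cdr3_h = "TGTCCCCCCGCGGCG"))
  expect_equal(clone_size_summary(call_clonotypes(all_single))$singleton_cell_fraction, 1)

  one_clone <- cells_from_pairs(make_pair("y1"), make_pair("y2"), make_pair("y3"))
  expect_equal(clone_size_summary(call_clonotypes(one_clone))$singleton_cell_fraction, 0)
})

test_that("isotype heterogeneity is scored at class level, subclass on request", {
  # 5 cells all IGHG1: homogeneous
  homog <- do.call(cells_from_pairs, lapply(paste0("h", 1:5), make_pair))
  clh <- call_clonotypes(homog)
  expect_equal(clone_isotype_heterogeneity(clh)$fraction, 0)

  # IGHM x2 + IGHG1 x3: heterogeneous
  het <- cells_from_pairs(
    make_pair("m1", c_gene = "IGHM"), make_pair("m2", c_gene = "IGHM"),
    make_pair("g1"), make_pair("g2"), make_pair("g3"))
  clm <- call_clonotypes(het)
  res <- clone_isotype_heterogeneity(clm)
  expect_equal(res$fraction, 1)
  expect_true(res$flags$heterogeneous)

  # IGHG1 x3 + IGHG2 x3: homogeneous at class level, heterogeneous at subclass
  sub <- cells_from_pairs(
    make_pair("a1"), make_pair("a2"), make_pair("a3"),
    make_pair("b1", c_gene = "IGHG2"), make_pair("b2", c_gene = "IGHG2"),
    make_pair("b3", c_gene = "IGHG2"))
  cls <- call_clonotypes(sub)
  expect_equal(clone_isotype_heterogeneity(cls)$fraction, 0)
  expect_equal(clone_isotype_heterogeneity(cls, level = "subclass", cells = sub)$fraction, 1)
})

test_that("heterogeneity with no clone at min_size returns a zero denominator, not an error", {
  single <- cells_from_pairs(make_pair("z1"))
  res <- clone_isotype_heterogeneity(call_clonotypes(single), min_size = 5)
  expect_true(is.na(res$fraction))
  expect_equal(res$n_eligible, 0L)
})

test_that("heterogeneity across min_size thresholds matches a naive recount", {
  co <- generate_cohort(small_profile(3000), seed = 13, expression = FALSE)
  cells <- filter_paired_cells(co$contigs, co$truth$barcode)
  cl <- call_clonotypes(cells)
  assign <- cell_clone_ids(cl)
  for (ms in 2:10) {
    res <- clone_isotype_heterogeneity(cl, min_size = ms)
    # naive oracle: recount from the per-cell table
    tab <- split(cells$isotype_class, assign)
    big <- tab[vapply(tab, length, integer(1)) >= ms]
    oracle <- if (length(big) == 0) NA_real_ else {
      mean(vapply(big, function(x) length(unique(x)) >= 2, logical(1)))
    }
    expect_equal(res$fraction, oracle, info = paste("min_size =", ms))
  }
})
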