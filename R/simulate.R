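.isotype_classes <- c("IGHM", "IGHG", "IGHA", "IGHE")

.subclass_pool <- list(
  IGHM = "IGHM",
  IGHG = c("IGHG1", "IGHG2", "IGHG3", "IGHG4"),
  IGHA = c("IGHA1", "IGHA2"),
  IGHE = "IGHE"
)

#' Default synthetic cohort profile
#'
#' Returns the shipped calibration of the synthetic germinal center
#' cohort: 40,000 cells from 3 donors across the 14 GC clusters.
#'
#' Per-cluster V-region identity mixtures place probability `w100` at
#' exactly 100% (unmutated) and spread the rest uniformly within the
#' \[98,100), \[96,98), \[94,96) and \[71,94) identity bins. The PreM
#' cluster is bimodal (36% unmutated, 51% below 98%), PBL carries 17%
#' heavily mutated cells, the memory-precursor clusters are skewed to
#' high identity, and a subset of DZ/LZ clusters (DZ-1, INT-2, LZ-1) is
#' biased toward heavier mutation; pooled, the mixtures give a median
#' identity of 95.5%, 2% unmutated, 15% at or above 98% and 32% below
#' 94%.
#'
#' Isotype-class probabilities are calibrated so that the *measured*
#' per-cluster marginals, after clonal isotype inheritance and intraclonal
#' switching, recover the study conditions (pooled IGHG/IGHA/IGHM of
#' 43/33/24%, PreM 54% IGHM, PBL 71% IGHG, memory-precursor clusters
#' dominated by IGHM); because about 18% of cells inherit a
#' proportionally-pooled founder class, the per-cluster generator
#' probabilities are deconvolved accordingly (see the methods vignette
#' for the calibration identity). IGHE has probability zero everywhere
#' and appears only as an empty row in composition tables.
#'
#' The clonal model packs 26% of each donor's cells into clones of size
#' 2 + Geometric(0.45) (singleton-cell fraction 0.74); each non-founder
#' member switches isotype class with probability `p_switch = 0.07`,
#' respecting switch irreversibility (IGHM to IGHG or IGHA, IGHG to IGHA
#' only), which yields roughly a fifth of clones of five or more cells
#' containing mixed isotype classes.
#'
#' The expression model draws negative-binomial counts (dispersion
#' size 2) for 500 genes with gamma-distributed baseline means and an
#' 8-fold up-regulation of hallmark genes in their designated clusters
#' (CXCR4/AICDA in DZ, CD83/BCL2A1 in LZ, CCR6/CELF2 in PreM,
#' PRDM1/FKBP11 in PBL, FCRL2/FCRL3 in FCRL2/3). A 2% contaminant
#' fraction violating the QC rules exercises the filter audit.
#'
#' @return A list of class `cohort_profile` with elements `n_cells`,
#'   `n_donors`, `cluster_proportions`, `identity_model`,
#'   `isotype_probs`, `clonal_model`, `expression_model`,
#'   `contaminant_rate`.
#' @export
default_profile <- function() {
  clusters <- gc_clusters()

  cluster_proportions <- c(
    "DZ-1" = 0.12, "DZ-2" = 0.10, "DZ-3" = 0.08, "INT-1" = 0.10,
    "INT-2" = 0.09, "INT-3" = 0.02, "INT-4" = 0.08, "LZ-1" = 0.13,
    "LZ-2" = 0.10, "LZ-3" = 0.07, "FCRL2/3" = 0.02, "PreM" = 0.04,
    "PBL-1" = 0.03, "PBL-2" = 0.02)[clusters]

  bin_names <- identity_bin_levels()
  # bulk DZ/LZ base mixture (0.0010, 0.1035, 0.2983, 0.2509, 0.3463) split
  # into a heavier-mutated and a lighter-mutated variant that pool back to it
  bulk_heavy  <- c(0.0010, 0.1035, 0.2483, 0.2509, 0.3963)  # DZ-1, INT-2, LZ-1
  bulk_light  <- c(0.0010, 0.1035, 0.3304, 0.2509, 0.3142)  # remaining DZ/LZ
  identity_model <- rbind(
    "DZ-1" = bulk_heavy, "DZ-2" = bulk_light, "DZ-3" = bulk_light,
    "INT-1" = bulk_light, "INT-2" = bulk_heavy, "INT-4" = bulk_light,
    "LZ-1" = bulk_heavy, "LZ-2" = bulk_light, "LZ-3" = bulk_light,
    "INT-3" = c(0.15, 0.70, 0.09, 0.03, 0.03),
    "FCRL2/3" = c(0.05, 0.45, 0.25, 0.13, 0.12),
    "PreM" = c(0.36, 0.13, 0.18, 0.15, 0.18),
    "PBL-1" = c(0.02, 0.23, 0.33, 0.25, 0.17),
    "PBL-2" = c(0.02, 0.23, 0.33, 0.25, 0.17))
  colnames(identity_model) <- bin_names
  identity_model <- identity_model[clusters, ]

  # Generator-level class probabilities, deconvolved for the ~17.9%
  # of cells that inherit a pooled founder class through the clonal model
  # (calibration identity in the methods vignette).
  bulk_neutral <- c(0.20719, 0.43842, 0.35439, 0)
  bulk_g <- bulk_neutral + c(0, 0.04, -0.04, 0)        # INT-1, LZ-1, LZ-3
  bulk_a <- bulk_neutral + c(0, -0.030769, 0.030769, 0) # DZ-1, DZ-3, INT-2, LZ-2
  isotype_probs <- rbind(
    "DZ-1" = bulk_a, "DZ-2" = bulk_neutral, "DZ-3" = bulk_a,
    "INT-1" = bulk_g, "INT-2" = bulk_a, "INT-4" = bulk_neutral,
    "LZ-1" = bulk_g, "LZ-2" = bulk_a, "LZ-3" = bulk_g,
    "INT-3" = c(0.90103, 0.068373, 0.030590, 0),
    "FCRL2/3" = c(0.90103, 0.068373, 0.030590, 0),
    "PreM" = c(0.60862, 0.27551, 0.11588, 0),
    "PBL-1" = c(0.048092, 0.77510, 0.17681, 0),
    "PBL-2" = c(0.048092, 0.77510, 0.17681, 0))
  colnames(isotype_probs) <- .isotype_classes
  isotype_probs <- isotype_probs / rowSums(isotype_probs)
  isotype_probs <- isotype_probs[clusters, ]

  hallmark <- list(
    CXCR4 = c("DZ-1", "DZ-2", "DZ-3"), AICDA = c("DZ-1", "DZ-2", "DZ-3"),
    CD83 = c("LZ-1", "LZ-2", "LZ-3"), BCL2A1 = c("LZ-1", "LZ-2", "LZ-3"),
    CCR6 = "PreM", CELF2 = "PreM",
    PRDM1 = c("PBL-1", "PBL-2"), FKBP11 = c("PBL-1", "PBL-2"),
    FCRL2 = "FCRL2/3", FCRL3 = "FCRL2/3")

  structure(list(
    n_cells = 40000L,
    n_donors = 3L,
    cluster_proportions = cluster_proportions,
    identity_model = identity_model,
    identity_range_low = 71,
    isotype_probs = isotype_probs,
    clonal_model = list(
      singleton_cell_fraction = 0.74,
      multi_size_geom_prob = 0.45,
      max_clone_size = 50L,
      p_switch = 0.07),
    expression_model = list(
      n_genes = 500L,
      baseline_shape = 0.3,
      baseline_rate = 1,
      baseline_floor = 0.05,
      dispersion = 2,
      hallmark_mean = 0.5,
      hallmark_fold = 8,
      hallmark = hallmark),
    contaminant_rate = 0.02
  ), class = "cohort_profile")
}

#' Serialize a cohort profile to JSON
#'
#' @param profile A `cohort_profile`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  x <- unclass(profile)
  x$identity_model <- as.data.frame(x$identity_model) |>
    tibble::rownames_to_column("cluster")
  x$isotype_probs <- as.data.frame(x$isotype_probs) |>
    tibble::rownames_to_column("cluster")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.sample_bin_value <- function(bin, low) {
  n <- length(bin)
  v <- numeric(n)
  v[bin == 1] <- 100
  idx <- bin == 2; v[idx] <- runif(sum(idx), 98, 100)
  idx <- bin == 3; v[idx] <- runif(sum(idx), 96, 98)
  idx <- bin == 4; v[idx] <- runif(sum(idx), 94, 96)
  idx <- bin == 5; v[idx] <- runif(sum(idx), low, 94)
  v
}

.rand_nt <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[[i]], replace = TRUE), collapse = "")
  }, character(1))
}

.gene_pools <- list(
  heavy_v = c("IGHV1-2", "IGHV1-69", "IGHV3-7", "IGHV3-23", "IGHV3-30",
              "IGHV4-34", "IGHV4-39", "IGHV5-51"),
  heavy_d = c("IGHD2-2", "IGHD3-10", "IGHD3-22", "IGHD6-13", ""),
  heavy_j = paste0("IGHJ", 1:6),
  igk_v = c("IGKV1-39", "IGKV3-20", "IGKV4-1", "IGKV1-5"),
  igk_j = paste0("IGKJ", 1:5),
  igl_v = c("IGLV1-44", "IGLV2-14", "IGLV3-21"),
  igl_j = c("IGLJ2", "IGLJ3")
)

# clone sizes for one donor: pack n_multi cells into clones of 2+Geom(p)
.draw_clone_sizes <- function(n_multi, p, max_size) {
  if (n_multi == 0) return(integer(0))
  sizes <- integer(0)
  total <- 0L
  while (total < n_multi) {
    s <- min(2L + rgeom(1, p), max_size)
    sizes <- c(sizes, s)
    total <- total + s
  }
  excess <- total - n_multi
  if (excess > 0) {
    last <- sizes[length(sizes)] - excess
    if (last >= 2L) {
      sizes[length(sizes)] <- last
    } else {
      sizes <- sizes[-length(sizes)]
      short <- n_multi - sum(sizes)
      if (short > 0) {
        if (length(sizes) > 0 && short == 1L) {
          sizes[length(sizes)] <- sizes[length(sizes)] + 1L
        } else if (short >= 2L) {
          sizes <- c(sizes, short)
        } else {
          sizes[1] <- sizes[1] + short
        }
      }
    }
  }
  sizes
}

.switch_class <- function(class, p_switch) {
  n <- length(class)
  do_switch <- runif(n) < p_switch
  out <- class
  m <- do_switch & class == "IGHM"
  out[m] <- sample(c("IGHG", "IGHA"), sum(m), replace = TRUE)
  g <- do_switch & class == "IGHG"
  out[g] <- "IGHA"
  out
}

.generate_donor <- function(profile, donor, n_d) {
  clusters <- gc_clusters()
  prop <- profile$cluster_proportions
  cm <- profile$clonal_model

  n_multi <- round((1 - cm$singleton_cell_fraction) * n_d)
  sizes <- .draw_clone_sizes(n_multi, cm$multi_size_geom_prob, cm$max_clone_size)
  n_multi <- sum(sizes)
  n_single <- n_d - n_multi
  clone_of <- c(rep(seq_along(sizes), sizes),
                seq(length(sizes) + 1L, length.out = n_single))
  n_clones <- length(sizes) + n_single
  is_founder <- !duplicated(clone_of)

  barcode <- sprintf("%s_bc%06d", donor, seq_len(n_d))
  cluster_idx <- sample.int(length(clusters), n_d, replace = TRUE, prob = prop)
  cluster <- clusters[cluster_idx]

  # identity: per-cell mixture draw from the cell's cluster
  bin <- integer(n_d)
  for (ci in seq_along(clusters)) {
    idx <- which(cluster_idx == ci)
    if (length(idx) > 0) {
      bin[idx] <- sample.int(5L, length(idx), replace = TRUE,
                             prob = profile$identity_model[ci, ])
    }
  }
  identity <- .sample_bin_value(bin, profile$identity_range_low)

  # isotype: founders draw from own cluster; members inherit + switch
  class <- character(n_d)
  for (ci in seq_along(clusters)) {
    idx <- which(cluster_idx == ci & is_founder)
    if (length(idx) > 0) {
      class[idx] <- .isotype_classes[
        sample.int(4L, length(idx), replace = TRUE,
                   prob = profile$isotype_probs[ci, ])]
    }
  }
  founder_row <- which(is_founder)
  founder_class <- class[founder_row][clone_of]
  nf <- !is_founder
  class[nf] <- .switch_class(founder_class[nf], cm$p_switch)

  subclass <- vapply(class, function(cl) {
    pool <- .subclass_pool[[cl]]
    if (length(pool) == 1) pool else sample(pool, 1)
  }, character(1), USE.NAMES = FALSE)

  # clonal V(D)J + CDR3, inherited from the founder
  g <- .gene_pools
  f_heavy_v <- sample(g$heavy_v, n_clones, replace = TRUE)
  f_heavy_d <- sample(g$heavy_d, n_clones, replace = TRUE, prob = c(rep(0.225, 4), 0.1))
  f_heavy_j <- sample(g$heavy_j, n_clones, replace = TRUE)
  f_locus <- sample(c("IGK", "IGL"), n_clones, replace = TRUE, prob = c(0.6, 0.4))
  f_light_v <- ifelse(f_locus == "IGK",
                      sample(g$igk_v, n_clones, replace = TRUE),
                      sample(g$igl_v, n_clones, replace = TRUE))
  f_light_j <- ifelse(f_locus == "IGK",
                      sample(g$igk_j, n_clones, replace = TRUE),
                      sample(g$igl_j, n_clones, replace = TRUE))
  f_cdr3_h <- .rand_nt(n_clones, 3L * sample(13:20, n_clones, replace = TRUE))
  f_cdr3_l <- .rand_nt(n_clones, 3L * sample(9:12, n_clones, replace = TRUE))

  heavy_v <- f_heavy_v[clone_of]; heavy_d <- f_heavy_d[clone_of]
  heavy_j <- f_heavy_j[clone_of]; locus <- f_locus[clone_of]
  light_v <- f_light_v[clone_of]; light_j <- f_light_j[clone_of]
  cdr3_h <- f_cdr3_h[clone_of]; cdr3_l <- f_cdr3_l[clone_of]

  # decompose per-cell identity into heavy/light so the mean recovers it
  delta <- runif(n_d, -0.5, 0.5)
  delta[identity + abs(delta) > 100] <- 0
  delta[identity - abs(delta) < 0] <- 0
  id_heavy <- identity + delta
  id_light <- identity - delta

  umis_h <- 4L + rpois(n_d, 25)
  umis_l <- 4L + rpois(n_d, 25)

  # contaminants: injected among singleton cells so planted clone sizes
  # of QC-passing cells stay exact
  n_cont <- round(profile$contaminant_rate * n_d)
  singles <- which(clone_of > length(sizes))
  cont_idx <- sort(sample(singles, min(n_cont, length(singles))))
  cont_type <- sample(c("extra_heavy", "low_umi_heavy", "ighd", "nonproductive_heavy"),
                      length(cont_idx), replace = TRUE)
  expected_rule <- c(extra_heavy = "multiple_eligible_heavy",
                     low_umi_heavy = "no_eligible_heavy",
                     ighd = "ighd_heavy",
                     nonproductive_heavy = "no_eligible_heavy")[cont_type]

  productive_h <- rep(TRUE, n_d)
  c_gene_h <- subclass
  low <- cont_idx[cont_type == "low_umi_heavy"]
  umis_h[low] <- sample(0:3, length(low), replace = TRUE)
  ighd <- cont_idx[cont_type == "ighd"]
  c_gene_h[ighd] <- "IGHD"
  nonp <- cont_idx[cont_type == "nonproductive_heavy"]
  productive_h[nonp] <- FALSE

  heavy <- tibble::tibble(
    barcode = barcode, donor = donor, chain = "IGH",
    v_gene = heavy_v, d_gene = heavy_d, j_gene = heavy_j,
    c_gene = c_gene_h, cdr3_nt = cdr3_h,
    productive = productive_h, full_length = TRUE, high_confidence = TRUE,
    umis = umis_h, v_identity_pct = id_heavy)
  light <- tibble::tibble(
    barcode = barcode, donor = donor, chain = locus,
    v_gene = light_v, d_gene = "", j_gene = light_j,
    c_gene = ifelse(locus == "IGK", "IGKC", "IGLC2"), cdr3_nt = cdr3_l,
    productive = TRUE, full_length = TRUE, high_confidence = TRUE,
    umis = umis_l, v_identity_pct = id_light)

  extra_i <- cont_idx[cont_type == "extra_heavy"]
  extra <- heavy[extra_i, , drop = FALSE]
  if (nrow(extra) > 0) {
    extra$cdr3_nt <- .rand_nt(nrow(extra), 3L * sample(13:20, nrow(extra), replace = TRUE))
    extra$umis <- 4L + rpois(nrow(extra), 25)
  }
  contigs <- dplyr::bind_rows(heavy, light, extra)
  contigs <- contigs[order(match(contigs$barcode, barcode)), ]

  truth <- tibble::tibble(
    barcode = barcode, donor = donor, cluster = cluster,
    group = assign_cluster_groups(cluster),
    identity = identity, identity_bin = bin_germline_identity(identity),
    isotype_class = class, isotype_subclass = subclass,
    clone_id = sprintf("%s_planted%06d", donor, clone_of),
    clone_size = c(sizes, rep(1L, n_single))[clone_of],
    is_founder = is_founder,
    contaminant = barcode %in% barcode[cont_idx])

  injection_log <- tibble::tibble(
    barcode = barcode[cont_idx], donor = donor,
    type = cont_type, expected_rule = unname(expected_rule))

  annotations <- tibble::tibble(barcode = barcode, donor = donor,
                                sorted_fraction = "GC", cluster = cluster)

  list(contigs = contigs, truth = truth, injection_log = injection_log,
       annotations = annotations, cluster_idx = cluster_idx)
}

.generate_expression <- function(profile, donor_data) {
  em <- profile$expression_model
  clusters <- gc_clusters()
  hall <- names(em$hallmark)
  n_bg <- em$n_genes - length(hall)
  genes <- c(hall, sprintf("GENE%04d", seq_len(n_bg)))
  base_mu <- c(rep(em$hallmark_mean, length(hall)),
               em$baseline_floor + stats::rgamma(n_bg, shape = em$baseline_shape,
                                                 rate = em$baseline_rate))
  # per-cluster gene mean matrix (genes x clusters)
  mu_mat <- matrix(base_mu, nrow = length(genes), ncol = length(clusters),
                   dimnames = list(genes, clusters))
  for (g in hall) {
    mu_mat[g, em$hallmark[[g]]] <- em$hallmark_mean * em$hallmark_fold
  }
  lapply(donor_data, function(dd) {
    n_d <- nrow(dd$truth)
    mus <- mu_mat[, dd$cluster_idx, drop = FALSE]  # genes x cells
    counts <- rnbinom(length(mus), mu = as.vector(mus), size = em$dispersion)
    m <- Matrix::Matrix(matrix(counts, nrow = length(genes)), sparse = TRUE)
    m <- Matrix::t(m)  # cells x genes
    dimnames(m) <- list(dd$truth$barcode, genes)
    methods::as(m, "CsparseMatrix")
  })
}

#' Generate a synthetic paired expression + V(D)J cohort
#'
#' Draws a full multi-donor cohort with the statistical structure the
#' pipeline assumes: per-cluster germline-identity mixtures, calibrated
#' isotype-class probabilities, clonal structure with intraclonal
#' switching, negative-binomial expression with hallmark-gene fold-ups,
#' and a small contaminant fraction violating the QC rules. Seeded runs
#' are reproducible; with `out_dir` set, per-donor contig CSVs, MTX trios
#' and annotation TSVs are written in the exact formats the readers
#' consume, alongside a JSON snapshot of the profile.
#'
#' @param profile A `cohort_profile`, e.g. [default_profile()].
#' @param seed Integer RNG seed.
#' @param out_dir Optional output directory; created if absent.
#' @param expression Generate the expression matrices (default TRUE); with
#'   FALSE, only the repertoire side is generated and every cell is
#'   treated as expressed.
#' @return List with `contigs` (pooled tibble), `expression` (named list
#'   of per-donor cells x genes sparse matrices, or NULL), `annotations`,
#'   `truth` (per-cell planted labels: cluster, group, identity and bin,
#'   isotype class and subclass, clone id and size, contaminant flag),
#'   `injection_log`, `profile`, and `donors`.
#' @export
generate_cohort <- function(profile = default_profile(), seed = 1L,
                            out_dir = NULL, expression = TRUE) {
  set.seed(seed)
  n_donors <- profile$n_donors
  donors <- paste0("donor", seq_len(n_donors))
  n_each <- diff(round(seq(0, profile$n_cells, length.out = n_donors + 1)))

  donor_data <- lapply(seq_len(n_donors), function(i) {
    .generate_donor(profile, donors[[i]], n_each[[i]])
  })
  names(donor_data) <- donors

  expr <- if (expression) .generate_expression(profile, donor_data) else NULL

  out <- list(
    contigs = dplyr::bind_rows(lapply(donor_data, `[[`, "contigs")),
    expression = expr,
    annotations = dplyr::bind_rows(lapply(donor_data, `[[`, "annotations")),
    truth = dplyr::bind_rows(lapply(donor_data, `[[`, "truth")),
    injection_log = dplyr::bind_rows(lapply(donor_data, `[[`, "injection_log")),
    profile = profile,
    donors = donors
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_profile(profile, file.path(out_dir, "profile.json"))
    for (d in donors) {
      ddir <- file.path(out_dir, d)
      dir.create(ddir, showWarnings = FALSE, recursive = TRUE)
      write_contig_table(donor_data[[d]]$contigs,
                         file.path(ddir, "contigs.csv"))
      readr::write_tsv(donor_data[[d]]$annotations,
                       file.path(ddir, "annotations.tsv"), progress = FALSE)
      if (!is.null(expr)) {
        write_expression_matrix(expr[[d]], file.path(ddir, "expression"))
      }
    }
  }
  out
}
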