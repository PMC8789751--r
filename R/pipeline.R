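#' Run the full repertoire analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> qc -> clonotypes -> enrichment -> differential
#' expression -> dot-plot -> report, writing every stage output as TSV
#' into `out_dir` together with a machine-readable JSON run manifest
#' (seed, row counts, audit counters, file digests). Deterministic given
#' `seed`: re-running with identical configuration reproduces identical
#' output digests.
#'
#' @param out_dir Output directory (created if absent).
#' @param profile Cohort profile; defaults to [default_profile()].
#' @param seed Integer RNG seed.
#' @param de_groups Which cell dichotomy to test for differential
#'   expression: high (>= 98%) vs low (< 96%) germline identity
#'   (`"identity_high_vs_low"`) or IGHM vs IGHG (`"isotype_m_vs_g"`).
#' @param de_within Restrict the DE comparison to one major group
#'   (DZ, LZ, MP or PBL) or `"all"`.
#' @return The run manifest, invisibly, as a list.
#' @export
run_pipeline <- function(out_dir, profile = default_profile(), seed = 1L,
                         de_groups = c("identity_high_vs_low", "isotype_m_vs_g"),
                         de_within = "all") {
  de_groups <- match.arg(de_groups)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  outputs <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    write_result_table(x, path)
    outputs[[name]] <<- unname(tools::md5sum(path))
    path
  }

  cohort <- generate_cohort(profile, seed = seed)
  expressed <- unlist(lapply(cohort$expression, rownames), use.names = FALSE)

  cells <- filter_paired_cells(cohort$contigs, expressed,
                               annotations = cohort$annotations)
  emit(cells, "cells.tsv")

  clones <- call_clonotypes(cells)
  het <- clone_isotype_heterogeneity(clones)
  clone_tab <- clones[, setdiff(names(clones), "members")]
  emit(clone_tab, "clones.tsv")
  emit(clone_size_summary(clones)[, c("donor", "n_clonotypes", "n_cells",
                                      "singleton_cell_fraction", "max_clone_size")],
       "clone_summary.tsv")

  enr_id <- categorical_enrichment_by_cluster(cells, "identity_bin")
  enr_iso <- categorical_enrichment_by_cluster(cells, "isotype_class")
  emit(enr_id$enrichment, "enrichment_identity_bin.tsv")
  emit(enr_id$composition, "composition_identity_bin.tsv")
  emit(enr_iso$enrichment, "enrichment_isotype_class.tsv")
  emit(enr_iso$composition, "composition_isotype_class.tsv")

  norm <- do.call(rbind, lapply(cohort$expression, normalize_counts))
  if (de_within != "all") {
    in_scope <- cells$group == de_within
  } else {
    in_scope <- rep(TRUE, nrow(cells))
  }
  if (de_groups == "identity_high_vs_low") {
    a <- cells$barcode[in_scope & cells$germline_identity_pct >= 98]
    b <- cells$barcode[in_scope & cells$germline_identity_pct < 96]
  } else {
    a <- cells$barcode[in_scope & cells$isotype_class == "IGHM"]
    b <- cells$barcode[in_scope & cells$isotype_class == "IGHG"]
  }
  de <- differential_expression(norm, a, b)
  emit(de, "differential_expression.tsv")

  panel <- names(profile$expression_model$hallmark)
  kept_norm <- norm[cells$barcode, , drop = FALSE]
  dots <- dotplot_summary(kept_norm, panel, cells$cluster)
  emit(dots, "dotplot.tsv")

  # report: repertoire composition by major group and the >=98 / <98 split
  strat <- cells |>
    dplyr::mutate(identity_stratum = ifelse(.data$germline_identity_pct >= 98,
                                            "ge98", "lt98")) |>
    dplyr::count(.data$group, .data$identity_stratum, .data$isotype_class) |>
    dplyr::group_by(.data$group, .data$identity_stratum) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  emit(strat, "report_isotype_by_identity_stratum.tsv")

  manifest <- list(
    command = "run_pipeline",
    seed = seed,
    tool_version = as.character(utils::packageVersion("gcrepertoire")),
    n_cells_simulated = profile$n_cells,
    qc_audit = as.list(qc_audit(cells)),
    n_cells_kept = nrow(cells),
    n_clonotypes = nrow(clones),
    clone_heterogeneity_fraction = het$fraction,
    outputs = as.list(outputs),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
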