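#' The 14 germinal center cluster labels
#'
#' Cluster labels used throughout the pipeline: three dark zone (DZ)
#' clusters, four intermediate (INT) clusters, three light zone (LZ)
#' clusters, the FCRL2/3 cluster, memory precursors (PreM) and two
#' plasmablast (PBL) clusters.
#'
#' @return Character vector of cluster labels.
#' @export
gc_clusters <- function() {
  c("DZ-1", "DZ-2", "DZ-3", "INT-1", "INT-2", "INT-3", "INT-4",
    "LZ-1", "LZ-2", "LZ-3", "FCRL2/3", "PreM", "PBL-1", "PBL-2")
}

#' Default cluster-to-group mapping
#'
#' Clusters are organized into four major groups: "DZ" (all DZ clusters
#' plus the DZ re-entry INT-1 cluster), "LZ" (the LZ-like INT-2 and INT-4
#' clusters and all LZ clusters), "MP" (memory precursors: INT-3, PreM and
#' FCRL2/3) and "PBL" (PBL-1 and PBL-2).
#'
#' @return Named character vector cluster -> group.
#' @export
default_cluster_groups <- function() {
  c("DZ-1" = "DZ", "DZ-2" = "DZ", "DZ-3" = "DZ", "INT-1" = "DZ",
    "INT-2" = "LZ", "INT-4" = "LZ", "LZ-1" = "LZ", "LZ-2" = "LZ",
    "LZ-3" = "LZ",
    "INT-3" = "MP", "PreM" = "MP", "FCRL2/3" = "MP",
    "PBL-1" = "PBL", "PBL-2" = "PBL")
}

#' Map cluster labels to major GC groups
#'
#' @param cluster Character vector of cluster labels.
#' @param group_map Named vector cluster -> group; defaults to
#'   [default_cluster_groups()].
#' @return Character vector of group labels (DZ, LZ, MP or PBL).
#' @export
assign_cluster_groups <- function(cluster, group_map = default_cluster_groups()) {
  out <- unname(group_map[cluster])
  bad <- unique(cluster[is.na(out) & !is.na(cluster)])
  if (length(bad) > 0) {
    stop("unknown cluster label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Collapse an IGH constant-gene call to its isotype class
#'
#' IGHG1-IGHG4 collapse to IGHG, IGHA1-IGHA2 to IGHA; IGHM and IGHE map to
#' themselves. IGHD carriers are removed upstream by the QC filter and are
#' rejected here.
#'
#' @param c_gene Character vector of heavy-chain constant gene calls.
#' @return Character vector over `{IGHM, IGHG, IGHA, IGHE}`.
#' @export
assign_isotype_class <- function(c_gene) {
  map <- c(IGHM = "IGHM", IGHE = "IGHE",
           IGHG1 = "IGHG", IGHG2 = "IGHG", IGHG3 = "IGHG", IGHG4 = "IGHG",
           IGHA1 = "IGHA", IGHA2 = "IGHA")
  out <- unname(map[c_gene])
  bad <- unique(c_gene[is.na(out)])
  if (length(bad) > 0) {
    stop("cannot classify constant gene(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Combine heavy- and light-chain germline identities
#'
#' Per-cell germline identity is the unweighted arithmetic mean of the
#' heavy- and light-chain V-region identities (the default combiner).
#'
#' @param heavy_pct,light_pct Numeric vectors of per-chain V-region
#'   germline identity percentages in \[0, 100\].
#' @return Numeric vector of combined identities, full precision.
#' @export
combined_germline_identity <- function(heavy_pct, light_pct) {
  if (any(heavy_pct < 0 | heavy_pct > 100 | light_pct < 0 | light_pct > 100,
          na.rm = TRUE)) {
    stop("germline identity must lie in [0, 100]", call. = FALSE)
  }
  (heavy_pct + light_pct) / 2
}

#' Identity bin labels, from unmutated to heavily mutated
#'
#' @return Character vector `c("B100","B98","B96","B94","B_LT94")`.
#' @export
identity_bin_levels <- function() c("B100", "B98", "B96", "B94", "B_LT94")

#' Bin combined germline identity into five mutational-load subgroups
#'
#' The five bins partition \[0, 100\]: `B100` holds exactly 100%
#' (unmutated), `B98` = \[98, 100), `B96` = \[96, 98), `B94` = \[94, 96),
#' `B_LT94` = below 94 (heavily mutated). Boundaries are left-closed, so
#' the textual "high identity (>98%)" stratum is `B100` plus `B98` and
#' "mutated (<98%)" is the union of the three lowest bins.
#'
#' @param pct Numeric vector of combined germline identity percentages.
#' @return Factor with levels [identity_bin_levels()].
#' @export
bin_germline_identity <- function(pct) {
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    stop("germline identity must lie in [0, 100]", call. = FALSE)
  }
  bin <- ifelse(pct == 100, "B100",
         ifelse(pct >= 98, "B98",
         ifelse(pct >= 96, "B96",
         ifelse(pct >= 94, "B94", "B_LT94"))))
  factor(bin, levels = identity_bin_levels())
}

.audit_counter_names <- c(
  "input_barcodes", "missing_expression", "no_eligible_heavy",
  "multiple_eligible_heavy", "no_eligible_light", "multiple_eligible_light",
  "empty_heavy_c_gene", "ighd_heavy", "kept")

#' Filter contigs into QC-passing paired cells
#'
#' Applies the secondary cell filter: a barcode is kept only if (a) it has
#' expression data, (b) after per-contig eligibility filtering (productive,
#' full length, high confidence and a UMI count strictly greater than
#' `umi_min - 1`) exactly one heavy (IGH) and exactly one light (IGK or
#' IGL) contig remain, and (c) the heavy constant gene is present and is
#' not IGHD. Cells failing a rule are silently dropped; per-rule drop
#' counts are returned in the `audit` attribute (first failing rule in the
#' order missing expression, heavy count, light count, missing constant
#' gene, IGHD).
#'
#' @param contigs Contig tibble (see [read_contig_table()]); may pool
#'   donors, grouping is by (donor, barcode).
#' @param expressed_barcodes Character vector of barcodes present in the
#'   expression matrix.
#' @param annotations Optional annotation tibble with `barcode`, `donor`,
#'   `cluster` columns; when given, `cluster` and `group` are attached.
#' @param umi_min Minimum UMI count per chain; the default 4 implements
#'   the strict "greater than 3" threshold. Applies to both chains unless
#'   `umi_chains = "heavy"`.
#' @param umi_chains Apply the UMI threshold to `"both"` chains (default)
#'   or the `"heavy"` chain only.
#' @param identity_combine Function combining heavy and light identity
#'   into the per-cell value; defaults to [combined_germline_identity()].
#' @param group_map Cluster-to-group mapping for annotation.
#' @return Tibble of paired cells (one row per kept cell, in first-contig
#'   input order) with columns barcode, donor, isotype_subclass,
#'   isotype_class, heavy_v/d/j, light_v/j, cdr3_nt_heavy, cdr3_nt_light,
#'   umis_heavy, umis_light, identity_heavy, identity_light,
#'   germline_identity_pct, identity_bin, and (if annotated) cluster and
#'   group. The `audit` attribute carries the drop-reason counters; see
#'   [qc_audit()].
#' @export
filter_paired_cells <- function(contigs, expressed_barcodes,
                                annotations = NULL,
                                umi_min = 4L,
                                umi_chains = c("both", "heavy"),
                                identity_combine = combined_germline_identity,
                                group_map = default_cluster_groups()) {
  umi_chains <- match.arg(umi_chains)
  audit <- setNames(integer(length(.audit_counter_names)), .audit_counter_names)

  key <- paste(contigs$donor, contigs$barcode, sep = "\r")
  first_seen <- !duplicated(key)
  cell_key <- key[first_seen]
  cell_barcode <- contigs$barcode[first_seen]
  cell_donor <- contigs$donor[first_seen]
  audit[["input_barcodes"]] <- length(cell_key)

  flags_ok <- contigs$productive & contigs$full_length & contigs$high_confidence
  is_heavy <- contigs$chain == "IGH"
  is_light <- contigs$chain %in% c("IGK", "IGL")
  umi_ok <- if (umi_chains == "both") contigs$umis >= umi_min
            else (!is_heavy) | (contigs$umis >= umi_min)
  eligible <- flags_ok & umi_ok & (is_heavy | is_light)

  fkey <- factor(key, levels = cell_key)
  n_heavy <- as.integer(table(fkey[eligible & is_heavy]))
  n_light <- as.integer(table(fkey[eligible & is_light]))

  expressed <- cell_barcode %in% expressed_barcodes
  drop_reason <- rep(NA_character_, length(cell_key))
  drop_reason[!expressed] <- "missing_expression"
  todo <- is.na(drop_reason)
  drop_reason[todo & n_heavy == 0] <- "no_eligible_heavy"
  todo <- is.na(drop_reason)
  drop_reason[todo & n_heavy > 1] <- "multiple_eligible_heavy"
  todo <- is.na(drop_reason)
  drop_reason[todo & n_light == 0] <- "no_eligible_light"
  todo <- is.na(drop_reason)
  drop_reason[todo & n_light > 1] <- "multiple_eligible_light"

  cand <- which(is.na(drop_reason))
  heavy_idx <- match(cell_key[cand], key[eligible & is_heavy])
  light_idx <- match(cell_key[cand], key[eligible & is_light])
  h <- contigs[which(eligible & is_heavy)[heavy_idx], ]
  l <- contigs[which(eligible & is_light)[light_idx], ]

  empty_c <- !nzchar(h$c_gene)
  drop_reason[cand[empty_c]] <- "empty_heavy_c_gene"
  ighd <- !empty_c & h$c_gene == "IGHD"
  drop_reason[cand[ighd]] <- "ighd_heavy"

  keep <- !empty_c & !ighd
  h <- h[keep, ]
  l <- l[keep, ]

  combined <- identity_combine(h$v_identity_pct, l$v_identity_pct)
  cells <- tibble::tibble(
    barcode = h$barcode,
    donor = h$donor,
    isotype_subclass = h$c_gene,
    isotype_class = assign_isotype_class(h$c_gene),
    heavy_v = h$v_gene, heavy_d = h$d_gene, heavy_j = h$j_gene,
    light_v = l$v_gene, light_j = l$j_gene,
    cdr3_nt_heavy = h$cdr3_nt, cdr3_nt_light = l$cdr3_nt,
    umis_heavy = h$umis, umis_light = l$umis,
    identity_heavy = h$v_identity_pct,
    identity_light = l$v_identity_pct,
    germline_identity_pct = combined,
    identity_bin = bin_germline_identity(combined)
  )

  if (!is.null(annotations)) {
    akey <- paste(annotations$donor, annotations$barcode, sep = "\r")
    ckey <- paste(cells$donor, cells$barcode, sep = "\r")
    cells$cluster <- annotations$cluster[match(ckey, akey)]
    ok <- !is.na(cells$cluster)
    grp <- rep(NA_character_, nrow(cells))
    grp[ok] <- assign_cluster_groups(cells$cluster[ok], group_map)
    cells$group <- grp
  }

  tab <- table(factor(drop_reason, levels = .audit_counter_names))
  for (nm in names(tab)) audit[[nm]] <- audit[[nm]] + as.integer(tab[[nm]])
  audit[["kept"]] <- nrow(cells)
  attr(cells, "audit") <- audit
  cells
}

#' Drop-reason audit counters of a QC run
#'
#' @param cells Result of [filter_paired_cells()].
#' @return Named integer vector of per-rule drop counts plus
#'   `input_barcodes` and `kept`; the drop reasons and `kept` sum to
#'   `input_barcodes`.
#' @export
qc_audit <- function(cells) attr(cells, "audit")
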