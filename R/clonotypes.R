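#' Call clonotypes from paired cells
#'
#' Groups cells into clonotypes per donor. Two cells belong to the same
#' clonotype when they share (i) the same called V(D)J gene segments
#' (heavy V/D/J and light V/J, gene-level string equality; an empty D
#' call matches an empty D call) and (ii) the identical concatenated
#' heavy+light CDR3 nucleotide sequence. Grouping is strictly per donor.
#' Clone ids are assigned deterministically as `<donor>_clone<k>` with `k`
#' ordered by descending clone size, then lexicographic key, so permuting
#' the input leaves memberships and ids unchanged.
#'
#' @param cells Paired-cell tibble from [filter_paired_cells()].
#' @return Tibble with one row per clonotype: `clone_id`, `donor`,
#'   `size`, `n_isotype_classes`, `isotype_classes` (comma-joined sorted
#'   class set), key fields (`heavy_v`, `heavy_d`, `heavy_j`, `light_v`,
#'   `light_j`, `cdr3_concat`), and `members` (list column of barcodes).
#'   The `cell_clones` attribute maps each input cell (by row) to its
#'   `clone_id`.
#' @export
call_clonotypes <- function(cells) {
  key <- paste(cells$heavy_v, cells$heavy_d, cells$heavy_j,
               cells$light_v, cells$light_j,
               paste0(cells$cdr3_nt_heavy, cells$cdr3_nt_light),
               sep = "|")
  full <- paste(cells$donor, key, sep = "\r")
  clones <- tibble::tibble(
    donor = cells$donor, key = key, full = full,
    barcode = cells$barcode, isotype_class = cells$isotype_class
  )
  agg <- clones |>
    dplyr::group_by(.data$donor, .data$key, .data$full) |>
    dplyr::summarise(
      size = dplyr::n(),
      members = list(.data$barcode),
      isotype_set = list(sort(unique(.data$isotype_class))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$donor, dplyr::desc(.data$size), .data$key) |>
    dplyr::group_by(.data$donor) |>
    dplyr::mutate(clone_id = paste0(.data$donor, "_clone", dplyr::row_number())) |>
    dplyr::ungroup()

  kf <- strsplit(agg$key, "|", fixed = TRUE)
  # cdr3 concat never empty; V/D/J fields may be; strsplit drops trailing
  # empties, so pad defensively
  kf <- lapply(kf, function(f) c(f, rep("", 6 - length(f)))[1:6])
  out <- tibble::tibble(
    clone_id = agg$clone_id,
    donor = agg$donor,
    size = as.integer(agg$size),
    n_isotype_classes = vapply(agg$isotype_set, length, integer(1)),
    isotype_classes = vapply(agg$isotype_set, paste, character(1), collapse = ","),
    heavy_v = vapply(kf, `[[`, character(1), 1),
    heavy_d = vapply(kf, `[[`, character(1), 2),
    heavy_j = vapply(kf, `[[`, character(1), 3),
    light_v = vapply(kf, `[[`, character(1), 4),
    light_j = vapply(kf, `[[`, character(1), 5),
    cdr3_concat = vapply(kf, `[[`, character(1), 6),
    members = agg$members
  )
  attr(out, "cell_clones") <- out$clone_id[match(full, agg$full)]
  out
}

#' Per-cell clone assignments of a clonotype call
#'
#' @param clonotypes Result of [call_clonotypes()].
#' @return Character vector of clone ids, parallel to the `cells` input
#'   rows of the call.
#' @export
cell_clone_ids <- function(clonotypes) attr(clonotypes, "cell_clones")

#' Summarize clone sizes per donor
#'
#' @param clonotypes Result of [call_clonotypes()].
#' @return Tibble with one row per donor: number of clonotypes, number of
#'   cells, fraction of cells in singleton clonotypes, maximum clone size,
#'   and a list-column `size_histogram` (table of clone sizes).
#' @export
clone_size_summary <- function(clonotypes) {
  stopifnot(nrow(clonotypes) > 0)
  clonotypes |>
    dplyr::group_by(.data$donor) |>
    dplyr::summarise(
      n_clonotypes = dplyr::n(),
      n_cells = sum(.data$size),
      singleton_cell_fraction = sum(.data$size[.data$size == 1]) / sum(.data$size),
      max_clone_size = max(.data$size),
      size_histogram = list(table(.data$size)),
      .groups = "drop"
    )
}

#' Score intraclonal isotype heterogeneity
#'
#' Among clonotypes with at least `min_size` member cells, computes the
#' fraction whose members span two or more isotype *classes* (IGHM, IGHG,
#' IGHA, IGHE). Subclass differences (e.g. IGHG1 vs IGHG2) are not
#' heterogeneity at the default class level; set `level = "subclass"` to
#' distinguish them (requires `cells` for subclass lookup).
#'
#' @param clonotypes Result of [call_clonotypes()].
#' @param min_size Minimum clone size considered (default 5; must be >= 2).
#' @param level `"class"` (default) or `"subclass"`.
#' @param cells Paired-cell tibble; required for `level = "subclass"`.
#' @return List with `fraction` (NA with a zero `n_eligible` when no clone
#'   reaches `min_size`), `n_eligible`, `n_heterogeneous`, and `flags`, a
#'   tibble of eligible clones with a logical `heterogeneous` column.
#' @export
clone_isotype_heterogeneity <- function(clonotypes, min_size = 5L,
                                        level = c("class", "subclass"),
                                        cells = NULL) {
  level <- match.arg(level)
  stopifnot(min_size >= 2)
  eligible <- clonotypes[clonotypes$size >= min_size, , drop = FALSE]
  if (nrow(eligible) == 0) {
    return(list(fraction = NA_real_, n_eligible = 0L, n_heterogeneous = 0L,
                flags = tibble::tibble(clone_id = character(0), donor = character(0),
                                       size = integer(0), heterogeneous = logical(0))))
  }
  if (level == "class") {
    het <- eligible$n_isotype_classes >= 2
  } else {
    if (is.null(cells)) stop("subclass-level scoring requires `cells`", call. = FALSE)
    assign <- cell_clone_ids(clonotypes)
    if (is.null(assign) || length(assign) != nrow(cells)) {
      stop("`cells` does not match the clonotype call", call. = FALSE)
    }
    nsub <- tapply(cells$isotype_subclass, assign, function(x) length(unique(x)))
    het <- unname(nsub[eligible$clone_id]) >= 2
  }
  list(
    fraction = mean(het),
    n_eligible = nrow(eligible),
    n_heterogeneous = sum(het),
    flags = tibble::tibble(clone_id = eligible$clone_id, donor = eligible$donor,
                           size = eligible$size, heterogeneous = het)
  )
}
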