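#' @importFrom rlang .data
#' @importFrom stats median p.adjust phyper quantile rbinom rgeom rnbinom
#'   rpois runif sd setNames wilcox.test
#' @importFrom utils head
NULL

#' Default column mapping for 10x-style contig annotation tables
#'
#' Maps the fields of the internal contig data model to the column names of
#' a `filtered_contig_annotations.csv`-style file. The per-chain V-region
#' germline identity column (`v_identity`) is an extension column: Cell
#' Ranger does not emit it, so it may instead be supplied as a separate
#' table via the `identity_table` argument of [read_contig_table()].
#'
#' @return Named character vector mapping internal field -> file column.
#' @export
contig_column_map <- function() {
  c(
    barcode         = "barcode",
    chain           = "chain",
    v_gene          = "v_gene",
    d_gene          = "d_gene",
    j_gene          = "j_gene",
    c_gene          = "c_gene",
    cdr3_nt         = "cdr3_nt",
    productive      = "productive",
    full_length     = "full_length",
    high_confidence = "high_confidence",
    umis            = "umis",
    v_identity      = "v_identity_pct"
  )
}

.parse_flag <- function(x, column, path) {
  out <- rep(NA, length(x))
  lx <- tolower(trimws(as.character(x)))
  out[lx %in% "true"] <- TRUE
  out[lx %in% "false"] <- FALSE
  bad <- which(is.na(out) & !is.na(x) & nzchar(lx))
  if (length(bad) > 0) {
    stop(sprintf("unparsable boolean in column '%s' of %s (row %d: '%s')",
                 column, path, bad[1], x[bad[1]]), call. = FALSE)
  }
  as.logical(out)
}

#' Read a V(D)J contig annotation table
#'
#' Parses a 10x-style contig annotation CSV (one row per assembled contig)
#' into the pipeline's contig data model. Boolean flag columns accept
#' `True/False`, `TRUE/FALSE` and `true/false`. Missing gene calls are
#' stored as empty strings. Donor identity is supplied per file and never
#' inferred from barcode suffixes; barcodes are opaque strings.
#'
#' @param path Path to the CSV file (header row required).
#' @param donor Donor identifier attached to every contig of this file.
#' @param column_map Named character vector mapping internal field names to
#'   file column names; see [contig_column_map()].
#' @param identity_table Optional data frame with columns `barcode`,
#'   `chain`, `v_identity_pct` supplying per-chain germline identity when
#'   the contig file lacks the identity extension column.
#' @return A tibble with one row per contig and columns `barcode`, `donor`,
#'   `chain`, `v_gene`, `d_gene`, `j_gene`, `c_gene`, `cdr3_nt`,
#'   `productive`, `full_length`, `high_confidence`, `umis`,
#'   `v_identity_pct`.
#' @export
read_contig_table <- function(path, donor, column_map = contig_column_map(),
                              identity_table = NULL) {
  if (!file.exists(path)) stop("contig table not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- setdiff(names(column_map), "v_identity")
  if (!is.null(identity_table)) {
    needed <- column_map[required]
  } else {
    needed <- column_map
  }
  missing <- needed[!needed %in% names(raw)]
  if (length(missing) > 0) {
    stop(sprintf("contig table %s is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(raw)
  chr <- function(field) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw)) return(rep("", n))
    x <- raw[[col]]
    x[is.na(x)] <- ""
    x
  }
  umis_raw <- chr("umis")
  umis <- suppressWarnings(as.integer(umis_raw))
  bad <- which(is.na(umis) | umis < 0)
  if (length(bad) > 0) {
    stop(sprintf("unparsable UMI count in %s at row %d: '%s'",
                 path, bad[1], umis_raw[bad[1]]), call. = FALSE)
  }
  contigs <- tibble::tibble(
    barcode = chr("barcode"),
    donor = as.character(donor),
    chain = chr("chain"),
    v_gene = chr("v_gene"),
    d_gene = chr("d_gene"),
    j_gene = chr("j_gene"),
    c_gene = chr("c_gene"),
    cdr3_nt = chr("cdr3_nt"),
    productive = .parse_flag(chr("productive"), column_map[["productive"]], path),
    full_length = .parse_flag(chr("full_length"), column_map[["full_length"]], path),
    high_confidence = .parse_flag(chr("high_confidence"), column_map[["high_confidence"]], path),
    umis = umis
  )
  if (is.null(identity_table)) {
    ident <- suppressWarnings(as.numeric(chr("v_identity")))
  } else {
    stopifnot(all(c("barcode", "chain", "v_identity_pct") %in% names(identity_table)))
    key <- paste(contigs$barcode, contigs$chain, sep = "\r")
    tkey <- paste(identity_table$barcode, identity_table$chain, sep = "\r")
    ident <- identity_table$v_identity_pct[match(key, tkey)]
  }
  if (any(!is.na(ident) & (ident < 0 | ident > 100))) {
    stop("v_identity_pct outside [0, 100] in ", path, call. = FALSE)
  }
  contigs$v_identity_pct <- ident
  contigs
}

#' Write a contig annotation table
#'
#' Writes contigs in the canonical CSV dialect consumed by
#' [read_contig_table()]. Booleans are written as `True`/`False` as in 10x
#' output.
#'
#' @param contigs Contig tibble as returned by [read_contig_table()].
#' @param path Output CSV path.
#' @param column_map Column mapping, see [contig_column_map()].
#' @return `path`, invisibly.
#' @export
write_contig_table <- function(contigs, path, column_map = contig_column_map()) {
  out <- tibble::tibble(
    barcode = contigs$barcode,
    chain = contigs$chain,
    v_gene = contigs$v_gene,
    d_gene = contigs$d_gene,
    j_gene = contigs$j_gene,
    c_gene = contigs$c_gene,
    cdr3_nt = contigs$cdr3_nt,
    productive = ifelse(contigs$productive, "True", "False"),
    full_length = ifelse(contigs$full_length, "True", "False"),
    high_confidence = ifelse(contigs$high_confidence, "True", "False"),
    umis = contigs$umis,
    v_identity_pct = contigs$v_identity_pct
  )
  names(out) <- unname(column_map[c("barcode", "chain", "v_gene", "d_gene",
                                    "j_gene", "c_gene", "cdr3_nt", "productive",
                                    "full_length", "high_confidence", "umis",
                                    "v_identity")])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sparse expression matrix with barcode/feature sidecars
#'
#' Reads a MatrixMarket coordinate integer matrix plus its `barcodes.tsv`
#' and `features.tsv` sidecars into a cells x genes sparse count matrix.
#' The on-disk orientation is inferred from the sidecar lengths: a
#' genes x cells matrix (the 10x convention) is transposed on read, so the
#' returned object is always cells x genes. Feature files with 2 or 3
#' columns use the second column (gene symbol); duplicated symbols are
#' disambiguated with numeric suffixes (`.1`, `.2`, ...).
#'
#' @param mtx_path Path to the MTX file.
#' @param barcodes_path Path to the barcode list (one per line).
#' @param features_path Path to the feature list (1-3 tab-separated columns).
#' @return A `dgCMatrix` with barcodes as rownames and gene symbols as
#'   colnames.
#' @export
read_expression_matrix <- function(mtx_path, barcodes_path, features_path) {
  m <- Matrix::readMM(mtx_path)
  if (methods::is(m, "nMatrix")) m <- methods::as(m, "dMatrix")
  barcodes <- readr::read_lines(barcodes_path, progress = FALSE)
  feat_lines <- readr::read_lines(features_path, progress = FALSE)
  feat_fields <- strsplit(feat_lines, "\t", fixed = TRUE)
  genes <- vapply(feat_fields, function(f) if (length(f) >= 2) f[[2]] else f[[1]],
                  character(1))
  nb <- length(barcodes)
  ng <- length(genes)
  if (nrow(m) == nb && ncol(m) == ng) {
    # already cells x genes
  } else if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "matrix dimensions %d x %d match neither %d barcodes x %d features nor the transpose",
      nrow(m), ncol(m), nb, ng), call. = FALSE)
  }
  if (any(m@x < 0) || any(m@x != round(m@x))) {
    stop("expression matrix must contain non-negative integer counts", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in ", barcodes_path, call. = FALSE)
  genes <- make.unique(genes, sep = ".")
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(barcodes, genes)
  m
}

#' Write a sparse expression matrix with sidecars
#'
#' Writes a cells x genes count matrix in the 10x on-disk convention
#' (genes x cells MTX plus `barcodes.tsv` and `features.tsv`).
#'
#' @param counts Cells x genes sparse matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_expression_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(counts), file.path(dir, "matrix.mtx"))
  readr::write_lines(rownames(counts), file.path(dir, "barcodes.tsv"))
  genes <- colnames(counts)
  readr::write_lines(paste(genes, genes, "Gene Expression", sep = "\t"),
                     file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read per-cell annotations
#'
#' Reads a TSV with header columns `barcode`, `donor`, optionally
#' `sorted_fraction`, and `cluster`.
#'
#' @param path TSV path.
#' @return Tibble of annotations; errors if a (donor, barcode) pair occurs
#'   more than once.
#' @export
read_cell_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("barcode", "donor") %in% names(ann))) {
    stop("annotation table must contain 'barcode' and 'donor' columns", call. = FALSE)
  }
  if (anyDuplicated(paste(ann$donor, ann$barcode, sep = "\r"))) {
    stop("duplicate (donor, barcode) pair in ", path, call. = FALSE)
  }
  ann
}

#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`; the
#' description is dropped, empty gene fields are skipped, and genes are
#' de-duplicated within a set preserving first occurrence. Duplicate set
#' names are an error.
#'
#' @param path GMT file path.
#' @return A list with elements `sets` (named list of character vectors)
#'   and `source` (the file name).
#' @export
read_gene_sets <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    name <- fields[[1]]
    if (name %in% names(sets)) {
      stop("duplicate gene-set name in GMT: ", name, call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(genes)]
    if (length(genes) == 0) {
      stop(sprintf("GMT set '%s' (line %d) is empty", name, i), call. = FALSE)
    }
    sets[[name]] <- genes
  }
  list(sets = sets, source = basename(path))
}

#' Write a result table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
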