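#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects a Matrix Market file plus gene and barcode TSVs (first column
#' used as identifier). Row/column counts must match the triplet header.
#'
#' @param dir directory containing the three files.
#' @param matrix_file,features_file,barcodes_file file names inside `dir`.
#' @return a [gene_matrix()] with `kind = "raw_counts"`.
#' @export
read_matrix_market <- function(dir, matrix_file = "matrix.mtx",
                               features_file = "features.tsv",
                               barcodes_file = "barcodes.tsv") {
  paths <- file.path(dir, c(matrix_file, features_file, barcodes_file))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing file(s): ", paste(missing, collapse = ", "))
  m <- Matrix::readMM(paths[1])
  genes <- read.delim(paths[2], header = FALSE,
                      colClasses = "character")[[1]]
  units <- read.delim(paths[3], header = FALSE,
                      colClasses = "character")[[1]]
  if (length(genes) != nrow(m))
    stop(sprintf("format error: %d features listed but matrix has %d rows",
                 length(genes), nrow(m)))
  if (length(units) != ncol(m))
    stop(sprintf("format error: %d barcodes listed but matrix has %d columns",
                 length(units), ncol(m)))
  gene_matrix(as.matrix(m), genes, units, kind = "raw_counts")
}

#' Write a gene matrix as a Matrix Market triplet directory
#'
#' @param m a [gene_matrix()] with raw counts.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_matrix_market <- function(m, dir) {
  stopifnot(inherits(m, "gene_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(dir, "features.tsv"))
  writeLines(m$unit_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense expression table (TSV/CSV)
#'
#' First column holds gene ids (or unit ids, per `orientation`); the body
#' must be numeric. Duplicated gene ids are retained verbatim (probe
#' tables) and flagged in the `"duplicate_gene_ids"` attribute; collapse
#' them with [collapse_probes()].
#'
#' @param path file path; `.csv` is comma-separated, anything else tab.
#' @param kind declared value kind (see [gene_matrix()]).
#' @param orientation `"genes_in_rows"` (default) or `"units_in_rows"`.
#' @return a [gene_matrix()].
#' @export
read_dense_table <- function(path, kind = "raw_counts",
                             orientation = c("genes_in_rows", "units_in_rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character")
  ids <- raw[[1]]
  body <- raw[-1]
  num <- vapply(body, function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(raw)))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(raw),
                                     dimnames = list(NULL, names(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("parse error: non-numeric value at row %d, column '%s'",
                 bad[1, 1], colnames(num)[bad[1, 2]]))
  if (orientation == "units_in_rows") {
    num <- t(num)
    gene_matrix(num, colnames(body), ids, kind = kind,
                allow_duplicate_genes = TRUE)
  } else {
    gene_matrix(num, ids, colnames(body), kind = kind,
                allow_duplicate_genes = TRUE)
  }
}

#' Write a gene matrix as a dense TSV (genes in rows)
#'
#' @param m a [gene_matrix()].
#' @param path output path.
#' @param id_column header name of the identifier column.
#' @return `path`, invisibly.
#' @export
write_dense_table <- function(m, path, id_column = "gene") {
  stopifnot(inherits(m, "gene_matrix"))
  df <- data.frame(m$gene_ids, m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_column, m$unit_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene symbols
#'
#' Probes absent from the map are dropped (a warning reports how many).
#' `method = "mean"` averages all probe rows of a symbol;
#' `method = "max_mean_probe"` keeps the single probe with the highest
#' row mean (ties broken by first occurrence).
#'
#' @param m a [gene_matrix()] whose gene ids are probe ids.
#' @param probe_map data.frame with columns `probe`, `symbol`; each probe
#'   must map to exactly one symbol.
#' @param method collapse rule.
#' @return a [gene_matrix()] with one row per symbol (first-appearance order).
#' @export
collapse_probes <- function(m, probe_map, method = c("mean", "max_mean_probe")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "gene_matrix"),
            all(c("probe", "symbol") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe))
    stop("probe_map assigns some probe to multiple symbols")
  sym <- probe_map$symbol[match(m$gene_ids, probe_map$probe)]
  dropped <- sum(is.na(sym))
  if (dropped) warning(dropped, " probes absent from map were dropped")
  keep <- !is.na(sym)
  v <- m$values[keep, , drop = FALSE]
  sym <- sym[keep]
  sym_order <- unique(sym)
  if (method == "mean") {
    out <- rowsum(v, group = factor(sym, levels = sym_order)) /
      as.vector(table(factor(sym, levels = sym_order)))
  } else {
    rm_ <- rowMeans(v)
    pick <- vapply(sym_order, function(s) {
      idx <- which(sym == s)
      idx[which.max(rm_[idx])]
    }, integer(1))
    out <- v[pick, , drop = FALSE]
  }
  gene_matrix(as.matrix(out), sym_order, m$unit_ids, kind = m$kind)
}

#' Read a GMT geneset file
#'
#' Each line: set name, description, then tab-separated genes. Duplicate
#' genes within a line are removed preserving order.
#'
#' @param path GMT file path.
#' @return a named list of [gene_panel()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  panels <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d fields (need >= 3)", i, length(fields)))
    gene_panel(fields[1], fields[-(1:2)])
  })
  names(panels) <- vapply(panels, `[[`, character(1), "name")
  panels
}

#' Write gene panels as a GMT file
#'
#' @param panels a list of [gene_panel()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(panels, path) {
  lines <- vapply(panels, function(p)
    paste(c(p$name, "na", p$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an lncRNA-mRNA interaction table
#'
#' A TSV dump with one row per (lncRNA, target) pair and an interaction
#' count column; header names are configurable. Duplicated pairs resolve
#' to the maximum count with a warning; negative counts are rejected.
#'
#' @param path TSV path.
#' @param lncrna_col,mrna_col,count_col column names in the file.
#' @return data.frame with columns `lncrna`, `mrna`, `n_interactions`.
#' @export
read_interaction_table <- function(path, lncrna_col = "lncRNA",
                                   mrna_col = "target",
                                   count_col = "interactions") {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  needed <- c(lncrna_col, mrna_col, count_col)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("interaction table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  interaction_table(data.frame(lncrna = as.character(df[[lncrna_col]]),
                               mrna = as.character(df[[mrna_col]]),
                               n_interactions = df[[count_col]],
                               stringsAsFactors = FALSE))
}

#' Read a unit metadata TSV
#'
#' @param path TSV with at least `unit_id`, `dataset_id`, `condition`.
#' @return validated data.frame (see [validate_unit_meta()]).
#' @export
read_unit_meta <- function(path) {
  validate_unit_meta(read.delim(path, header = TRUE,
                                colClasses = "character"))
}
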