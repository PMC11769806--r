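#' Gene-by-unit expression matrix
#'
#' The central container of the package: a dense numeric matrix with genes
#' in rows and units (cells or samples) in columns, plus a declared value
#' kind. Raw counts must be non-negative integers; `lognorm` holds
#' log1p-transformed depth-normalized values; `intensity` holds
#' (linear-scale) microarray intensities.
#'
#' @param values numeric matrix, genes x units.
#' @param gene_ids character vector of gene symbols, one per row.
#' @param unit_ids character vector of unit identifiers, one per column.
#' @param kind one of `"raw_counts"`, `"lognorm"`, `"intensity"`.
#' @param allow_duplicate_genes keep duplicated gene ids (probe-level
#'   tables before collapsing). Duplicated ids are recorded in the
#'   `"duplicate_gene_ids"` attribute.
#' @return an object of class `gene_matrix`.
#' @export
gene_matrix <- function(values, gene_ids = rownames(values),
                        unit_ids = colnames(values),
                        kind = c("raw_counts", "lognorm", "intensity"),
                        allow_duplicate_genes = FALSE) {
  kind <- match.arg(kind)
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(gene_ids) || is.null(unit_ids))
    stop("gene_ids and unit_ids are required (or set as dimnames)")
  gene_ids <- as.character(gene_ids)
  unit_ids <- as.character(unit_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) != nrow(values)")
  if (length(unit_ids) != ncol(values))
    stop("length(unit_ids) != ncol(values)")
  if (anyNA(values)) stop("expression values contain NA/NaN")
  dup_report <- character(0)
  if (anyDuplicated(gene_ids)) {
    dup_report <- unique(gene_ids[duplicated(gene_ids)])
    if (!allow_duplicate_genes)
      stop("duplicate gene ids: ", paste(head(dup_report, 10), collapse = ", "))
  }
  if (anyDuplicated(unit_ids))
    stop("duplicate unit ids: ",
         paste(head(unique(unit_ids[duplicated(unit_ids)]), 10), collapse = ", "))
  if (kind == "raw_counts") {
    if (any(values < 0)) stop("raw_counts must be non-negative")
    if (max(abs(values - round(values))) > 1e-8)
      stop("raw_counts must be integers")
  }
  dimnames(values) <- list(gene_ids, unit_ids)
  structure(list(values = values, gene_ids = gene_ids, unit_ids = unit_ids,
                 kind = kind),
            duplicate_gene_ids = dup_report,
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("<gene_matrix> %d genes x %d units, kind = %s\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' @export
dim.gene_matrix <- function(x) dim(x$values)

#' Subset a gene matrix by genes and/or units
#'
#' @param m a [gene_matrix()].
#' @param genes,units character, integer or logical index; `NULL` keeps all.
#' @return a `gene_matrix`.
#' @export
gm_subset <- function(m, genes = NULL, units = NULL) {
  stopifnot(inherits(m, "gene_matrix"))
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(units)) v <- v[, units, drop = FALSE]
  gene_matrix(v, rownames(v), colnames(v), m$kind)
}

#' Validate a unit metadata table
#'
#' Requires columns `unit_id`, `dataset_id`, `condition`; optional
#' `donor_id`, `cluster_label`, `cell_type`. Conditions must come from
#' the recognised set (ND, preT2D, T2D, T1D). When `units` is supplied
#' the table must cover exactly those ids.
#'
#' @param meta a data.frame.
#' @param units optional character vector of expected unit ids.
#' @return the validated data.frame (invisibly usable downstream).
#' @export
validate_unit_meta <- function(meta, units = NULL) {
  required <- c("unit_id", "dataset_id", "condition")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("unit metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  meta$unit_id <- as.character(meta$unit_id)
  bad <- setdiff(unique(meta$condition), CONDITION_LEVELS)
  if (length(bad))
    stop("unknown condition labels: ", paste(bad, collapse = ", "))
  key <- paste(meta$dataset_id, meta$unit_id)
  if (anyDuplicated(key))
    stop("duplicate (dataset_id, unit_id) rows in metadata")
  if (!is.null(units)) {
    if (!setequal(meta$unit_id, units))
      stop("metadata unit_id set does not match matrix unit ids")
    meta <- meta[match(units, meta$unit_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

#' Named gene panel
#'
#' A named, non-empty list of unique gene symbols. Duplicates are removed
#' preserving first occurrence.
#'
#' @param name panel name.
#' @param genes character vector of gene symbols.
#' @return an object of class `gene_panel`.
#' @export
gene_panel <- function(name, genes) {
  genes <- as.character(genes)
  genes <- genes[!duplicated(genes)]
  if (!length(genes)) stop("gene panel '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %s: %d genes (%s%s)\n", x$name, length(x$genes),
              paste(head(x$genes, 5), collapse = ", "),
              if (length(x$genes) > 5) ", ..." else ""))
  invisible(x)
}

#' Normalize an lncRNA-mRNA interaction table
#'
#' Enforces non-negative interaction counts and resolves duplicated
#' (lncrna, mrna) pairs to the maximum count (conservative for a
#' count-threshold filter), with a warning.
#'
#' @param df data.frame with columns `lncrna`, `mrna`, `n_interactions`.
#' @return the deduplicated data.frame.
#' @export
interaction_table <- function(df) {
  required <- c("lncrna", "mrna", "n_interactions")
  if (!all(required %in% names(df)))
    stop("interaction table needs columns: ", paste(required, collapse = ", "))
  df$n_interactions <- as.numeric(df$n_interactions)
  if (anyNA(df$n_interactions)) stop("non-numeric interaction counts")
  if (any(df$n_interactions < 0)) stop("negative interaction counts")
  key <- paste(df$lncrna, df$mrna, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    agg <- tapply(df$n_interactions, key, max)
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$n_interactions <- as.numeric(agg[paste(df$lncrna, df$mrna, sep = "\r")])
    warning(n_dup, " duplicate (lncrna, mrna) pairs resolved to max count")
  }
  rownames(df) <- NULL
  df[c("lncrna", "mrna", "n_interactions")]
}

#' Analysis thresholds
#'
#' Holds every cutoff the pipeline applies: bulk log2 fold-change and
#' adjusted-p cutoffs, marker fold-change and detection-fraction cutoffs,
#' the detection-fraction ladder used for panel/marker overlap counting,
#' the minimum interaction count for network edges, and the correlation
#' screen p cutoff.
#'
#' @param lfc_bulk bulk DE |log2FC| cutoff (default 1).
#' @param padj adjusted-p cutoff (default 0.05).
#' @param lfc_marker marker log2FC cutoff (default 0.25).
#' @param min_pct minimum detection fraction for marker testing (default 0.1).
#' @param pct1_levels detection-fraction ladder for overlap counting.
#' @param interactions_min minimum interaction count for network edges.
#' @param corr_p correlation screen p cutoff.
#' @return an object of class `thresholds`.
#' @export
thresholds <- function(lfc_bulk = 1, padj = 0.05, lfc_marker = 0.25,
                       min_pct = 0.1, pct1_levels = c(0.1, 0.2, 0.3, 0.4),
                       interactions_min = 1, corr_p = 0.05) {
  th <- list(lfc_bulk = lfc_bulk, padj = padj, lfc_marker = lfc_marker,
             min_pct = min_pct, pct1_levels = pct1_levels,
             interactions_min = interactions_min, corr_p = corr_p)
  num <- unlist(th)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all thresholds must be positive finite numbers")
  if (any(th$pct1_levels > 1) || th$min_pct > 1)
    stop("detection-fraction thresholds must lie in (0, 1]")
  structure(th, class = "thresholds")
}
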