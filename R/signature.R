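#' Condition-specific up-regulated genes shared across datasets
#'
#' Within the identified population of each dataset, runs a case-vs-control
#' rank-sum test ([wilcoxon_de()]) and keeps genes with
#' `p_adj < th$padj` and `log2_fc > th$lfc_marker`; the signature is the
#' intersection of these per-dataset up-sets, sorted by mean log2
#' fold-change (descending). When the intersection is empty, per-dataset
#' and pairwise diagnostics are returned instead of an error.
#'
#' @param datasets list; each element a list with `matrix` (log-normalized
#'   [gene_matrix()]), `meta` (unit metadata) and `mask` (logical: which
#'   units belong to the population).
#' @param contrast character pair `c(case, control)`.
#' @param th a [thresholds()] object.
#' @return object of class `common_up`: list with `genes`, `per_dataset`
#'   (DE tables), `up_sets`, `diagnostics`.
#' @export
common_upregulated <- function(datasets, contrast = c("T2D", "ND"),
                               th = thresholds()) {
  stopifnot(length(datasets) >= 1)
  per <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    mask <- d$mask
    cond <- d$meta$condition[mask]
    if (sum(cond == contrast[1]) < 3 || sum(cond == contrast[2]) < 3)
      stop("dataset ", i, ": population needs >= 3 case and >= 3 control units")
    sub <- gm_subset(d$matrix, units = mask)
    wilcoxon_de(sub, cond == contrast[1], th = th)
  })
  up_sets <- lapply(per, function(tab)
    tab$gene[tab$p_adj < th$padj & tab$log2_fc > th$lfc_marker])
  common <- Reduce(intersect, up_sets)
  if (length(common)) {
    lfc_mat <- vapply(per, function(tab)
      tab$log2_fc[match(common, tab$gene)], numeric(length(common)))
    mean_lfc <- rowMeans(matrix(lfc_mat, nrow = length(common)))
    common <- common[order(mean_lfc, decreasing = TRUE)]
  }
  diag <- list(n_up_per_dataset = lengths(up_sets))
  if (!length(common) && length(up_sets) > 1) {
    pairs <- combn(length(up_sets), 2)
    diag$pairwise_intersections <- apply(pairs, 2, function(ij)
      length(intersect(up_sets[[ij[1]]], up_sets[[ij[2]]])))
  }
  structure(list(genes = common, per_dataset = per, up_sets = up_sets,
                 diagnostics = diag),
            class = "common_up")
}

#' @export
print.common_up <- function(x, ...) {
  cat(sprintf("<common_up> %d shared up-regulated genes (%s)\n",
              length(x$genes), paste(head(x$genes, 10), collapse = ", ")))
  cat("  per-dataset up-set sizes:",
      paste(x$diagnostics$n_up_per_dataset, collapse = ", "), "\n")
  invisible(x)
}

#' Screen for genes positively correlated with anchor genes
#'
#' For every candidate gene (anchors themselves excluded), computes the
#' Pearson correlation and its two-sided p-value (t transform of r with
#' n - 2 degrees of freedom) against each anchor within the population
#' units of each dataset. A gene is retained only if `r > 0` and
#' `p < th$corr_p` for every anchor in every dataset (the conjunctive
#' reading of "positively correlated in all datasets"). No multiplicity
#' correction is applied by default; `adjust = TRUE` switches the cutoff
#' to BH-adjusted p-values per (dataset, anchor) column. Candidates
#' constant in any dataset are excluded (r undefined) and counted.
#'
#' @param datasets list; each element a list with `matrix` (log-normalized
#'   [gene_matrix()]) and `mask` (logical population mask, or `NULL` for
#'   all units).
#' @param anchors a [gene_panel()]; all anchors must be present in every
#'   dataset.
#' @param th a [thresholds()] object.
#' @param adjust apply BH per (dataset, anchor) test family.
#' @return object of class `corr_screen`: list with `hits` (data.frame:
#'   gene plus one r/p column pair per dataset x anchor), `n_candidates`,
#'   `n_constant_excluded`.
#' @export
correlation_screen <- function(datasets, anchors, th = thresholds(),
                               adjust = FALSE) {
  stopifnot(inherits(anchors, "gene_panel"))
  r_cols <- list(); p_cols <- list()
  candidates <- NULL
  n_constant <- 0L
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    mm <- if (is.null(d$mask)) d$matrix else gm_subset(d$matrix, units = d$mask)
    miss <- setdiff(anchors$genes, mm$gene_ids)
    if (length(miss))
      stop("dataset ", i, " lacks anchor gene(s): ",
           paste(miss, collapse = ", "))
    v <- mm$values
    n <- ncol(v)
    sds <- sqrt(rowSums((v - rowMeans(v))^2) / (n - 1))
    const <- sds == 0
    cand_i <- setdiff(rownames(v)[!const], anchors$genes)
    n_constant <- n_constant + sum(const & !rownames(v) %in% anchors$genes)
    candidates <- if (is.null(candidates)) cand_i else
      intersect(candidates, cand_i)
    for (a in anchors$genes) {
      r <- suppressWarnings(as.vector(cor(t(v), v[a, ])))
      names(r) <- rownames(v)
      tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
      p <- 2 * pt(-abs(tstat), df = n - 2)
      key <- sprintf("ds%d_%s", i, a)
      r_cols[[key]] <- r
      p_cols[[key]] <- p
    }
  }
  rmat <- sapply(r_cols, function(x) x[candidates])
  pmat <- sapply(p_cols, function(x) x[candidates])
  if (length(candidates) == 1) {
    rmat <- matrix(rmat, nrow = 1, dimnames = list(candidates, names(r_cols)))
    pmat <- matrix(pmat, nrow = 1, dimnames = list(candidates, names(p_cols)))
  }
  crit <- if (adjust) apply(pmat, 2, benjamini_hochberg) else pmat
  if (is.null(dim(crit)))
    crit <- matrix(crit, nrow = nrow(pmat), dimnames = dimnames(pmat))
  keep <- rowSums(rmat > 0 & crit < th$corr_p) == ncol(rmat)
  hits <- data.frame(gene = candidates[keep], stringsAsFactors = FALSE)
  for (key in names(r_cols)) {
    hits[[paste0("r_", key)]] <- rmat[keep, key]
    hits[[paste0("p_", key)]] <- pmat[keep, key]
  }
  rownames(hits) <- NULL
  structure(list(hits = hits, n_candidates = length(candidates),
                 n_constant_excluded = n_constant,
                 anchors = anchors$genes),
            class = "corr_screen")
}

#' @export
print.corr_screen <- function(x, ...) {
  cat(sprintf("<corr_screen> %d of %d candidates retained (anchors: %s)\n",
              nrow(x$hits), x$n_candidates,
              paste(x$anchors, collapse = ", ")))
  invisible(x)
}

#' Attach protein-class annotations to genes
#'
#' Multi-label: a gene listed under several classes keeps them all
#' (semicolon-separated); genes absent from the table are labelled
#' `"unknown"`.
#'
#' @param genes character vector or [gene_panel()].
#' @param class_table data.frame with columns `gene`, `class` (multiple
#'   rows per gene allowed).
#' @return data.frame with columns `gene`, `classes`.
#' @export
annotate_classes <- function(genes, class_table) {
  if (inherits(genes, "gene_panel")) genes <- genes$genes
  stopifnot(all(c("gene", "class") %in% names(class_table)))
  ann <- vapply(genes, function(g) {
    cl <- unique(class_table$class[class_table$gene == g])
    if (!length(cl)) "unknown" else paste(sort(cl), collapse = ";")
  }, character(1))
  data.frame(gene = genes, classes = unname(ann), stringsAsFactors = FALSE)
}
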