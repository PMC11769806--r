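#' Gene-panel Z-score signature scores
#'
#' Each panel gene is Z-scored across the units in `scope` (sample SD,
#' n-1 denominator; constant genes contribute 0), and the per-unit score
#' is the mean Z across the panel genes present in the matrix. Panel
#' genes absent from the matrix are dropped and reported in the
#' `"missing_genes"` attribute; it is an error if none are present.
#'
#' @param m a [gene_matrix()].
#' @param panel a [gene_panel()].
#' @param scope unit subset (character/integer/logical index), or `NULL`
#'   for all units. Z-scores are computed within the scope.
#' @return object of class `panel_scores`: list with `panel_name`,
#'   `unit_ids`, `scores`, `genes_used`.
#' @export
panel_score <- function(m, panel, scope = NULL) {
  stopifnot(inherits(m, "gene_matrix"), inherits(panel, "gene_panel"))
  if (!is.null(scope)) m <- gm_subset(m, units = scope)
  present <- intersect(panel$genes, m$gene_ids)
  missing <- setdiff(panel$genes, present)
  if (!length(present))
    stop("no panel gene present in matrix; missing: ",
         paste(head(missing, 10), collapse = ", "))
  v <- m$values[present, , drop = FALSE]
  mu <- rowMeans(v)
  s <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1))
  z <- (v - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  structure(list(panel_name = panel$name, unit_ids = m$unit_ids,
                 scores = setNames(colMeans(z), m$unit_ids),
                 genes_used = present),
            missing_genes = missing,
            class = "panel_scores")
}

#' @export
print.panel_scores <- function(x, ...) {
  cat(sprintf("<panel_scores> %s: %d units, %d genes used\n",
              x$panel_name, length(x$scores), length(x$genes_used)))
  invisible(x)
}

#' Built-in stromal activation gene panel
#'
#' The collagen/ECM-remodelling panel used to read out activated stromal
#' (stellate) cells: LAMB1, ACTA2, FN1, COL1A1, COL1A2, COL3A1, MMP1, MMP2.
#'
#' @return a [gene_panel()].
#' @export
activation_panel <- function() {
  gene_panel("psc_activation",
             c("LAMB1", "ACTA2", "FN1", "COL1A1", "COL1A2", "COL3A1",
               "MMP1", "MMP2"))
}

#' Activation-status score
#'
#' [panel_score()] with the built-in [activation_panel()]; all panel genes
#' present in the matrix are used.
#'
#' @inheritParams panel_score
#' @return a `panel_scores` object.
#' @export
activation_score <- function(m, scope = NULL) {
  panel_score(m, activation_panel(), scope = scope)
}

#' Rank-recovery geneset score
#'
#' For each unit, genes are ranked by expression (descending; ties broken
#' by stable gene order) and the recovery curve counts geneset genes among
#' the top k for k up to `ceiling(top_fraction * G)`. The score is the
#' area under this curve divided by the maximum achievable area (all
#' geneset genes at the top), giving a value in `[0, 1]`.
#'
#' @param m a [gene_matrix()].
#' @param geneset a [gene_panel()].
#' @param top_fraction fraction of the ranking inspected (default 0.05).
#' @return named numeric vector of per-unit scores.
#' @export
recovery_auc_score <- function(m, geneset, top_fraction = 0.05) {
  stopifnot(inherits(m, "gene_matrix"), inherits(geneset, "gene_panel"),
            top_fraction > 0, top_fraction <= 1)
  in_set <- m$gene_ids %in% geneset$genes
  if (!any(in_set))
    stop("geneset shares no genes with the matrix")
  G <- nrow(m$values)
  k_max <- ceiling(top_fraction * G)
  s <- sum(in_set)
  max_area <- sum(pmin(seq_len(k_max), s))
  scores <- vapply(seq_len(ncol(m$values)), function(j) {
    ord <- order(-m$values[, j], seq_len(G))[seq_len(k_max)]
    sum(cumsum(in_set[ord])) / max_area
  }, numeric(1))
  setNames(scores, m$unit_ids)
}

#' ROC curve and AUC from scores and binary labels
#'
#' Higher scores indicate the positive (case) class; tied score pairs
#' contribute 0.5 concordance, so the AUC equals the Mann-Whitney U
#' statistic divided by `n1 * n0` and the trapezoidal integral of the
#' threshold-sweep curve.
#'
#' @param scores numeric vector.
#' @param labels logical vector (`TRUE` = positive class).
#' @return object of class `roc_curve`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n0, numeric(1))
  structure(list(thresholds = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d thresholds)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}
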