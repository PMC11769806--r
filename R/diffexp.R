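#' Median-of-ratios size factors
#'
#' For each unit, the factor is the median over genes (restricted to genes
#' with a positive geometric mean across units) of the ratio between the
#' unit's count and the gene's geometric mean; factors are then rescaled
#' to geometric mean 1. When no gene is positive in every unit the
#' function falls back to library-size factors, with a warning.
#'
#' @param m a raw-count [gene_matrix()].
#' @return named positive numeric vector, one factor per unit.
#' @export
size_factors <- function(m) {
  stopifnot(inherits(m, "gene_matrix"))
  v <- m$values
  if (any(colSums(v) == 0)) stop("some units have all-zero counts")
  all_pos <- rowSums(v > 0) == ncol(v)
  if (!any(all_pos)) {
    warning("no gene positive in all units; falling back to library-size factors")
    sf <- colSums(v)
  } else {
    lg <- rowMeans(log(v[all_pos, , drop = FALSE]))
    sf <- apply(v[all_pos, , drop = FALSE], 2, function(col)
      exp(median(log(col) - lg)))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, m$unit_ids)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

## ---- rank-sum machinery ---------------------------------------------------

## per-gene mid-ranks and tie correction terms for a genes x units matrix
.rank_core <- function(v) {
  n <- ncol(v)
  R <- matrix(0, nrow(v), n, dimnames = dimnames(v))
  tiesum <- numeric(nrow(v))
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    R[i, ] <- rank(x)
    tc <- tabulate(match(x, unique(x)))
    tiesum[i] <- sum(tc^3 - tc)
  }
  list(R = R, tiesum = tiesum, n = n)
}

## exact two-sided permutation p for the rank-sum statistic, vectorised
## over genes; R is genes x N mid-rank matrix, mask the group-1 columns
.wilcox_exact_p <- function(R, mask) {
  N <- ncol(R)
  n1 <- sum(mask)
  idx <- combn(N, n1)
  K <- ncol(idx)
  Z <- matrix(0, N, K)
  Z[cbind(as.vector(idx), rep(seq_len(K), each = n1))] <- 1
  mu <- n1 * (N + 1) / 2
  w_obs <- rowSums(R[, mask, drop = FALSE])
  p <- numeric(nrow(R))
  chunk <- max(1L, floor(2e6 / K))
  for (start in seq(1, nrow(R), by = chunk)) {
    rows <- start:min(start + chunk - 1, nrow(R))
    W <- R[rows, , drop = FALSE] %*% Z
    p[rows] <- rowMeans(abs(W - mu) >= abs(w_obs[rows] - mu) - 1e-9)
  }
  p
}

## rank-sum test for one binary split given a precomputed rank core.
## Exact permutation enumeration when both groups have <= exact_max units,
## tie-corrected normal approximation otherwise (no continuity correction).
.wilcox_from_core <- function(core, mask, exact_max = 8) {
  n1 <- sum(mask)
  n2 <- core$n - n1
  stopifnot(n1 > 0, n2 > 0)
  W <- rowSums(core$R[, mask, drop = FALSE])
  U <- W - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)
  sigma2 <- (n1 * n2 / 12) *
    ((core$n + 1) - core$tiesum / (core$n * (core$n - 1)))
  z <- ifelse(sigma2 > 0, (U - n1 * n2 / 2) / sqrt(sigma2), 0)
  if (n1 <= exact_max && n2 <= exact_max) {
    p <- .wilcox_exact_p(core$R, mask)
    p[sigma2 <= 0] <- 1
  } else {
    p <- ifelse(sigma2 > 0, 2 * pnorm(-abs(z)), 1)
  }
  data.frame(stat = z, auc = auc, p_value = pmin(p, 1))
}

#' Wilcoxon rank-sum differential expression
#'
#' Two-group rank-sum test per gene on a log-normalized matrix, with
#' mid-ranks and tie-corrected variance; when both groups have at most
#' `exact_max` units the two-sided p-value is computed by exhaustive
#' enumeration of all group assignments. Log2 fold-changes are computed on
#' expm1-transformed means with pseudocount 1 (the single-cell
#' convention); detection fractions (`pct_in`, `pct_out`) are the
#' fractions of units with nonzero expression. Genes whose detection
#' fraction is below `th$min_pct` in both groups are not tested.
#' Adjustment is Benjamini-Hochberg over the tested genes.
#'
#' @param m a [gene_matrix()] (log-normalized values).
#' @param group1 logical vector (length = units) marking the group of
#'   interest; fold-changes are group1 vs rest.
#' @param th a [thresholds()] object.
#' @param positive_only drop rows with non-positive log2 fold-change.
#' @param exact_max maximum per-group size for exact enumeration.
#' @return data.frame with columns `gene`, `base_mean`, `log2_fc`, `stat`,
#'   `p_value`, `p_adj`, `pct_in`, `pct_out`, `auc`.
#' @export
wilcoxon_de <- function(m, group1, th = thresholds(), positive_only = FALSE,
                        exact_max = 8) {
  stopifnot(inherits(m, "gene_matrix"), is.logical(group1),
            length(group1) == ncol(m$values))
  if (!any(group1) || all(group1)) stop("both groups must be non-empty")
  v <- m$values
  pct_in <- rowMeans(v[, group1, drop = FALSE] > 0)
  pct_out <- rowMeans(v[, !group1, drop = FALSE] > 0)
  tested <- pmax(pct_in, pct_out) >= th$min_pct
  vt <- v[tested, , drop = FALSE]
  if (!nrow(vt)) stop("no gene passes the detection-fraction filter")
  core <- .rank_core(vt)
  res <- .wilcox_from_core(core, group1, exact_max = exact_max)
  e <- expm1(vt)
  lfc <- log2((rowMeans(e[, group1, drop = FALSE]) + 1) /
                (rowMeans(e[, !group1, drop = FALSE]) + 1))
  out <- data.frame(gene = rownames(vt),
                    base_mean = rowMeans(vt),
                    log2_fc = lfc,
                    stat = res$stat,
                    p_value = res$p_value,
                    p_adj = benjamini_hochberg(res$p_value),
                    pct_in = pct_in[tested],
                    pct_out = pct_out[tested],
                    auc = res$auc,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_untested") <- sum(!tested)
  if (positive_only) out <- out[out$log2_fc > 0, , drop = FALSE]
  out
}

#' One-vs-rest cluster marker detection
#'
#' For each cluster, runs [wilcoxon_de()] of the cluster against all other
#' units and keeps positive markers with `log2_fc > th$lfc_marker` and
#' `pct_in >= th$min_pct`, sorted by p-value then descending fold-change.
#' Singleton clusters are skipped with a warning.
#'
#' @param m a log-normalized [gene_matrix()].
#' @param clusters cluster label per unit.
#' @param th a [thresholds()] object.
#' @return data.frame (`cluster`, `gene`, `log2_fc`, `pct_in`, `pct_out`,
#'   `p_value`, `p_adj`).
#' @export
find_markers <- function(m, clusters, th = thresholds()) {
  stopifnot(inherits(m, "gene_matrix"),
            length(clusters) == ncol(m$values))
  clusters <- as.character(clusters)
  levels_ <- unique(clusters)
  if (length(levels_) < 2) stop("need at least 2 clusters")
  v <- m$values
  pos <- v > 0
  e <- expm1(v)
  core <- .rank_core(v)
  tables <- lapply(levels_, function(cl) {
    mask <- clusters == cl
    if (sum(mask) < 2) {
      warning("singleton cluster '", cl, "' skipped")
      return(NULL)
    }
    pct_in <- rowMeans(pos[, mask, drop = FALSE])
    pct_out <- rowMeans(pos[, !mask, drop = FALSE])
    tested <- pmax(pct_in, pct_out) >= th$min_pct
    if (!any(tested)) return(NULL)
    res <- .wilcox_from_core(
      list(R = core$R[tested, , drop = FALSE],
           tiesum = core$tiesum[tested], n = core$n),
      mask, exact_max = 0)
    lfc <- log2((rowMeans(e[tested, mask, drop = FALSE]) + 1) /
                  (rowMeans(e[tested, !mask, drop = FALSE]) + 1))
    df <- data.frame(cluster = cl, gene = rownames(v)[tested],
                     log2_fc = lfc,
                     pct_in = pct_in[tested], pct_out = pct_out[tested],
                     p_value = res$p_value,
                     p_adj = benjamini_hochberg(res$p_value),
                     stringsAsFactors = FALSE)
    df <- df[df$log2_fc > th$lfc_marker & df$pct_in >= th$min_pct, ,
             drop = FALSE]
    df[order(df$p_value, -df$log2_fc), , drop = FALSE]
  })
  out <- do.call(rbind, tables)
  if (is.null(out))
    out <- data.frame(cluster = character(0), gene = character(0),
                      log2_fc = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), p_value = numeric(0),
                      p_adj = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Bulk negative-binomial differential expression
#'
#' Normalizes raw counts with median-of-ratios [size_factors()], then for
#' each gene computes the per-group normalized means, a pooled
#' method-of-moments NB dispersion (weighted by group degrees of freedom,
#' floored at 1e-8), and a Wald statistic for the difference of log means
#' via the delta method. The statistic is referred to a Student t with
#' `n1 + n2 - 2` degrees of freedom (small-sample plug-in variance).
#' Log2 fold-changes use pseudocount `c0` on the normalized-count scale.
#' All-zero genes (within the contrast units) are excluded and reported in
#' the `"excluded_genes"` attribute.
#'
#' @param m a raw-count [gene_matrix()].
#' @param meta unit metadata (see [validate_unit_meta()]).
#' @param contrast character pair `c(case, control)`.
#' @param th a [thresholds()] object.
#' @param c0 fold-change pseudocount (normalized count scale).
#' @return object of class `bulk_de_result`: list with `table` (gene,
#'   base_mean, log2_fc, stat, p_value, p_adj), `up_genes`, `down_genes`,
#'   `size_factors`, and the contrast.
#' @export
bulk_de <- function(m, meta, contrast = c("T2D", "ND"), th = thresholds(),
                    c0 = 0.5) {
  stopifnot(inherits(m, "gene_matrix"), length(contrast) == 2)
  meta <- validate_unit_meta(meta, units = m$unit_ids)
  g1 <- meta$condition == contrast[1]
  g2 <- meta$condition == contrast[2]
  if (sum(g1) < 2 || sum(g2) < 2)
    stop("each contrast group needs at least 2 units")
  mm <- gm_subset(m, units = g1 | g2)
  g1 <- meta$condition[g1 | g2] == contrast[1]
  sf <- size_factors(mm)
  norm <- sweep(mm$values, 2, sf, "/")
  nonzero <- rowSums(norm) > 0
  excluded <- rownames(norm)[!nonzero]
  norm <- norm[nonzero, , drop = FALSE]
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, !g1, drop = FALSE])
  v1 <- rowSums((norm[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((norm[, !g1, drop = FALSE] - m2)^2) / (n2 - 1)
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, NA_real_)
  a2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, NA_real_)
  w1 <- (n1 - 1) * !is.na(a1)
  w2 <- (n2 - 1) * !is.na(a2)
  alpha <- (ifelse(is.na(a1), 0, a1) * w1 + ifelse(is.na(a2), 0, a2) * w2) /
    (w1 + w2)
  alpha <- pmax(alpha, 1e-8)
  se2 <- (m1 + alpha * m1^2) / (n1 * (m1 + c0)^2) +
    (m2 + alpha * m2^2) / (n2 * (m2 + c0)^2)
  z <- (log(m1 + c0) - log(m2 + c0)) / sqrt(se2)
  p <- 2 * pt(-abs(z), df = n1 + n2 - 2)
  lfc <- log2((m1 + c0) / (m2 + c0))
  tab <- data.frame(gene = rownames(norm),
                    base_mean = rowMeans(norm),
                    log2_fc = lfc, stat = z, p_value = p,
                    p_adj = benjamini_hochberg(p),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  up <- tab$gene[tab$log2_fc > th$lfc_bulk & tab$p_adj < th$padj]
  down <- tab$gene[tab$log2_fc < -th$lfc_bulk & tab$p_adj < th$padj]
  structure(list(table = tab, up_genes = up, down_genes = down,
                 size_factors = sf, contrast = contrast),
            excluded_genes = excluded,
            class = "bulk_de_result")
}

#' @export
print.bulk_de_result <- function(x, ...) {
  cat(sprintf("<bulk_de_result> %s vs %s: %d genes tested, %d up / %d down\n",
              x$contrast[1], x$contrast[2], nrow(x$table),
              length(x$up_genes), length(x$down_genes)))
  invisible(x)
}
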