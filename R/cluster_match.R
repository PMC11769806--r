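#' Depth-normalize and log-transform raw counts
#'
#' Scales each unit to `scale_factor` total counts and applies log1p —
#' the conventional single-cell normalization all profile and marker work
#' in this package operates on.
#'
#' @param m a raw-count [gene_matrix()].
#' @param scale_factor per-unit target total (default 1e4).
#' @return a [gene_matrix()] with `kind = "lognorm"`.
#' @export
lognormalize <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "gene_matrix"))
  if (m$kind != "raw_counts")
    stop("lognormalize expects raw counts")
  tot <- colSums(m$values)
  if (any(tot == 0)) stop("units with zero total counts")
  v <- log1p(sweep(m$values, 2, tot / scale_factor, "/"))
  gene_matrix(v, m$gene_ids, m$unit_ids, "lognorm")
}

#' Graph-based cell clustering
#'
#' Standard single-cell clustering: the log-normalized matrix is reduced
#' to a linear embedding (PCA on the most variable genes, scaled), a
#' k-nearest-neighbour graph is built in PC space and converted to a
#' shared-nearest-neighbour (Jaccard-weighted) graph, and communities are
#' found by multilevel modularity optimization at the given resolution.
#' Labels are integers with 0 the largest cluster, in descending size
#' order; the result is deterministic given the seed.
#'
#' @param m a log-normalized [gene_matrix()].
#' @param n_components number of principal components (default 30).
#' @param n_neighbors k for the kNN graph (default 20).
#' @param resolution modularity resolution (default 1).
#' @param seed RNG seed for the community search.
#' @param n_hvg number of highly variable genes used for the embedding.
#' @param snn_prune SNN Jaccard weights below this are dropped.
#' @return integer vector of cluster labels (0-based), named by unit.
#' @export
cluster_cells <- function(m, n_components = 30, n_neighbors = 20,
                          resolution = 1, seed = 0, n_hvg = 1000,
                          snn_prune = 1 / 15) {
  stopifnot(inherits(m, "gene_matrix"))
  n <- ncol(m$values)
  if (n < n_neighbors + 1)
    stop("need at least n_neighbors + 1 units")
  if (n <= n_components) {
    warning("fewer units than components; reducing n_components")
    n_components <- n - 1
  }
  v <- m$values
  gvar <- rowSums((v - rowMeans(v))^2)
  keep <- gvar > 0
  v <- v[keep, , drop = FALSE]
  gvar <- gvar[keep]
  if (nrow(v) > n_hvg)
    v <- v[order(gvar, decreasing = TRUE)[seq_len(n_hvg)], , drop = FALSE]
  x <- scale(t(v))
  ## PCA via eigen of the gene-gene covariance (genes were pre-selected)
  cv <- crossprod(x) / (n - 1)
  n_components <- min(n_components, ncol(cv) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  scores <- x %*% ev$vectors[, seq_len(n_components), drop = FALSE]
  ## kNN -> shared-nearest-neighbour Jaccard graph
  d <- as.matrix(dist(scores))
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(n_neighbors + 1)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = n_neighbors + 1),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  jac <- shared / (2 * (n_neighbors + 1) - shared)
  jac@x[jac@x < snn_prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  setNames(as.integer(relabel[as.character(memb)]), m$unit_ids)
}

#' Per-cluster mean expression profiles
#'
#' @param m a [gene_matrix()] (log-normalized values recommended).
#' @param labels cluster label per unit; empty levels are excluded.
#' @return object of class `cluster_profiles`: list with `means`
#'   (genes x clusters matrix), `n_units`, `gene_ids`.
#' @export
cluster_profiles <- function(m, labels) {
  stopifnot(inherits(m, "gene_matrix"),
            length(labels) == ncol(m$values))
  labels <- as.character(labels)
  f <- factor(labels, levels = unique(labels))
  sums <- t(rowsum(t(m$values), f))
  n_units <- as.vector(table(f))
  means <- sweep(sums, 2, n_units, "/")
  structure(list(means = means, n_units = setNames(n_units, levels(f)),
                 gene_ids = m$gene_ids),
            class = "cluster_profiles")
}

#' Pearson similarity between cluster profiles of two datasets
#'
#' Correlations are computed on the gene intersection of the two
#' profile sets; with fewer than 3 shared genes every pair is marked
#' missing (`NA`).
#'
#' @param profiles_a,profiles_b [cluster_profiles()] objects.
#' @return object of class `similarity_matrix`: list with `pearson`
#'   (rows = clusters of a, cols = clusters of b) and `n_shared_genes`.
#' @export
pearson_similarity <- function(profiles_a, profiles_b) {
  stopifnot(inherits(profiles_a, "cluster_profiles"),
            inherits(profiles_b, "cluster_profiles"))
  shared <- intersect(profiles_a$gene_ids, profiles_b$gene_ids)
  if (length(shared) < 3) {
    r <- matrix(NA_real_, ncol(profiles_a$means), ncol(profiles_b$means),
                dimnames = list(colnames(profiles_a$means),
                                colnames(profiles_b$means)))
  } else {
    r <- suppressWarnings(cor(profiles_a$means[shared, , drop = FALSE],
                              profiles_b$means[shared, , drop = FALSE]))
  }
  structure(list(pearson = r, n_shared_genes = length(shared)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d cluster pairs, %d shared genes\n",
              nrow(x$pearson), ncol(x$pearson), x$n_shared_genes))
  invisible(x)
}

#' Directional marker-overlap ratios between two marker tables
#'
#' For clusters (a, b) with marker sets `M_a`, `M_b` at the given
#' detection-fraction level, computes both directional ratios
#' `|M_a  intersect  M_b| / |M_a|` (row) and `/ |M_b|` (col). Clusters with an
#' empty marker set are reported as missing.
#'
#' @param markers_a,markers_b marker tables from [find_markers()].
#' @param pct_level optional extra `pct_in` cutoff applied to both tables.
#' @return list with matrices `overlap_row`, `overlap_col`, `n_overlap`
#'   (class `marker_overlap`).
#' @export
marker_overlap <- function(markers_a, markers_b, pct_level = NULL) {
  filt <- function(tab) {
    levels_ <- unique(tab$cluster)
    if (!is.null(pct_level)) tab <- tab[tab$pct_in >= pct_level, , drop = FALSE]
    split(tab$gene, factor(tab$cluster, levels = levels_))
  }
  sa <- filt(markers_a); sb <- filt(markers_b)
  ov <- matrix(0L, length(sa), length(sb), dimnames = list(names(sa), names(sb)))
  for (i in seq_along(sa)) for (j in seq_along(sb))
    ov[i, j] <- length(intersect(sa[[i]], sb[[j]]))
  la <- lengths(sa); lb <- lengths(sb)
  row_ratio <- ov / ifelse(la > 0, la, NA)                  # recycles by row
  col_ratio <- t(t(ov) / ifelse(lb > 0, lb, NA))
  structure(list(overlap_row = row_ratio, overlap_col = col_ratio,
                 n_overlap = ov),
            class = "marker_overlap")
}

#' Panel enrichment across clusters
#'
#' For each cluster: the mean panel Z-score of its member units, and the
#' number of panel genes among the cluster's markers at each
#' detection-fraction (`pct.1`) level. Reports the argmax cluster per
#' level (ties broken toward the larger cluster) and by mean score.
#'
#' @param m a log-normalized [gene_matrix()].
#' @param labels cluster label per unit.
#' @param panel a [gene_panel()].
#' @param markers marker table from [find_markers()].
#' @param pct_levels detection-fraction ladder.
#' @return object of class `panel_enrichment`: list with `mean_score`,
#'   `overlap_counts` (clusters x levels), `argmax_by_level`,
#'   `argmax_score`.
#' @export
panel_enrichment_by_cluster <- function(m, labels, panel, markers,
                                        pct_levels = c(0.1, 0.2, 0.3, 0.4)) {
  stopifnot(inherits(m, "gene_matrix"), inherits(panel, "gene_panel"))
  labels <- as.character(labels)
  ps <- panel_score(m, panel)
  mean_score <- tapply(ps$scores, labels, mean)
  cl_sizes <- table(labels)
  cls <- names(mean_score)
  counts <- sapply(pct_levels, function(lv) {
    vapply(cls, function(cl) {
      mg <- markers$gene[markers$cluster == cl & markers$pct_in >= lv]
      length(intersect(panel$genes, mg))
    }, integer(1))
  })
  counts <- matrix(counts, nrow = length(cls),
                   dimnames = list(cls, paste0("pct1_", pct_levels)))
  pick_max <- function(x) {
    best <- which(x == max(x))
    if (length(best) > 1)
      best <- best[which.max(cl_sizes[cls[best]])]
    cls[best]
  }
  structure(list(mean_score = mean_score,
                 overlap_counts = counts,
                 argmax_by_level = apply(counts, 2, pick_max),
                 argmax_score = pick_max(as.vector(mean_score)),
                 pct_levels = pct_levels),
            class = "panel_enrichment")
}

#' @export
print.panel_enrichment <- function(x, ...) {
  cat("<panel_enrichment>\n  mean-score argmax cluster:", x$argmax_score,
      "\n  overlap argmax per pct level:",
      paste(sprintf("%s=%s", names(x$argmax_by_level), x$argmax_by_level),
            collapse = ", "), "\n")
  invisible(x)
}

#' Identify the cluster with the highest anchor-gene expression
#'
#' Returns the cluster whose units have the highest mean expression of
#' the anchor gene; exact ties are broken toward the larger cluster.
#'
#' @param m a [gene_matrix()].
#' @param labels cluster label per unit.
#' @param anchor_gene gene symbol (error if absent).
#' @return the winning cluster label (character).
#' @export
identify_population <- function(m, labels, anchor_gene) {
  stopifnot(inherits(m, "gene_matrix"))
  if (!anchor_gene %in% m$gene_ids)
    stop("anchor gene '", anchor_gene, "' absent from matrix")
  labels <- as.character(labels)
  x <- m$values[anchor_gene, ]
  mu <- tapply(x, labels, mean)
  sizes <- table(labels)[names(mu)]
  best <- which(mu == max(mu))
  if (length(best) > 1) best <- best[which.max(sizes[best])]
  names(mu)[best]
}
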