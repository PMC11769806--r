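#' Up-regulated features in a PBMC-like intensity matrix
#'
#' Per-feature two-sided rank-sum test on intensities (exact enumeration
#' at the small group sizes typical of arrays) with log2 fold-change of
#' group means on the linear intensity scale. The default cutoff is raw
#' `p < th$padj` together with `log2_fc > th$lfc_bulk`; with the group
#' sizes of a small array BH at 0.05 is often unattainable, so adjustment
#' is opt-in via `adjust = TRUE`. Features constant across all units are
#' never returned.
#'
#' @param m an intensity [gene_matrix()].
#' @param meta unit metadata.
#' @param contrast character pair `c(case, control)`.
#' @param th a [thresholds()] object.
#' @param adjust use BH-adjusted p-values for the cutoff.
#' @return object of class `pbmc_de_result`: list with `table` (feature
#'   statistics) and `up_genes`.
#' @export
pbmc_upregulated <- function(m, meta, contrast = c("T2D", "ND"),
                             th = thresholds(), adjust = FALSE) {
  stopifnot(inherits(m, "gene_matrix"))
  meta <- validate_unit_meta(meta, units = m$unit_ids)
  sel <- meta$condition %in% contrast
  mm <- gm_subset(m, units = sel)
  g1 <- meta$condition[sel] == contrast[1]
  if (sum(g1) < 2 || sum(!g1) < 2)
    stop("each contrast group needs at least 2 units")
  v <- mm$values
  const <- apply(v, 1, function(x) length(unique(x)) == 1)
  v <- v[!const, , drop = FALSE]
  core <- .rank_core(v)
  res <- .wilcox_from_core(core, g1, exact_max = 8)
  m1 <- rowMeans(v[, g1, drop = FALSE])
  m2 <- rowMeans(v[, !g1, drop = FALSE])
  lfc <- log2(m1 / m2)
  tab <- data.frame(gene = rownames(v), base_mean = rowMeans(v),
                    log2_fc = lfc, stat = res$stat,
                    p_value = res$p_value,
                    p_adj = benjamini_hochberg(res$p_value),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  crit <- if (adjust) tab$p_adj else tab$p_value
  up <- tab$gene[crit < th$padj & tab$log2_fc > th$lfc_bulk]
  structure(list(table = tab, up_genes = up, contrast = contrast,
                 n_constant = sum(const)),
            class = "pbmc_de_result")
}

#' @export
print.pbmc_de_result <- function(x, ...) {
  cat(sprintf("<pbmc_de_result> %s vs %s: %d features tested, %d up\n",
              x$contrast[1], x$contrast[2], nrow(x$table),
              length(x$up_genes)))
  invisible(x)
}

#' Build the bipartite lncRNA-mRNA network
#'
#' Edges are interaction records whose mRNA belongs to the signature,
#' whose lncRNA belongs to the up-regulated lncRNA set, and whose
#' interaction count is at least `th$interactions_min`. Nodes are derived
#' from the surviving edges only, so no orphan nodes occur; an empty
#' network is allowed.
#'
#' @param records interaction data.frame (`lncrna`, `mrna`,
#'   `n_interactions`), e.g. from [read_interaction_table()].
#' @param signature character vector or [gene_panel()] of signature mRNAs.
#' @param up_lncrnas character vector or [gene_panel()] of up-regulated
#'   lncRNAs (a mixed up-set is fine; only its lncRNA members can match).
#' @param th a [thresholds()] object.
#' @return object of class `bipartite_network`: list with `nodes`
#'   (id, part), `edges` (lncrna, mrna, n_interactions), `lncrnas`.
#' @export
build_network <- function(records, signature, up_lncrnas, th = thresholds()) {
  if (inherits(signature, "gene_panel")) signature <- signature$genes
  if (inherits(up_lncrnas, "gene_panel")) up_lncrnas <- up_lncrnas$genes
  records <- interaction_table(records)
  keep <- records$mrna %in% signature &
    records$lncrna %in% up_lncrnas &
    records$n_interactions >= th$interactions_min
  edges <- records[keep, , drop = FALSE]
  edges <- edges[order(edges$lncrna, edges$mrna), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(
    id = c(unique(edges$lncrna), unique(edges$mrna)),
    part = rep(c("lncRNA", "mRNA"),
               c(length(unique(edges$lncrna)), length(unique(edges$mrna)))),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 lncrnas = unique(edges$lncrna)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %d lncRNAs, %d mRNAs, %d edges\n",
              sum(x$nodes$part == "lncRNA"), sum(x$nodes$part == "mRNA"),
              nrow(x$edges)))
  invisible(x)
}

#' Export a bipartite network
#'
#' Writes the edge list as TSV and, optionally, the typed graph as
#' GraphML (node attribute `part`).
#'
#' @param net a [build_network()] result.
#' @param edge_path TSV output path.
#' @param graphml_path optional GraphML output path.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(net, edge_path, graphml_path = NULL) {
  write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      net$edges[c("lncrna", "mrna")], directed = FALSE,
      vertices = data.frame(name = net$nodes$id, part = net$nodes$part))
    igraph::E(g)$n_interactions <- net$edges$n_interactions
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}

#' ROC evaluation of an lncRNA panel
#'
#' Scores every unit with the combined lncRNA [panel_score()] and with
#' each individual lncRNA, then computes ROC/AUC against the case
#' condition.
#'
#' @param m an intensity [gene_matrix()].
#' @param meta unit metadata.
#' @param lncrnas character vector or [gene_panel()] of lncRNA features.
#' @param contrast character pair `c(case, control)`.
#' @return list with `combined` (a [roc_auc()] result) and `per_lncrna`
#'   (named list of `roc_curve` objects).
#' @export
lncrna_panel_roc <- function(m, meta, lncrnas, contrast = c("T2D", "ND")) {
  if (inherits(lncrnas, "gene_panel")) lncrnas <- lncrnas$genes
  stopifnot(inherits(m, "gene_matrix"))
  meta <- validate_unit_meta(meta, units = m$unit_ids)
  sel <- meta$condition %in% contrast
  mm <- gm_subset(m, units = sel)
  labels <- meta$condition[sel] == contrast[1]
  panel <- gene_panel("lncrna_panel", lncrnas)
  combined <- roc_auc(panel_score(mm, panel)$scores, labels)
  per <- lapply(intersect(lncrnas, mm$gene_ids), function(g)
    roc_auc(mm$values[g, ], labels))
  names(per) <- intersect(lncrnas, mm$gene_ids)
  list(combined = combined, per_lncrna = per)
}
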