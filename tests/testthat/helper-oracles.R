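# Independent brute-force oracles used across test files.

# step-up FDR adjustment straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    j_ge <- which(p[ord] >= p[ord][i])
    adj[ord[i]] <- min(pmin(1, m * p[ord][j_ge] / j_ge))
  }
  adj
}

# all-pairs concordance count
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

# exhaustive two-sided rank-sum p: enumerate every assignment of n1 units
# to group 1 and count statistics at least as far from the null mean
wilcox_enum_oracle <- function(x, group1) {
  r <- rank(x)
  N <- length(x)
  n1 <- sum(group1)
  mu <- n1 * (N + 1) / 2
  w_obs <- sum(r[group1])
  combos <- combn(N, n1)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

rand_gene_matrix <- function(n_genes, n_units, kind = "raw_counts",
                             lambda = 5) {
  v <- matrix(rpois(n_genes * n_units, lambda), n_genes, n_units)
  if (kind != "raw_counts") v <- v + runif(length(v))
  gene_matrix(v, sprintf("G%03d", seq_len(n_genes)),
              sprintf("U%03d", seq_len(n_units)), kind = kind)
}

# small, fast synthetic configuration for unit tests (overridable defaults)
tiny_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 600, n_cells_per_dataset = 800,
         n_bulk_samples_per_condition = 10, cells_per_bulk = 150,
         n_decoy_records = 50),
    list(...))
  do.call(synth_config, args)
}
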