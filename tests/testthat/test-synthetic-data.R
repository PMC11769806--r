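test_that("generator output is deterministic and structurally valid", {
  cfg <- tiny_config()
  a <- simulate_scrna(cfg, 1)
  b <- simulate_scrna(cfg, 1)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$meta, b$meta)
  expect_true(all(a$matrix$values >= 0))
  expect_true(all(a$matrix$values == round(a$matrix$values)))
  expect_setequal(unique(a$meta$condition), c("T2D", "ND"))
  expect_true(all(a$meta$cell_type %in% cfg$cell_types$name))
  # another dataset index gives different draws but the same gene universe
  # rules (specials always retained)
  c2 <- simulate_scrna(cfg, 2)
  gs <- synth_gene_sets(cfg)
  expect_true(all(gs$signature %in% c2$matrix$gene_ids))
  expect_true(gs$anchor %in% c2$matrix$gene_ids)
})

test_that("degenerate proportions and absent target type behave as specified", {
  ct <- data.frame(name = "alpha", proportion = 1, scale = 1)
  expect_error(synth_config(cell_types = ct, target_type = "stellate"),
               "config error")
  cfg <- tiny_config(cell_types = data.frame(
    name = c("alpha", "stellate"), proportion = c(0, 1), scale = 1))
  s <- simulate_scrna(cfg, 1)
  expect_true(all(s$meta$cell_type == "stellate"))
})

test_that("zero effect size leaves planted genes null across conditions", {
  hits <- 0L
  n_seeds <- 15L
  for (s in seq_len(n_seeds)) {
    cfg <- tiny_config(seed = 100 + s, signature_effect = 0,
                       n_cells_per_dataset = 600)
    sim <- simulate_scrna(cfg, 1)
    psc <- sim$meta$cell_type == "stellate"
    g <- cfg$signature_genes[1]
    p <- suppressWarnings(
      wilcox.test(sim$matrix$values[g, psc & sim$meta$condition == "T2D"],
                  sim$matrix$values[g, psc & sim$meta$condition == "ND"]))$p.value
    if (p < 0.01) hits <- hits + 1L
  }
  expect_lte(hits, 2L)
})

test_that("planted fold change matches the configured effect at large n", {
  cfg <- tiny_config(n_cells_per_dataset = 6000, signature_effect = 2,
                     depth_scale = 1)
  sim <- simulate_scrna(cfg, 1)
  psc <- sim$meta$cell_type == "stellate"
  case <- sim$meta$condition == "T2D"
  for (g in cfg$signature_genes) {
    ratio <- mean(sim$matrix$values[g, psc & case]) /
      mean(sim$matrix$values[g, psc & !case])
    expect_gt(ratio, 0.9 * 2^2)
    expect_lt(ratio, 1.1 * 2^2)
  }
})

test_that("pseudo-bulk cohort carries the planted signal via the target type", {
  cfg <- tiny_config(n_bulk_samples_per_condition = 1)
  b <- simulate_bulk(cfg)
  expect_equal(ncol(b$matrix$values), 2)
  expect_true(all(b$matrix$values == round(b$matrix$values)))

  # planted genes rank at the top by bulk log2FC under the cohort design
  cfg2 <- synth_config(seed = 21, n_genes = 600,
                       n_bulk_samples_per_condition = 30,
                       cells_per_bulk = 200, signature_effect = 2,
                       cell_types = data.frame(
                         name = c("alpha", "beta", "stellate"),
                         proportion = c(0.5, 0.4, 0.1), scale = 1))
  b2 <- simulate_bulk(cfg2)
  case <- b2$meta$condition == "T2D"
  m1 <- rowMeans(b2$matrix$values[, case]) + 0.5
  m0 <- rowMeans(b2$matrix$values[, !case]) + 0.5
  lfc <- log2(m1 / m0)
  top <- names(sort(lfc, decreasing = TRUE))[seq_len(ceiling(0.01 * length(lfc)))]
  expect_true(all(cfg2$signature_genes %in% top))

  # no carrier population -> no condition effect on planted genes
  cfg3 <- tiny_config(seed = 31, cell_types = data.frame(
    name = c("alpha", "stellate"), proportion = c(1, 0), scale = 1),
    n_bulk_samples_per_condition = 15)
  b3 <- simulate_bulk(cfg3)
  case3 <- b3$meta$condition == "T2D"
  for (g in cfg3$signature_genes) {
    p <- suppressWarnings(wilcox.test(b3$matrix$values[g, case3],
                                      b3$matrix$values[g, !case3]))$p.value
    expect_gt(p, 0.001)
  }
})

test_that("PBMC array has the configured shape and planted separation", {
  cfg <- tiny_config(pbmc_shift_sd = 6)
  p <- simulate_pbmc_array(cfg)
  expect_equal(ncol(p$matrix$values), 2 * cfg$n_pbmc_per_condition)
  expect_equal(p$matrix$kind, "intensity")
  labels <- p$meta$condition == "T2D"
  for (g in cfg$lncrna_genes)
    expect_equal(roc_auc(p$matrix$values[g, ], labels)$auc, 1.0)

  # null array: no lncRNA separates the groups strongly in most seeds
  high <- 0L
  for (s in 1:10) {
    cfg0 <- tiny_config(seed = 200 + s, pbmc_shift_sd = 0, n_up_mrna = 0)
    p0 <- simulate_pbmc_array(cfg0)
    l0 <- p0$meta$condition == "T2D"
    aucs <- vapply(cfg0$lncrna_genes, function(g)
      roc_auc(p0$matrix$values[g, ], l0)$auc, numeric(1))
    if (any(aucs > 0.9)) high <- high + 1L
  }
  expect_lte(high, 4L)
})

test_that("interaction table contains planted pairs plus configured decoys", {
  cfg <- tiny_config()
  tab <- simulate_interaction_table(cfg)
  planted <- attr(tab, "planted")
  key <- paste(tab$lncrna, tab$mrna)
  pkey <- paste(planted$lncrna, planted$mrna)
  expect_true(all(pkey %in% key))
  expect_true(all(tab$n_interactions[match(pkey, key)] >= 1))
  expect_equal(sum(tab$n_interactions == 0),
               round(cfg$decoy_zero_fraction * cfg$n_decoy_records))

  cfg0 <- tiny_config(n_decoy_records = 0)
  tab0 <- simulate_interaction_table(cfg0)
  expect_setequal(paste(tab0$lncrna, tab0$mrna),
                  paste(attr(tab0, "planted")$lncrna,
                        attr(tab0, "planted")$mrna))
})

test_that("latent-factor stromal simulator plants the correlation module", {
  cfg <- tiny_config()
  s <- simulate_correlated_psc(cfg, n_cells = 800, loading = 0.8)
  v <- s$matrix$values
  r_module <- cor(v[s$module_genes[1], ], v[s$anchors[1], ])
  expect_gt(r_module, 0.5)
  background <- setdiff(s$matrix$gene_ids,
                        c(s$module_genes, s$anchors,
                          synth_gene_sets(cfg)$activation))
  r_bg <- cor(v[background[1], ], v[s$anchors[1], ])
  expect_lt(abs(r_bg), 0.2)
})
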