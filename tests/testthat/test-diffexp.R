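test_that("size factors are symmetric, scale-equivariant, and match brute force", {
  v <- matrix(rpois(200, 10) + 1, 100, 2)
  v[, 2] <- v[, 1]
  m <- gene_matrix(v, sprintf("G%03d", 1:100), c("a", "b"), "raw_counts")
  expect_equal(unname(size_factors(m)), c(1, 1))

  v2 <- cbind(v[, 1], 2 * v[, 1])
  m2 <- gene_matrix(v2, m$gene_ids, c("a", "b"), "raw_counts")
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  set.seed(8)
  v3 <- matrix(rnbinom(600, mu = 20, size = 2), 100, 6)
  v3[1, ] <- v3[1, ] + 1  # ensure at least one all-positive gene
  m3 <- gene_matrix(v3, m$gene_ids, sprintf("s%d", 1:6), "raw_counts")
  sf3 <- size_factors(m3)
  # brute force: per-gene geometric means, per-unit median ratio
  all_pos <- rowSums(v3 > 0) == 6
  geo <- exp(rowMeans(log(v3[all_pos, ])))
  raw <- apply(v3[all_pos, ], 2, function(col) median(col / geo))
  expect_equal(unname(sf3), raw / exp(mean(log(raw))), tolerance = 1e-12)

  v4 <- diag(5)  # no gene positive everywhere
  m4 <- gene_matrix(v4, paste0("g", 1:5), paste0("u", 1:5), "raw_counts")
  expect_warning(size_factors(m4), "library-size")
})

test_that("benjamini_hochberg matches the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  for (i in 1:500) {
    p <- runif(sample(1:20, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p) && all(adj <= 1))
  }
})

test_that("rank-sum p-values match exact enumeration for all small splits", {
  m1 <- gene_matrix(matrix(1:6, 1), "G", paste0("u", 1:6), "lognorm")
  res <- wilcoxon_de(m1, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     th = thresholds(min_pct = 0.01))
  expect_equal(res$p_value, 0.1)

  # all-tied values give p = 1 by convention
  mt <- gene_matrix(matrix(rep(2, 6), 1), "G", paste0("u", 1:6), "lognorm")
  rest <- wilcoxon_de(mt, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                      th = thresholds(min_pct = 0.01))
  expect_equal(rest$p_value, 1)

  # exhaustive check over group sizes up to 8, with and without ties,
  # against an independent enumeration oracle and (tie-free) wilcox.test
  set.seed(42)
  th <- thresholds(min_pct = 0.01)
  for (n1 in c(2, 3, 5, 8)) for (n2 in c(2, 4, 8)) {
    N <- n1 + n2
    x_free <- sample(seq_len(N))            # tie-free
    x_tied <- sample(rep(1:3, length.out = N))
    g <- c(rep(TRUE, n1), rep(FALSE, n2))
    for (x in list(x_free, x_tied)) {
      m <- gene_matrix(matrix(x, 1), "G", paste0("u", 1:N), "lognorm")
      p_pkg <- wilcoxon_de(m, g, th = th)$p_value
      expect_equal(p_pkg, wilcox_enum_oracle(x, g), tolerance = 1e-12)
    }
    p_ref <- wilcox.test(x_free[g], x_free[!g], exact = TRUE)$p.value
    m <- gene_matrix(matrix(x_free, 1), "G", paste0("u", 1:N), "lognorm")
    expect_equal(wilcoxon_de(m, g, th = th)$p_value, p_ref,
                 tolerance = 1e-12)
  }
})

test_that("rank-sum statistic is symmetric under null permutations", {
  set.seed(13)
  v <- matrix(rnorm(30 * 40, 1), 30, 40)
  m <- gene_matrix(v, sprintf("G%02d", 1:30), sprintf("u%02d", 1:40),
                   "lognorm")
  aucs <- replicate(20, {
    g <- sample(c(rep(TRUE, 20), rep(FALSE, 20)))
    mean(wilcoxon_de(m, g, th = thresholds(min_pct = 0.01))$auc)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("rank-sum test holds its nominal size under the null", {
  set.seed(77)
  v <- matrix(rnbinom(2000 * 60, mu = 3, size = 2), 2000, 60)
  m <- lognormalize(gene_matrix(v, sprintf("G%04d", 1:2000),
                                sprintf("u%02d", 1:60), "raw_counts"))
  g <- rep(c(TRUE, FALSE), 30)
  res <- wilcoxon_de(m, g, th = thresholds(min_pct = 0.01))
  frac <- mean(res$p_value < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("bulk_de returns null results for identical groups and is invariant", {
  # identical unit profiles: every gene is null, so lfc = 0, stat = 0, p = 1
  set.seed(5)
  col <- rnbinom(100, mu = 20, size = 3) + 1
  ids <- paste0("s", 1:8)
  m_id <- gene_matrix(matrix(col, 100, 8), sprintf("G%03d", 1:100), ids,
                      "raw_counts")
  meta <- data.frame(unit_id = ids, dataset_id = "B",
                     condition = rep(c("T2D", "ND"), each = 4))
  res_id <- bulk_de(m_id, meta)
  expect_equal(res_id$table$log2_fc, rep(0, 100))
  expect_equal(res_id$table$stat, rep(0, 100))
  expect_equal(res_id$table$p_value, rep(1, 100))

  v <- matrix(rnbinom(100 * 8, mu = 20, size = 3) + 1, 100, 8)
  m <- gene_matrix(v, sprintf("G%03d", 1:100), ids, "raw_counts")
  res <- bulk_de(m, meta)

  # invariance to unit ordering
  perm <- sample(8)
  m2 <- gm_subset(m, units = perm)
  res2 <- bulk_de(m2, meta[perm, ])
  expect_equal(res2$table[order(res2$table$gene), ],
               res$table[order(res$table$gene), ], tolerance = 1e-12,
               ignore_attr = TRUE)

  # size factors are normalized to geometric mean 1, so any common
  # rescaling of the factor vector leaves the normalized counts (and
  # hence the whole result) unchanged
  expect_equal(exp(mean(log(res$size_factors))), 1, tolerance = 1e-12)

  expect_error(bulk_de(m, within(meta, condition[2:4] <- "ND")),
               "at least 2 units")
})

test_that("bulk_de recovers planted genes and excludes all-zero genes", {
  cfg <- tiny_config(seed = 3)
  b <- simulate_bulk(cfg)
  res <- bulk_de(b$matrix, b$meta)
  expect_true(all(cfg$signature_genes %in% res$up_genes))
  expect_false(any(res$table$gene %in% attr(res, "excluded_genes")))
})

test_that("markers are found in their own cluster only and filters are monotone", {
  set.seed(21)
  n <- 60
  v <- matrix(rpois(100 * 2 * n, 2), 100, 2 * n)
  v[1:5, 1:n] <- v[1:5, 1:n] + rpois(5 * n, 8)       # markers of cluster A
  v[6:10, (n + 1):(2 * n)] <- v[6:10, (n + 1):(2 * n)] + rpois(5 * n, 8)
  m <- lognormalize(gene_matrix(v, sprintf("G%03d", 1:100),
                                sprintf("u%03d", 1:(2 * n)), "raw_counts"))
  cl <- rep(c("A", "B"), each = n)
  mk <- find_markers(m, cl)
  expect_true(all(sprintf("G%03d", 1:5) %in% mk$gene[mk$cluster == "A"]))
  expect_true(all(sprintf("G%03d", 6:10) %in% mk$gene[mk$cluster == "B"]))
  expect_false(any(sprintf("G%03d", 1:5) %in% mk$gene[mk$cluster == "B"]))

  # identical clusters yield no markers
  v2 <- cbind(v[, 1:10], v[, 1:10])
  m2 <- lognormalize(gene_matrix(v2, m$gene_ids, sprintf("u%02d", 1:20),
                                 "raw_counts"))
  mk2 <- find_markers(m2, rep(c("A", "B"), each = 10))
  expect_equal(nrow(mk2), 0)

  # raising min_pct or lfc_marker can only shrink the marker set
  mk_strict <- find_markers(m, cl, th = thresholds(min_pct = 0.5))
  expect_true(all(paste(mk_strict$cluster, mk_strict$gene) %in%
                    paste(mk$cluster, mk$gene)))
  mk_lfc <- find_markers(m, cl, th = thresholds(lfc_marker = 1))
  expect_true(all(paste(mk_lfc$cluster, mk_lfc$gene) %in%
                    paste(mk$cluster, mk$gene)))

  expect_warning(find_markers(m, c("C", rep(c("A", "B"), length.out = 2 * n - 1))),
                 "singleton")
})
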