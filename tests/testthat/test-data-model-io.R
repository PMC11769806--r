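test_that("gene_matrix enforces its invariants", {
  v <- matrix(1:6, 3, 2)
  m <- gene_matrix(v, c("A", "B", "C"), c("u1", "u2"), "raw_counts")
  expect_s3_class(m, "gene_matrix")
  expect_error(gene_matrix(-v, c("A", "B", "C"), c("u1", "u2"), "raw_counts"),
               "non-negative")
  expect_error(gene_matrix(v + 0.5, c("A", "B", "C"), c("u1", "u2"),
                           "raw_counts"), "integers")
  expect_error(gene_matrix(v, c("A", "A", "C"), c("u1", "u2"), "raw_counts"),
               "duplicate gene ids: A")
  expect_error(gene_matrix(v, c("A", "B", "C"), c("u1", "u1"), "raw_counts"),
               "duplicate unit ids")
  vna <- v; vna[1] <- NA
  expect_error(gene_matrix(vna, c("A", "B", "C"), c("u1", "u2"), "lognorm"),
               "NA")
})

test_that("matrix market triplets expand correctly and round-trip", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "3 2 2"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("A", "B", "C"), file.path(dir, "features.tsv"))
  writeLines(c("u1", "u2"), file.path(dir, "barcodes.tsv"))
  m <- read_matrix_market(dir)
  expect_equal(unname(m$values),
               matrix(c(5, 0, 0, 0, 0, 2), 3, 2))

  # empty triplet -> all-zero matrix of header dimensions
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 2 0"),
             file.path(dir, "matrix.mtx"))
  expect_equal(sum(read_matrix_market(dir)$values), 0)

  # dimension mismatch between ids and header
  writeLines(c("A", "B"), file.path(dir, "features.tsv"))
  expect_error(read_matrix_market(dir), "format error")

  # round-trip on a random integer matrix
  set.seed(42)
  orig <- rand_gene_matrix(50, 20)
  dir2 <- withr::local_tempdir()
  write_matrix_market(orig, dir2)
  back <- read_matrix_market(dir2)
  expect_equal(back$values, orig$values)
  expect_equal(back$gene_ids, orig$gene_ids)
  expect_equal(back$unit_ids, orig$unit_ids)
})

test_that("dense tables parse, flag duplicates, and round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "A,1,2", "B,3,4"), f)
  m <- read_dense_table(f, kind = "intensity")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m$values["B", "s2"], 4)

  # duplicated probe rows load verbatim and are reported
  writeLines(c("gene,s1,s2", "A,1,2", "A,3,4"), f)
  md <- read_dense_table(f, kind = "intensity")
  expect_equal(nrow(md$values), 2)
  expect_equal(attr(md, "duplicate_gene_ids"), "A")

  # non-numeric cell gives coordinates
  writeLines(c("gene,s1,s2", "A,1,x", "B,3,4"), f)
  expect_error(read_dense_table(f, kind = "intensity"),
               "row 1, column 's2'")

  # units-in-rows orientation is transposed on load
  writeLines(c("sample,A,B", "s1,1,3", "s2,2,4"), f)
  mu <- read_dense_table(f, kind = "intensity", orientation = "units_in_rows")
  expect_equal(mu$gene_ids, c("A", "B"))
  expect_equal(unname(mu$values["A", ]), c(1, 2))

  # write/read round-trip preserves values and unit order
  set.seed(11)
  orig <- rand_gene_matrix(15, 6, kind = "intensity")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_dense_table(orig, tf)
  back <- read_dense_table(tf, kind = "intensity")
  expect_equal(back$values, orig$values)
  expect_identical(back$unit_ids, orig$unit_ids)
})

test_that("collapse_probes implements both collapse rules", {
  v <- rbind(p1 = c(1, 3), p2 = c(3, 5), p3 = c(7, 7))
  m <- gene_matrix(v, rownames(v), c("u1", "u2"), "intensity")
  map <- data.frame(probe = c("p1", "p2", "p3"),
                    symbol = c("G", "G", "H"))
  cm <- collapse_probes(m, map, method = "mean")
  expect_equal(unname(cm$values["G", ]), c(2, 4))
  expect_equal(unname(cm$values["H", ]), c(7, 7))  # single probe unchanged
  ck <- collapse_probes(m, map, method = "max_mean_probe")
  expect_equal(unname(ck$values["G", ]), c(3, 5))
  expect_equal(unname(ck$values["H", ]), c(7, 7))
  expect_warning(collapse_probes(m, map[-1, ], method = "mean"),
                 "1 probes absent")
})

test_that("max_mean_probe equals brute-force per-gene argmax of row means", {
  set.seed(3)
  m <- rand_gene_matrix(20, 8, kind = "intensity")
  map <- data.frame(probe = m$gene_ids,
                    symbol = paste0("S", sample(1:8, 20, replace = TRUE)))
  got <- collapse_probes(m, map, method = "max_mean_probe")
  for (s in unique(map$symbol)) {
    probes <- map$probe[map$symbol == s]
    best <- probes[which.max(rowMeans(m$values[probes, , drop = FALSE]))]
    expect_equal(got$values[s, ], setNames(m$values[best, ], got$unit_ids))
  }
})

test_that("mean collapse preserves per-sample totals under a full map", {
  set.seed(4)
  m <- rand_gene_matrix(30, 5, kind = "intensity")
  map <- data.frame(probe = m$gene_ids,
                    symbol = paste0("S", rep(1:10, each = 3)))
  cm <- collapse_probes(m, map, method = "mean")
  # every symbol has 3 probes here, so sum(mean rows) * 3 = original sums
  expect_equal(colSums(cm$values) * 3, colSums(m$values))
})

test_that("GMT files parse, dedup within line, and round-trip", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB", "S2\tdesc\tA\tA\tB"), f)
  panels <- read_gmt(f)
  expect_equal(panels$S1$genes, c("A", "B"))
  expect_equal(panels$S2$genes, c("A", "B"))
  writeLines(c("S1\tdesc\tA", "BAD\tonlydesc"), f)
  expect_error(read_gmt(f), "line 2")

  set.seed(5)
  orig <- lapply(1:5, function(i)
    gene_panel(paste0("P", i), sample(LETTERS, sample(3:10, 1))))
  names(orig) <- vapply(orig, `[[`, character(1), "name")
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(orig, f2)
  back <- read_gmt(f2)
  expect_equal(lapply(back, `[[`, "genes"), lapply(orig, `[[`, "genes"))
})

test_that("interaction tables dedup to max count and reject negatives", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("lncRNA\ttarget\tinteractions", "L1\tG1\t3", "L2\tG2\t0"), f)
  tab <- read_interaction_table(f)
  expect_equal(nrow(tab), 2)
  writeLines(c("lncRNA\ttarget\tinteractions", "L1\tG1\t3", "L1\tG1\t5"), f)
  expect_warning(tab2 <- read_interaction_table(f), "duplicate")
  expect_equal(tab2$n_interactions, 5)
  writeLines(c("lncRNA\ttarget\tinteractions", "L1\tG1\t-2"), f)
  expect_error(read_interaction_table(f), "negative")

  # random 100-row table equals a brute-force group-by-max dedup
  set.seed(9)
  df <- data.frame(lncrna = paste0("L", sample(1:12, 100, replace = TRUE)),
                   mrna = paste0("G", sample(1:12, 100, replace = TRUE)),
                   n_interactions = sample(0:6, 100, replace = TRUE))
  got <- suppressWarnings(interaction_table(df))
  want <- aggregate(n_interactions ~ lncrna + mrna, df, max)
  key <- function(d) paste(d$lncrna, d$mrna)
  expect_setequal(key(got), key(want))
  expect_equal(got$n_interactions,
               want$n_interactions[match(key(got), key(want))])
})

test_that("unit metadata validation catches structural problems", {
  meta <- data.frame(unit_id = c("u1", "u2"), dataset_id = "D",
                     condition = c("T2D", "ND"))
  expect_silent(validate_unit_meta(meta))
  expect_error(validate_unit_meta(meta[, -3]), "lacks columns")
  bad <- meta; bad$condition[1] <- "weird"
  expect_error(validate_unit_meta(bad), "unknown condition")
  expect_error(validate_unit_meta(rbind(meta, meta[1, ])), "duplicate")
  expect_error(validate_unit_meta(meta, units = c("u1", "u3")),
               "does not match")
})
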