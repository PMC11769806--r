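## md5 of an arbitrary R object via deterministic serialization
.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.CONFIG_KEYS <- c("seed", "case", "control", "anchor_gene", "bulk", "scrna",
                  "pbmc", "interactions", "classes", "thresholds",
                  "cluster", "outdir")

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration, injects threshold and contrast defaults,
#' resolves paths relative to the config file, and rejects unknown keys
#' or missing files. Normalization is idempotent: validating an already
#' normalized configuration is a fixed point.
#'
#' @param path YAML file path, or an already-parsed list (then `base_dir`
#'   resolves relative paths).
#' @param base_dir base directory for relative paths (defaults to the
#'   config file's directory).
#' @return object of class `pipeline_config`.
#' @export
validate_config <- function(path, base_dir = NULL) {
  if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- yaml::read_yaml(path)
    base_dir <- base_dir %||% dirname(normalizePath(path))
  } else {
    cfg <- path
    base_dir <- base_dir %||% "."
  }
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  resolve <- function(p, what) {
    if (is.null(p)) return(NULL)
    full <- if (grepl("^/", p)) p else file.path(base_dir, p)
    if (!file.exists(full)) stop(what, " path does not exist: ", full)
    normalizePath(full)
  }
  norm_pair <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (!all(c("matrix", "meta") %in% names(x)))
      stop(what, " entry needs 'matrix' and 'meta' keys")
    list(matrix = resolve(x$matrix, what), meta = resolve(x$meta, what))
  }
  th_args <- cfg$thresholds %||% list()
  bad_th <- setdiff(names(th_args), names(formals(thresholds)))
  if (length(bad_th))
    stop("unknown threshold key(s): ", paste(bad_th, collapse = ", "))
  out <- list(
    seed = as.integer(cfg$seed %||% 1L),
    case = cfg$case %||% "T2D",
    control = cfg$control %||% "ND",
    anchor_gene = cfg$anchor_gene %||% "PDGFRB",
    bulk = norm_pair(cfg$bulk, "bulk"),
    scrna = lapply(cfg$scrna %||% list(), norm_pair, what = "scrna"),
    pbmc = norm_pair(cfg$pbmc, "pbmc"),
    interactions = resolve(cfg$interactions, "interactions"),
    classes = resolve(cfg$classes, "classes"),
    thresholds = do.call(thresholds, th_args),
    cluster = list(
      n_components = cfg$cluster$n_components %||% 30,
      n_neighbors = cfg$cluster$n_neighbors %||% 20,
      resolution = cfg$cluster$resolution %||% 1),
    outdir = cfg$outdir)
  if (is.null(out$bulk) || length(out$scrna) == 0)
    stop("config must provide a bulk dataset and at least one scrna dataset")
  structure(out, class = "pipeline_config")
}

.read_matrix_any <- function(path, kind) {
  if (dir.exists(path)) read_matrix_market(path)
  else read_dense_table(path, kind = kind)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  path
}

#' Run the full cross-dataset analysis pipeline
#'
#' Executes the nine pipeline stages in dependency order: bulk
#' differential expression, single-cell clustering, marker detection,
#' bulk-panel enrichment mapping, cross-dataset cluster matching,
#' anchor-based population identification, shared-signature discovery
#' with the correlation screen and activation scoring, PBMC
#' differential expression, and lncRNA-mRNA network construction with
#' ROC evaluation. Every stage writes TSV outputs into `outdir` and a
#' manifest row (stage, status, outputs, output md5s, parameter hash).
#' PBMC-dependent stages are skipped cleanly when the config provides no
#' PBMC dataset. Re-running with the same config and seed reproduces
#' byte-identical outputs.
#'
#' @param cfg a [validate_config()] result (or a path to a YAML config).
#' @param outdir output directory (created if needed); defaults to the
#'   config's `outdir`.
#' @return object of class `pipeline_run`: list of stage results plus the
#'   manifest data.frame and its md5 `manifest_hash`.
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  outdir <- outdir %||% cfg$outdir
  if (is.null(outdir)) stop("an output directory is required")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  th <- cfg$thresholds
  manifest <- data.frame(stage = character(0), status = character(0),
                         outputs = character(0), md5 = character(0),
                         param_hash = character(0),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(outdir, "manifest.tsv")
  record <- function(stage, status, files, params) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, status = status,
      outputs = paste(basename(files), collapse = ";"),
      md5 = paste(unname(tools::md5sum(files)), collapse = ";"),
      param_hash = .hash_obj(params), stringsAsFactors = FALSE))
    .write_tsv(manifest, manifest_path)
  }
  run_stage <- function(stage, params, fn) {
    files <- tryCatch(fn(), error = function(e) {
      record(stage, "failed", character(0), params)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    record(stage, "complete", files, params)
  }
  results <- list()

  ## 1. bulk differential expression -> up/down panels
  run_stage("bulk_de", list(th = unclass(th), contrast = c(cfg$case, cfg$control)), function() {
    set.seed(cfg$seed + 1)
    bm <- .read_matrix_any(cfg$bulk$matrix, "raw_counts")
    bmeta <- read_unit_meta(cfg$bulk$meta)
    res <- bulk_de(bm, bmeta, contrast = c(cfg$case, cfg$control), th = th)
    results$bulk <<- res
    c(.write_tsv(res$table, file.path(outdir, "de_bulk.tsv")),
      .write_tsv(data.frame(gene = res$up_genes),
                 file.path(outdir, "panel_up.tsv")),
      .write_tsv(data.frame(gene = res$down_genes),
                 file.path(outdir, "panel_down.tsv")))
  })
  if (!length(results$bulk$up_genes))
    stop("stage 'bulk_de' produced an empty up-panel; nothing to map")
  up_panel <- gene_panel("bulk_up", results$bulk$up_genes)

  ## 2. load + cluster the single-cell datasets
  sc <- list()
  run_stage("cluster", cfg$cluster, function() {
    files <- character(0)
    for (i in seq_along(cfg$scrna)) {
      mat <- .read_matrix_any(cfg$scrna[[i]]$matrix, "raw_counts")
      meta <- read_unit_meta(cfg$scrna[[i]]$meta)
      meta <- validate_unit_meta(meta, units = mat$unit_ids)
      ln <- lognormalize(mat)
      if (!is.null(meta$cluster_label) && all(nzchar(meta$cluster_label))) {
        labels <- setNames(meta$cluster_label, meta$unit_id)
      } else {
        labels <- cluster_cells(ln,
                                n_components = cfg$cluster$n_components,
                                n_neighbors = cfg$cluster$n_neighbors,
                                resolution = cfg$cluster$resolution,
                                seed = cfg$seed)
      }
      sc[[i]] <<- list(lognorm = ln, meta = meta, labels = labels,
                       id = unique(meta$dataset_id)[1])
      files <- c(files, .write_tsv(
        data.frame(unit_id = names(labels), cluster = unname(labels)),
        file.path(outdir, sprintf("clusters_%d.tsv", i))))
    }
    files
  })

  ## 3. cluster markers
  run_stage("markers", list(th = unclass(th)), function() {
    files <- character(0)
    for (i in seq_along(sc)) {
      sc[[i]]$markers <<- find_markers(sc[[i]]$lognorm, sc[[i]]$labels,
                                       th = th)
      files <- c(files, .write_tsv(
        sc[[i]]$markers, file.path(outdir, sprintf("markers_%d.tsv", i))))
    }
    files
  })

  ## 4. bulk-panel enrichment by cluster
  run_stage("enrich", list(levels = th$pct1_levels), function() {
    files <- character(0)
    for (i in seq_along(sc)) {
      en <- panel_enrichment_by_cluster(sc[[i]]$lognorm, sc[[i]]$labels,
                                        up_panel, sc[[i]]$markers,
                                        pct_levels = th$pct1_levels)
      sc[[i]]$enrichment <<- en
      df <- data.frame(cluster = rownames(en$overlap_counts),
                       mean_score = as.vector(en$mean_score),
                       en$overlap_counts, check.names = FALSE)
      files <- c(files, .write_tsv(
        df, file.path(outdir, sprintf("enrichment_%d.tsv", i))))
    }
    files
  })

  ## 5. cross-dataset cluster matching
  run_stage("match", list(), function() {
    files <- character(0)
    if (length(sc) >= 2) {
      profs <- lapply(sc, function(d) cluster_profiles(d$lognorm, d$labels))
      for (i in seq_along(sc)) for (j in seq_along(sc)) {
        if (i >= j) next
        ps <- pearson_similarity(profs[[i]], profs[[j]])
        mo <- marker_overlap(sc[[i]]$markers, sc[[j]]$markers)
        long <- expand.grid(cluster_a = rownames(ps$pearson),
                            cluster_b = colnames(ps$pearson),
                            KEEP.OUT.ATTRS = FALSE)
        long$pearson_r <- as.vector(ps$pearson)
        long$n_shared_genes <- ps$n_shared_genes
        long$overlap_ratio_row <- as.vector(
          mo$overlap_row[as.matrix(long[, 1:2])])
        long$overlap_ratio_col <- as.vector(
          mo$overlap_col[as.matrix(long[, 1:2])])
        files <- c(files, .write_tsv(
          long, file.path(outdir, sprintf("similarity_%d_%d.tsv", i, j))))
      }
    }
    files
  })

  ## 6. anchor-based population identification
  run_stage("population", list(anchor = cfg$anchor_gene), function() {
    pop <- vapply(seq_along(sc), function(i) {
      identify_population(sc[[i]]$lognorm, sc[[i]]$labels, cfg$anchor_gene)
    }, character(1))
    for (i in seq_along(sc)) sc[[i]]$population <<- pop[i]
    .write_tsv(data.frame(dataset = vapply(sc, `[[`, character(1), "id"),
                          population_cluster = pop),
               file.path(outdir, "population.tsv"))
  })

  ## 7. shared signature + correlation screen + activation scoring
  run_stage("signature", list(th = unclass(th)), function() {
    ds <- lapply(sc, function(d)
      list(matrix = d$lognorm, meta = d$meta,
           mask = unname(d$labels == d$population)))
    cu <- common_upregulated(ds, contrast = c(cfg$case, cfg$control), th = th)
    results$common_up <<- cu
    files <- .write_tsv(data.frame(gene = cu$genes),
                        file.path(outdir, "common_up.tsv"))
    if (length(cu$genes)) {
      screen <- correlation_screen(ds, gene_panel("signature", cu$genes),
                                   th = th)
      if (!is.null(cfg$classes) && nrow(screen$hits)) {
        cls <- read.delim(cfg$classes, colClasses = "character")
        screen$hits <- cbind(screen$hits,
                             classes = annotate_classes(screen$hits$gene,
                                                        cls)$classes)
      }
      results$screen <<- screen
      files <- c(files, .write_tsv(screen$hits,
                                   file.path(outdir, "corr_screen.tsv")))
    }
    act <- do.call(rbind, lapply(sc, function(d) {
      mask <- d$labels == d$population
      s <- activation_score(d$lognorm, scope = mask)
      data.frame(dataset = d$id, condition = d$meta$condition[mask],
                 score = unname(s$scores))
    }))
    c(files, .write_tsv(act, file.path(outdir, "activation_scores.tsv")))
  })

  ## 8. PBMC differential expression
  pbmc <- NULL
  if (!is.null(cfg$pbmc)) {
    run_stage("pbmc_de", list(th = unclass(th)), function() {
      pm <- .read_matrix_any(cfg$pbmc$matrix, "intensity")
      pmeta <- read_unit_meta(cfg$pbmc$meta)
      res <- pbmc_upregulated(pm, pmeta, contrast = c(cfg$case, cfg$control),
                              th = th)
      pbmc <<- list(matrix = pm, meta = pmeta, de = res)
      results$pbmc <<- res
      .write_tsv(res$table[res$table$gene %in% res$up_genes, ],
                 file.path(outdir, "pbmc_up.tsv"))
    })
  } else {
    record("pbmc_de", "skipped", character(0), list())
  }

  ## 9. lncRNA-mRNA network + panel ROC
  if (!is.null(pbmc) && !is.null(cfg$interactions)) {
    run_stage("network", list(min = th$interactions_min), function() {
      records <- read_interaction_table(cfg$interactions)
      sig <- c(results$common_up$genes,
               if (!is.null(results$screen)) results$screen$hits$gene)
      net <- build_network(records, sig, pbmc$de$up_genes, th = th)
      results$network <<- net
      files <- write_network(net, file.path(outdir, "network_edges.tsv"),
                             file.path(outdir, "network.graphml"))
      files <- c(files, file.path(outdir, "network.graphml"))
      if (length(net$lncrnas)) {
        roc <- lncrna_panel_roc(pbmc$matrix, pbmc$meta, net$lncrnas,
                                contrast = c(cfg$case, cfg$control))
        results$lncrna_roc <<- roc
        files <- c(files, .write_tsv(
          data.frame(feature = c("combined", names(roc$per_lncrna)),
                     auc = c(roc$combined$auc,
                             vapply(roc$per_lncrna, `[[`, numeric(1), "auc"))),
          file.path(outdir, "lncrna_auc.tsv")))
      }
      files
    })
  } else {
    record("network", "skipped", character(0), list())
  }

  results$sc <- sc
  results$manifest <- manifest
  results$manifest_hash <- unname(tools::md5sum(manifest_path))
  results$outdir <- outdir
  class(results) <- "pipeline_run"
  results
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$manifest[c("stage", "status", "outputs")])
  invisible(x)
}
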