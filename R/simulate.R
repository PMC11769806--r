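#' Synthetic study configuration
#'
#' Defines the multi-dataset cohort the generator emulates: several
#' single-cell datasets sharing eight islet cell types (one rare stromal
#' "stellate" population), negative-binomial counts with dataset-specific
#' sequencing depth, a planted condition-specific up-regulated gene set in
#' case-condition stellate cells, a pseudo-bulk case/control cohort, a
#' microarray-like PBMC matrix carrying lncRNAs, and an interaction table
#' with planted lncRNA-mRNA edges. The seed fully determines every output.
#'
#' Counts are negative binomial with variance `mu + mu^2 * nb_dispersion`
#' and a per-cell log-normal library-size factor (sigma `lib_sigma`).
#' Marker genes are type-exclusive multiplicative bumps (`2^marker_effect`),
#' so ground-truth cluster matching is well defined. The planted signature
#' genes are stellate-specific (multiplier `2^signature_psc_log2fc` in all
#' stellate cells) and additionally multiplied by `2^signature_effect` in
#' case-condition stellate cells only. The built-in stromal activation
#' genes are simulated as stellate-elevated identity genes; an optional
#' `activation_effect` adds a case-condition shift to them.
#'
#' @param seed integer master seed.
#' @param n_datasets number of single-cell datasets.
#' @param n_genes gene-universe size.
#' @param n_cells_per_dataset cells per single-cell dataset.
#' @param cell_types data.frame with columns `name`, `proportion`, `scale`;
#'   proportions must sum to 1 and must include the target type.
#' @param target_type cell type carrying the planted signature.
#' @param markers_per_type type-exclusive marker genes per type.
#' @param marker_effect log2 effect of marker genes in their own type.
#' @param signature_genes names of the planted condition-specific genes.
#' @param signature_effect log2 condition effect in case-condition target cells.
#' @param signature_psc_log2fc log2 target-type specificity of signature genes.
#' @param activation_effect log2 condition effect on activation-panel genes.
#' @param nb_dispersion global NB dispersion (variance `mu + mu^2 * disp`).
#' @param lib_sigma log-normal sigma of per-cell library-size jitter.
#' @param depth_scale per-dataset depth multipliers (recycled).
#' @param gene_keep_fraction fraction of non-special genes each dataset keeps.
#' @param case,control condition labels of the contrast.
#' @param n_donors_per_condition donors per condition per dataset.
#' @param n_bulk_samples_per_condition pseudo-bulk samples per condition.
#' @param cells_per_bulk cells summed per pseudo-bulk sample.
#' @param lncrna_genes planted lncRNA symbols for the PBMC matrix.
#' @param n_decoy_lncrna decoy lncRNA features in the PBMC matrix.
#' @param n_up_mrna planted up-regulated mRNAs in the PBMC matrix.
#' @param pbmc_shift_sd case up-shift of planted PBMC features, in units of
#'   the array's within-gene SD.
#' @param array_sigma within-gene SD of log2 intensities.
#' @param n_pbmc_per_condition PBMC samples per condition.
#' @param planted_interactions data.frame (`lncrna`, `mrna`) of planted
#'   edges, or `NULL` for all lncRNA x signature-gene pairs.
#' @param n_decoy_records decoy rows in the interaction table.
#' @param decoy_zero_fraction fraction of decoy rows with count 0.
#' @param module_size size of the latent-factor co-expression module used
#'   by [simulate_correlated_psc()].
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_datasets = 3,
                         n_genes = 2000,
                         n_cells_per_dataset = 3000,
                         cell_types = NULL,
                         target_type = "stellate",
                         markers_per_type = 25,
                         marker_effect = 3,
                         signature_genes = c("COL1A2", "VCAN", "SULF1"),
                         signature_effect = 2,
                         signature_psc_log2fc = 5,
                         activation_effect = 0,
                         nb_dispersion = 0.3,
                         lib_sigma = 0.3,
                         depth_scale = c(1, 0.6, 1.4),
                         gene_keep_fraction = 0.9,
                         case = "T2D",
                         control = "ND",
                         n_donors_per_condition = 3,
                         n_bulk_samples_per_condition = 30,
                         cells_per_bulk = 400,
                         lncrna_genes = c("LINC00472", "SNHG14", "C5orf66",
                                          "PWRN1", "ZFAS1", "ZRANB2-AS2"),
                         n_decoy_lncrna = 40,
                         n_up_mrna = 50,
                         pbmc_shift_sd = 4,
                         array_sigma = 0.5,
                         n_pbmc_per_condition = 5,
                         planted_interactions = NULL,
                         n_decoy_records = 500,
                         decoy_zero_fraction = 0.2,
                         module_size = 46) {
  if (is.null(cell_types))
    cell_types <- data.frame(
      name = c("alpha", "beta", "delta", "gamma", "ductal", "acinar",
               "endothelial", "stellate"),
      proportion = c(0.25, 0.30, 0.08, 0.07, 0.10, 0.08, 0.07, 0.05),
      scale = 1,
      stringsAsFactors = FALSE)
  if (abs(sum(cell_types$proportion) - 1) > 1e-8)
    stop("cell type proportions must sum to 1")
  if (!target_type %in% cell_types$name)
    stop("config error: target type '", target_type,
         "' absent from cell_types")
  n_types <- nrow(cell_types)
  n_special <- n_types * markers_per_type + length(signature_genes) + 7 +
    module_size
  if (n_genes < n_special + 100)
    stop("n_genes too small for the configured special gene blocks")
  cfg <- as.list(environment())
  cfg$cell_types <- cell_types
  structure(cfg, class = "synth_config")
}

## deterministic sub-seed per generator stage (kept < 2^31)
.sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(offset)
}

#' Ground-truth gene sets of a synthetic configuration
#'
#' @param cfg a [synth_config()].
#' @return list with per-type `markers`, the planted `signature`, the
#'   `activation` genes, the `anchor` gene, the latent-factor `module`
#'   genes, and the full `universe`.
#' @export
synth_gene_sets <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n_types <- nrow(cfg$cell_types)
  k <- cfg$markers_per_type
  universe <- sprintf("G%04d", seq_len(cfg$n_genes))
  markers <- lapply(seq_len(n_types), function(t)
    universe[((t - 1) * k + 1):(t * k)])
  names(markers) <- cfg$cell_types$name
  ## anchor: first marker of the target type, renamed to the canonical
  ## stromal marker symbol
  anchor <- "PDGFRB"
  t_idx <- match(cfg$target_type, cfg$cell_types$name)
  universe[(t_idx - 1) * k + 1] <- anchor
  markers[[cfg$target_type]][1] <- anchor
  sig_idx <- (n_types * k + 1):(n_types * k + length(cfg$signature_genes))
  universe[sig_idx] <- cfg$signature_genes
  act_extra <- c("LAMB1", "ACTA2", "FN1", "COL1A1", "COL3A1", "MMP1", "MMP2")
  act_idx <- max(sig_idx) + seq_along(act_extra)
  universe[act_idx] <- act_extra
  activation <- unique(c(act_extra, intersect(activation_panel()$genes,
                                              cfg$signature_genes)))
  mod_idx <- max(act_idx) + seq_len(cfg$module_size)
  list(markers = markers,
       signature = cfg$signature_genes,
       activation = activation,
       anchor = anchor,
       module = universe[mod_idx],
       universe = universe)
}

## genes x types matrix of NB means, deterministic in cfg$seed
.build_profiles <- function(cfg) {
  gs <- synth_gene_sets(cfg)
  set.seed(.sub_seed(cfg$seed, 999L))
  base <- rlnorm(cfg$n_genes, meanlog = log(0.3), sdlog = 1)
  names(base) <- gs$universe
  marker_all <- unlist(gs$markers)
  base[marker_all] <- pmax(base[marker_all], 0.5)
  base[gs$anchor] <- pmax(base[gs$anchor], 1)
  base[gs$signature] <- 0.1
  act_extra <- setdiff(gs$activation, gs$signature)
  base[act_extra] <- pmax(base[act_extra], 0.3)
  prof <- matrix(base, nrow = cfg$n_genes, ncol = nrow(cfg$cell_types),
                 dimnames = list(gs$universe, cfg$cell_types$name))
  prof <- sweep(prof, 2, cfg$cell_types$scale, "*")
  for (t in cfg$cell_types$name)
    prof[gs$markers[[t]], t] <- prof[gs$markers[[t]], t] * 2^cfg$marker_effect
  prof[gs$signature, cfg$target_type] <-
    prof[gs$signature, cfg$target_type] * 2^cfg$signature_psc_log2fc
  prof[act_extra, cfg$target_type] <- prof[act_extra, cfg$target_type] * 8
  list(profiles = prof, gene_sets = gs)
}

## per-dataset gene universe (special genes always retained)
.dataset_genes <- function(cfg, gs, dataset_index) {
  special <- unique(c(unlist(gs$markers), gs$signature, gs$activation,
                      gs$anchor, gs$module))
  others <- setdiff(gs$universe, special)
  set.seed(.sub_seed(cfg$seed, 700L + dataset_index))
  keep_others <- sort(sample(seq_along(others),
                             round(cfg$gene_keep_fraction * length(others))))
  keep <- gs$universe %in% c(special, others[keep_others])
  gs$universe[keep]
}

#' Simulate one single-cell dataset
#'
#' Negative-binomial counts with per-type mean profiles, dataset depth
#' scaling and per-cell library-size jitter. Case-condition cells of the
#' target type have the planted signature genes' means multiplied by
#' `2^signature_effect`. Metadata records the ground-truth cell type,
#' donor and condition.
#'
#' @param cfg a [synth_config()].
#' @param dataset_index which dataset (1-based; sets depth and sub-seed).
#' @return list with `matrix` (a raw-count [gene_matrix()]) and `meta`
#'   (unit metadata data.frame).
#' @export
simulate_scrna <- function(cfg, dataset_index = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  pr <- .build_profiles(cfg)
  gs <- pr$gene_sets
  depth <- rep_len(cfg$depth_scale, cfg$n_datasets)[dataset_index]
  n <- cfg$n_cells_per_dataset
  ds_id <- paste0("DS", dataset_index)
  set.seed(.sub_seed(cfg$seed, 10L + dataset_index))
  types <- sample(cfg$cell_types$name, n, replace = TRUE,
                  prob = cfg$cell_types$proportion)
  donors <- paste0(ds_id, "_", rep(c(cfg$case, cfg$control),
                                   each = cfg$n_donors_per_condition),
                   "_D", seq_len(cfg$n_donors_per_condition))
  donor_cond <- rep(c(cfg$case, cfg$control),
                    each = cfg$n_donors_per_condition)
  donor_of <- sample(seq_along(donors), n, replace = TRUE)
  cond <- donor_cond[donor_of]
  lib <- rlnorm(n, 0, cfg$lib_sigma)
  mu <- pr$profiles[, types, drop = FALSE]
  mu <- sweep(mu, 2, depth * lib, "*")
  bump <- which(types == cfg$target_type & cond == cfg$case)
  if (length(bump)) {
    mu[gs$signature, bump] <- mu[gs$signature, bump] * 2^cfg$signature_effect
    if (cfg$activation_effect != 0) {
      act_extra <- setdiff(gs$activation, gs$signature)
      mu[act_extra, bump] <- mu[act_extra, bump] * 2^cfg$activation_effect
    }
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  keep_genes <- .dataset_genes(cfg, gs, dataset_index)
  counts <- counts[keep_genes, , drop = FALSE]
  unit_ids <- paste0(ds_id, "_C", seq_len(n))
  colnames(counts) <- unit_ids
  meta <- data.frame(unit_id = unit_ids, dataset_id = ds_id,
                     donor_id = donors[donor_of], condition = cond,
                     cell_type = types, stringsAsFactors = FALSE)
  list(matrix = gene_matrix(counts, keep_genes, unit_ids, "raw_counts"),
       meta = meta)
}

#' Simulate a pseudo-bulk case/control cohort
#'
#' Each sample is the summed expression of a freshly drawn cell population
#' with the sample's condition: the per-type cell counts are multinomial in
#' the configured proportions, and the per-type contribution is the exact
#' negative-binomial sum of that many independent cells. Planted signature
#' genes are therefore enriched in case samples in proportion to the
#' target-type abundance.
#'
#' @param cfg a [synth_config()].
#' @return list with `matrix` (raw-count [gene_matrix()]) and `meta`.
#' @export
simulate_bulk <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  pr <- .build_profiles(cfg)
  gs <- pr$gene_sets
  set.seed(.sub_seed(cfg$seed, 101L))
  conds <- rep(c(cfg$case, cfg$control),
               each = cfg$n_bulk_samples_per_condition)
  n_s <- length(conds)
  counts <- matrix(0, cfg$n_genes, n_s,
                   dimnames = list(gs$universe, NULL))
  size_inv <- cfg$nb_dispersion
  for (j in seq_len(n_s)) {
    ncell <- as.vector(rmultinom(1, cfg$cells_per_bulk,
                                 cfg$cell_types$proportion))
    depth <- rlnorm(1, 0, 0.2)
    tot <- numeric(cfg$n_genes)
    for (t in seq_len(nrow(cfg$cell_types))) {
      if (ncell[t] == 0) next
      mu_t <- pr$profiles[, t] * depth
      if (conds[j] == cfg$case && cfg$cell_types$name[t] == cfg$target_type)
        mu_t[gs$signature] <- mu_t[gs$signature] * 2^cfg$signature_effect
      ## sum of k iid NB(mu, size) is NB(k*mu, k*size)
      tot <- tot + rnbinom(cfg$n_genes, mu = ncell[t] * mu_t,
                           size = ncell[t] / size_inv)
    }
    counts[, j] <- tot
  }
  unit_ids <- sprintf("BULK_%s_%02d", conds,
                      stats::ave(seq_len(n_s), conds, FUN = seq_along))
  colnames(counts) <- unit_ids
  meta <- data.frame(unit_id = unit_ids, dataset_id = "BULK",
                     donor_id = unit_ids, condition = conds,
                     stringsAsFactors = FALSE)
  list(matrix = gene_matrix(counts, gs$universe, unit_ids, "raw_counts"),
       meta = meta)
}

#' Simulate a PBMC-like expression microarray
#'
#' Log-normal intensities over the mRNA universe plus planted and decoy
#' lncRNA features. Planted lncRNAs (and `n_up_mrna` planted mRNAs) are
#' up-shifted in case samples by `pbmc_shift_sd` within-gene SDs on the
#' log2 scale. Values are returned on the linear intensity scale.
#'
#' @param cfg a [synth_config()].
#' @return list with `matrix` (intensity [gene_matrix()]), `meta`, and the
#'   planted `up_lncrnas` / `up_mrnas`.
#' @export
simulate_pbmc_array <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  gs <- synth_gene_sets(cfg)
  decoy_lnc <- sprintf("LNC%04d", seq_len(cfg$n_decoy_lncrna))
  features <- c(gs$universe, cfg$lncrna_genes, decoy_lnc)
  set.seed(.sub_seed(cfg$seed, 202L))
  non_special <- setdiff(gs$universe,
                         c(unlist(gs$markers), gs$signature, gs$activation,
                           gs$anchor, gs$module))
  up_mrna <- sample(non_special, min(cfg$n_up_mrna, length(non_special)))
  n_s <- 2 * cfg$n_pbmc_per_condition
  conds <- rep(c(cfg$case, cfg$control), each = cfg$n_pbmc_per_condition)
  base <- rnorm(length(features), mean = 6, sd = 1.5)
  log2v <- matrix(base, length(features), n_s) +
    matrix(rnorm(length(features) * n_s, 0, cfg$array_sigma),
           length(features), n_s)
  shift <- cfg$pbmc_shift_sd * cfg$array_sigma
  planted <- c(cfg$lncrna_genes, up_mrna)
  log2v[match(planted, features), conds == cfg$case] <-
    log2v[match(planted, features), conds == cfg$case] + shift
  unit_ids <- sprintf("PBMC_%s_%02d", conds,
                      stats::ave(seq_len(n_s), conds, FUN = seq_along))
  vals <- 2^log2v
  dimnames(vals) <- list(features, unit_ids)
  meta <- data.frame(unit_id = unit_ids, dataset_id = "PBMC",
                     donor_id = unit_ids, condition = conds,
                     stringsAsFactors = FALSE)
  list(matrix = gene_matrix(vals, features, unit_ids, "intensity"),
       meta = meta, up_lncrnas = cfg$lncrna_genes, up_mrnas = up_mrna)
}

#' Simulate an lncRNA-mRNA interaction table
#'
#' Contains every planted (lncrna, mrna) pair with count >= 1 plus
#' `n_decoy_records` decoy rows drawn from decoy lncRNAs and
#' non-signature mRNAs, a configurable fraction of them with count 0.
#'
#' @param cfg a [synth_config()].
#' @return data.frame with columns `lncrna`, `mrna`, `n_interactions`; the
#'   planted rows carry attribute `"planted"`.
#' @export
simulate_interaction_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  gs <- synth_gene_sets(cfg)
  set.seed(.sub_seed(cfg$seed, 303L))
  planted <- cfg$planted_interactions
  if (is.null(planted))
    planted <- expand.grid(lncrna = cfg$lncrna_genes,
                           mrna = cfg$signature_genes,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
  planted$n_interactions <- sample(1:5, nrow(planted), replace = TRUE)
  out <- planted
  if (cfg$n_decoy_records > 0) {
    decoy_lnc <- sprintf("LNC%04d", seq_len(max(cfg$n_decoy_lncrna, 10)))
    pool_mrna <- setdiff(gs$universe, cfg$signature_genes)
    n_try <- cfg$n_decoy_records * 3
    cand <- data.frame(lncrna = sample(decoy_lnc, n_try, replace = TRUE),
                       mrna = sample(pool_mrna, n_try, replace = TRUE),
                       stringsAsFactors = FALSE)
    cand <- cand[!duplicated(paste(cand$lncrna, cand$mrna)), , drop = FALSE]
    cand <- cand[seq_len(min(cfg$n_decoy_records, nrow(cand))), , drop = FALSE]
    n_zero <- round(cfg$decoy_zero_fraction * nrow(cand))
    cand$n_interactions <- c(rep(0L, n_zero),
                             sample(1:5, nrow(cand) - n_zero, replace = TRUE))
    out <- rbind(planted, cand)
  }
  out <- interaction_table(out)
  attr(out, "planted") <- planted[c("lncrna", "mrna")]
  out
}

#' Simulate a stromal-cell matrix with a latent co-expression module
#'
#' Generates log-normalized-scale expression for target-type cells in
#' which the planted signature genes (the screen anchors) and a module of
#' `module_size` genes load on a shared latent factor, so downstream
#' correlation screening has a defined ground truth. Background genes are
#' independent noise. Optionally the activation-panel genes load on the
#' same factor (`activation_loading`) and/or anchors plus activation genes
#' receive a case-condition shift (`condition_effect`).
#'
#' @param cfg a [synth_config()].
#' @param dataset_index sub-seed selector.
#' @param n_cells number of cells.
#' @param loading latent-factor loading of anchors and module genes.
#' @param activation_loading latent-factor loading of activation genes.
#' @param condition_effect additive case shift on anchors and activation
#'   genes (lognorm scale).
#' @return list with `matrix` (lognorm [gene_matrix()]), `meta`,
#'   `module_genes` and `anchors`.
#' @export
simulate_correlated_psc <- function(cfg, dataset_index = 1, n_cells = 1000,
                                    loading = 0.8, activation_loading = 0,
                                    condition_effect = 0) {
  stopifnot(inherits(cfg, "synth_config"), loading >= 0, loading <= 1)
  gs <- synth_gene_sets(cfg)
  set.seed(.sub_seed(cfg$seed, 404L + dataset_index))
  genes <- gs$universe
  n_g <- length(genes)
  z <- rnorm(n_cells)
  vals <- matrix(rnorm(n_g * n_cells), n_g, n_cells,
                 dimnames = list(genes, NULL))
  lam <- setNames(numeric(n_g), genes)
  lam[c(gs$signature, gs$module)] <- loading
  act_extra <- setdiff(gs$activation, gs$signature)
  lam[act_extra] <- activation_loading
  vals <- vals * sqrt(1 - lam^2) + outer(lam, z) + 1
  conds <- rep(c(cfg$case, cfg$control), length.out = n_cells)
  if (condition_effect != 0) {
    tgt <- c(gs$signature, act_extra)
    vals[tgt, conds == cfg$case] <- vals[tgt, conds == cfg$case] +
      condition_effect
  }
  unit_ids <- paste0("PSC", dataset_index, "_C", seq_len(n_cells))
  colnames(vals) <- unit_ids
  meta <- data.frame(unit_id = unit_ids,
                     dataset_id = paste0("PSC", dataset_index),
                     donor_id = unit_ids, condition = conds,
                     stringsAsFactors = FALSE)
  list(matrix = gene_matrix(vals, genes, unit_ids, "lognorm"),
       meta = meta, module_genes = gs$module, anchors = gs$signature)
}

#' Simulate a protein-class annotation table
#'
#' Assigns one or two of the four protein classes (transcription_factor,
#' secreted, membrane, intracellular) to the signature and module genes,
#' mimicking a protein-atlas-style export; multi-class genes get one row
#' per class.
#'
#' @param cfg a [synth_config()].
#' @return data.frame with columns `gene`, `class`.
#' @export
simulate_class_table <- function(cfg) {
  gs <- synth_gene_sets(cfg)
  set.seed(.sub_seed(cfg$seed, 505L))
  classes <- c("transcription_factor", "secreted", "membrane", "intracellular")
  genes <- c(gs$signature, gs$module)
  rows <- lapply(genes, function(g) {
    k <- sample(1:2, 1, prob = c(0.7, 0.3))
    data.frame(gene = g,
               class = sample(classes, k, prob = c(0.1, 0.3, 0.25, 0.35)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a complete synthetic input bundle to disk
#'
#' Produces every file the pipeline consumes, in the formats the readers
#' expect (Matrix Market triplets for single-cell counts, dense TSVs for
#' bulk and PBMC, TSV metadata, interaction and class tables), plus a
#' ready-to-run pipeline `config.yaml`.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory.
#' @return path of the written pipeline config, invisibly.
#' @export
write_synthetic_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr_meta <- function(meta, path)
    write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  bulk <- simulate_bulk(cfg)
  write_dense_table(bulk$matrix, file.path(dir, "bulk.tsv"))
  wr_meta(bulk$meta, file.path(dir, "bulk_meta.tsv"))
  sc_entries <- list()
  for (d in seq_len(cfg$n_datasets)) {
    sc <- simulate_scrna(cfg, d)
    sub <- file.path(dir, paste0("scrna_", d))
    write_matrix_market(sc$matrix, sub)
    wr_meta(sc$meta, file.path(dir, paste0("scrna_meta_", d, ".tsv")))
    sc_entries[[d]] <- list(matrix = paste0("scrna_", d),
                            meta = paste0("scrna_meta_", d, ".tsv"))
  }
  pbmc <- simulate_pbmc_array(cfg)
  write_dense_table(pbmc$matrix, file.path(dir, "pbmc.tsv"))
  wr_meta(pbmc$meta, file.path(dir, "pbmc_meta.tsv"))
  inter <- simulate_interaction_table(cfg)
  write.table(data.frame(lncRNA = inter$lncrna, target = inter$mrna,
                         interactions = inter$n_interactions),
              file.path(dir, "interactions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(simulate_class_table(cfg), file.path(dir, "classes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gs <- synth_gene_sets(cfg)
  config <- list(seed = cfg$seed,
                 case = cfg$case, control = cfg$control,
                 anchor_gene = gs$anchor,
                 bulk = list(matrix = "bulk.tsv", meta = "bulk_meta.tsv"),
                 scrna = sc_entries,
                 pbmc = list(matrix = "pbmc.tsv", meta = "pbmc_meta.tsv"),
                 interactions = "interactions.tsv",
                 classes = "classes.tsv")
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
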