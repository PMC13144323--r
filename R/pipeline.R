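# End-to-end driver: simulate -> segment -> features -> [embed] ->
# balance -> cluster -> enrich/predict -> [quantify], with per-stage
# cached outputs keyed by content hashes and a run manifest.

#' Pipeline configuration
#'
#' A master seed deterministically derives every stage's seed. Stage
#' toggles switch optional stages; `use_embedding` switches the
#' clustering input between handcrafted features (default) and VAE
#' latents.
#'
#' @param cohort a [cohort_config()] (its `seed` is overridden by the
#'   derived stage seed).
#' @param clustering a [clustering_config()] (ditto).
#' @param out_root output directory.
#' @param master_seed master seed.
#' @param use_embedding cluster on VAE latents instead of handcrafted
#'   features.
#' @param vae a [vae_config()] (used when `use_embedding` is `TRUE`).
#' @param min_cells patient exclusion threshold for prediction.
#' @param n_estimators random-forest size.
#' @param stages named logical vector toggling `quantify` and `report`.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            clustering = clustering_config(),
                            out_root = tempfile("chromacyte_run_"),
                            master_seed = 1,
                            use_embedding = FALSE,
                            vae = vae_config(),
                            min_cells = 100,
                            n_estimators = 10,
                            stages = c(quantify = FALSE, report = TRUE)) {
  structure(
    list(cohort = cohort, clustering = clustering, out_root = out_root,
         master_seed = as.integer(master_seed),
         use_embedding = use_embedding, vae = vae,
         min_cells = min_cells, n_estimators = n_estimators,
         stages = stages),
    class = "pipeline_config"
  )
}

hash_file <- function(path) unname(tools::md5sum(path))

hash_obj <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(x), collapse = "\n"), tmp)
  hash_file(tmp)
}

stage_record_path <- function(root, stage) {
  file.path(root, "cache", paste0(stage, ".json"))
}

stage_cached <- function(root, stage, input_hash) {
  rp <- stage_record_path(root, stage)
  if (!file.exists(rp)) return(FALSE)
  rec <- jsonlite::read_json(rp)
  if (!identical(rec$input_hash, input_hash)) return(FALSE)
  outs <- unlist(rec$outputs)
  all(file.exists(file.path(root, names(outs)))) &&
    all(vapply(names(outs), function(f)
      identical(hash_file(file.path(root, f)), outs[[f]]), logical(1)))
}

stage_commit <- function(root, stage, input_hash, out_files, seed) {
  outs <- lapply(out_files, function(f) hash_file(file.path(root, f)))
  names(outs) <- out_files
  rec <- list(stage = stage, input_hash = input_hash, outputs = outs,
              seed = seed)
  dir.create(file.path(root, "cache"), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(rec, stage_record_path(root, stage), auto_unbox = TRUE)
  rec
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, skipping stages whose
#' inputs (config + upstream outputs) are unchanged since the cached
#' run. All tabular outputs are CSV/JSON under `config$out_root`.
#'
#' @param config a [pipeline_config()].
#' @return A run manifest: list of per-stage records (stage, seed,
#'   skipped flag, output files with content hashes).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  root <- config$out_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  seed_of <- function(stage) derive_seed(config$master_seed, stage)

  # -- simulate ------------------------------------------------------------
  sim_cfg <- config$cohort
  sim_cfg$seed <- seed_of("simulate")
  sim_hash <- hash_obj(unclass(sim_cfg))
  sim_files <- c("manifest.csv", "truth.csv")
  if (stage_cached(root, "simulate", sim_hash)) {
    manifest$simulate <- c(jsonlite::read_json(stage_record_path(root, "simulate")),
                           skipped = TRUE)
  } else {
    write_cohort(sim_cfg, root)
    manifest$simulate <- c(stage_commit(root, "simulate", sim_hash, sim_files,
                                        sim_cfg$seed), skipped = FALSE)
  }
  cohort_manifest <- read.csv(file.path(root, "manifest.csv"),
                              stringsAsFactors = FALSE)

  # -- segment + features (per stack) --------------------------------------
  seg_hash <- hash_obj(list(sim_hash, "segment_features"))
  feat_file <- "features.csv"
  seg_file <- "segmentation.csv"
  if (stage_cached(root, "segment_features", seg_hash)) {
    manifest$segment_features <- c(
      jsonlite::read_json(stage_record_path(root, "segment_features")),
      skipped = TRUE)
  } else {
    seg_rows <- list()
    feat_rows <- list()
    for (i in seq_len(nrow(cohort_manifest))) {
      st <- read_stack(file.path(root, cohort_manifest$path[i]),
                       spacing = sim_cfg$voxel_spacing)
      seg <- segment_stack(st, individual_id = cohort_manifest$individual_id[i],
                           condition = cohort_manifest$condition[i])
      if (nrow(seg$records) == 0) next
      recs <- seg$records
      recs$nucleus_id <- paste0(cohort_manifest$nucleus_id[i],
                                ifelse(nrow(recs) > 1,
                                       paste0("_r", seq_len(nrow(recs))), ""))
      seg_rows[[length(seg_rows) + 1]] <- recs
      ft <- compute_feature_matrix(st, seg)
      ft$nucleus_id <- recs$nucleus_id
      feat_rows[[length(feat_rows) + 1]] <- ft
    }
    seg_all <- do.call(rbind, seg_rows)
    feat_all <- do.call(rbind, feat_rows)
    write.csv(seg_all, file.path(root, seg_file), row.names = FALSE)
    write.csv(feat_all, file.path(root, feat_file), row.names = FALSE)
    manifest$segment_features <- c(
      stage_commit(root, "segment_features", seg_hash, c(seg_file, feat_file),
                   NA), skipped = FALSE)
  }
  features <- read.csv(file.path(root, feat_file), stringsAsFactors = FALSE)

  # -- balance ---------------------------------------------------------------
  bal_seed <- seed_of("balance")
  bal_hash <- hash_obj(list(seg_hash, bal_seed))
  bal_file <- "balanced_manifest.csv"
  if (stage_cached(root, "balance", bal_hash)) {
    manifest$balance <- c(jsonlite::read_json(stage_record_path(root, "balance")),
                          skipped = TRUE)
  } else {
    counts <- aggregate(nucleus_id ~ individual_id + condition, data = features,
                        FUN = length)
    names(counts)[3] <- "n_nuclei"
    bal <- balance_counts(counts)
    sel <- select_nuclei(features[, c("nucleus_id", "individual_id")], bal,
                         seed = bal_seed)
    out <- data.frame(nucleus_id = sel$nucleus_id,
                      individual_id = sel$individual_id,
                      k_min = attr(bal, "k_min"))
    write.csv(out, file.path(root, bal_file), row.names = FALSE)
    manifest$balance <- c(stage_commit(root, "balance", bal_hash, bal_file,
                                       bal_seed), skipped = FALSE)
  }
  balanced <- read.csv(file.path(root, bal_file), stringsAsFactors = FALSE)
  k_min <- balanced$k_min[1]
  cells <- features[features$nucleus_id %in% balanced$nucleus_id, ]

  # -- optional embedding ----------------------------------------------------
  feature_cols <- setdiff(names(cells),
                          c("nucleus_id", "individual_id", "condition",
                            "label_id"))
  X <- as.matrix(cells[, feature_cols])
  X <- scale(X)
  X[!is.finite(X)] <- 0
  if (isTRUE(config$use_embedding)) {
    emb_seed <- seed_of("embed")
    vcfg <- config$vae
    vcfg$seed <- emb_seed
    stacks <- list(); masks <- list()
    sel_rows <- match(cells$nucleus_id, cohort_manifest$nucleus_id)
    for (j in seq_along(sel_rows)) {
      st <- read_stack(file.path(root, cohort_manifest$path[sel_rows[j]]),
                       spacing = sim_cfg$voxel_spacing)
      seg <- segment_stack(st)
      stacks[[j]] <- st
      masks[[j]] <- seg$labels == 1
    }
    fovs <- build_fov_array(stacks, masks)
    model <- train_vae(fovs, cells$condition, config = vcfg)
    X <- encode(fovs, model)
  }

  # -- cluster ---------------------------------------------------------------
  cl_cfg <- config$clustering
  cl_cfg$seed <- seed_of("cluster")
  cl_hash <- hash_obj(list(bal_hash, unclass(cl_cfg), config$use_embedding))
  lab_file <- "cluster_labels.csv"
  stab_file <- "cluster_stability.json"
  if (stage_cached(root, "cluster", cl_hash)) {
    manifest$cluster <- c(jsonlite::read_json(stage_record_path(root, "cluster")),
                          skipped = TRUE)
  } else {
    part <- iterate_consensus(X, cl_cfg)
    labs <- data.frame(nucleus_id = cells$nucleus_id,
                       individual_id = cells$individual_id,
                       condition = cells$condition,
                       cluster = part$labels,
                       is_UC = part$labels == "UC")
    write.csv(labs, file.path(root, lab_file), row.names = FALSE)
    jsonlite::write_json(
      list(mean_ari = part$mean_ari, sd_ari = part$sd_ari,
           n_iterations = part$n_iterations,
           cluster_sizes = part$cluster_sizes,
           uc_fraction = part$uc_fraction),
      file.path(root, stab_file), auto_unbox = TRUE, digits = NA
    )
    manifest$cluster <- c(stage_commit(root, "cluster", cl_hash,
                                       c(lab_file, stab_file), cl_cfg$seed),
                          skipped = FALSE)
  }
  labels_df <- read.csv(file.path(root, lab_file), stringsAsFactors = FALSE)

  # -- enrich + predict ------------------------------------------------------
  pred_seed <- seed_of("predict")
  pred_hash <- hash_obj(list(cl_hash, pred_seed, config$min_cells,
                             config$n_estimators))
  metr_file <- "prediction_metrics.json"
  conf_file <- "confusion_matrix.csv"
  imp_file <- "cluster_importance.csv"
  enr_file <- "enrichment_by_individual.csv"
  if (stage_cached(root, "predict", pred_hash)) {
    manifest$predict <- c(jsonlite::read_json(stage_record_path(root, "predict")),
                          skipped = TRUE)
  } else {
    cube <- count_cube(labels_df, k_min = k_min)
    prof <- enrichment(cube, "by_individual")
    prof <- filter_low_count_patients(prof, rowSums(cube$by_individual),
                                      min_cells = config$min_cells)
    cond <- cube$individual_condition[rownames(prof)]
    lopo <- lopo_predict(prof, cond, n_estimators = config$n_estimators,
                         seed = pred_seed)
    imp <- cluster_importance(lopo)
    write.csv(as.data.frame.matrix(lopo$confusion),
              file.path(root, conf_file), row.names = TRUE)
    write.csv(imp, file.path(root, imp_file), row.names = FALSE)
    write.csv(data.frame(individual_id = rownames(prof), prof,
                         check.names = FALSE),
              file.path(root, enr_file), row.names = FALSE)
    jsonlite::write_json(
      list(balanced_accuracy = lopo$balanced_accuracy,
           per_class_recall = as.list(lopo$per_class_recall),
           auroc = if (length(lopo$auroc) == 1) lopo$auroc
                   else as.list(lopo$auroc),
           n_patients = nrow(prof),
           excluded_patients = attr(prof, "excluded")),
      file.path(root, metr_file), auto_unbox = TRUE, digits = NA
    )
    manifest$predict <- c(stage_commit(root, "predict", pred_hash,
                                       c(metr_file, conf_file, imp_file,
                                         enr_file), pred_seed),
                          skipped = FALSE)
  }

  # -- optional quantify -----------------------------------------------------
  if (isTRUE(config$stages["quantify"])) {
    q_seed <- seed_of("quantify")
    q_hash <- hash_obj(list(sim_hash, q_seed))
    q_file <- "quantification.csv"
    if (stage_cached(root, "quantify", q_hash)) {
      manifest$quantify <- c(
        jsonlite::read_json(stage_record_path(root, "quantify")),
        skipped = TRUE)
    } else {
      phen <- sample_phenotypes(sample_cohort(sim_cfg), sim_cfg)
      n_q <- min(40, nrow(phen))
      rows <- lapply(seq_len(n_q), function(i) {
        mc <- render_multichannel(phen[i, ], c("lamin", "draq7"), sim_cfg)
        mask <- attr(mc, "truth")$mask
        data.frame(
          nucleus_id = phen$nucleus_id[i],
          condition = phen$condition[i],
          lamin = nuclear_expression(mc$lamin, mask),
          draq7 = nuclear_expression(mc$draq7, mask)
        )
      })
      qdf <- do.call(rbind, rows)
      write.csv(qdf, file.path(root, q_file), row.names = FALSE)
      manifest$quantify <- c(stage_commit(root, "quantify", q_hash, q_file,
                                          q_seed), skipped = FALSE)
    }
  }

  if (isTRUE(config$stages["report"])) {
    make_report(root)
  }
  manifest$out_root <- root
  class(manifest) <- "run_manifest"
  manifest
}

#' Assemble a plain-text report of a pipeline run
#'
#' Collects the stage outputs present under the run directory into a
#' single markdown report: cluster stability and sizes, enrichment
#' matrices, the confusion matrix, and importance table. Regeneration
#' from the same outputs is byte-stable. Figures (enrichment heatmap,
#' importance bars) are written alongside when ggplot2 is installed.
#'
#' @param root pipeline output directory.
#' @return Path of the written `report.md`, invisibly.
#' @export
make_report <- function(root) {
  lines <- c("# chromacyte run report", "")
  fmt_table <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) signif(col, 5) else col)
    header <- paste(names(df), collapse = " | ")
    sep <- paste(rep("---", ncol(df)), collapse = " | ")
    body <- apply(df, 1, paste, collapse = " | ")
    c(header, sep, body, "")
  }
  stab_file <- file.path(root, "cluster_stability.json")
  if (file.exists(stab_file)) {
    st <- jsonlite::read_json(stab_file)
    lines <- c(lines, "## Consensus clustering", "",
               sprintf("- clusters: %s", paste(unlist(st$cluster_sizes), collapse = ", ")),
               sprintf("- mean ARI vs individual runs: %.4f +/- %.4f",
                       st$mean_ari, st$sd_ari),
               sprintf("- unclustered (UC) fraction: %.4f", st$uc_fraction),
               sprintf("- iterations: %d", st$n_iterations), "")
  }
  enr_file <- file.path(root, "enrichment_by_individual.csv")
  if (file.exists(enr_file)) {
    enr <- read.csv(enr_file, check.names = FALSE)
    lines <- c(lines, "## Per-individual cluster enrichment (rows sum to 1)", "",
               fmt_table(enr))
  }
  conf_file <- file.path(root, "confusion_matrix.csv")
  if (file.exists(conf_file)) {
    cf <- read.csv(conf_file, check.names = FALSE)
    names(cf)[1] <- "truth \\ predicted"
    lines <- c(lines, "## Leave-one-patient-out confusion matrix", "",
               fmt_table(cf))
  }
  metr_file <- file.path(root, "prediction_metrics.json")
  if (file.exists(metr_file)) {
    mt <- jsonlite::read_json(metr_file)
    lines <- c(lines, "## Prediction metrics", "",
               sprintf("- balanced accuracy: %.4f", mt$balanced_accuracy), "")
  }
  imp_file <- file.path(root, "cluster_importance.csv")
  if (file.exists(imp_file)) {
    imp <- read.csv(imp_file, check.names = FALSE)
    lines <- c(lines, "## Mean Gini importance per cluster", "", fmt_table(imp))
  }
  out <- file.path(root, "report.md")
  writeLines(lines, out)
  if (requireNamespace("ggplot2", quietly = TRUE) && file.exists(enr_file)) {
    enr <- read.csv(enr_file, check.names = FALSE)
    long <- data.frame(
      individual = rep(enr$individual_id, ncol(enr) - 1),
      cluster = rep(names(enr)[-1], each = nrow(enr)),
      enrichment = unlist(enr[-1], use.names = FALSE)
    )
    p <- ggplot2::ggplot(long, ggplot2::aes(
      x = .data$cluster, y = .data$individual, fill = .data$enrichment)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "cluster", y = "individual",
                    title = "Per-individual cluster enrichment")
    try(suppressMessages(ggplot2::ggsave(
      file.path(root, "enrichment_heatmap.png"), p,
      width = 6, height = 5, dpi = 120)), silent = TRUE)
  }
  invisible(out)
}
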