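#' Configuration for an end-to-end pipeline run
#'
#' Bundles the scene specification, dataset sizes, preparation protocol
#' (rebalancing cap and split fractions), the model variants to train, the
#' training schedule and the saliency-scoring settings. The global seed
#' propagates deterministically to every stage.
#'
#' @param scene A [scene_spec()]; its `image_size` must match
#'   `train$input_size` implied by `model_variants`.
#' @param n_per_grade Images generated per grade (scalar or length-5).
#' @param rebalance_cap Target rows per grade after rebalancing (default
#'   500, the standard protocol cap).
#' @param split_fractions Train/val/test fractions (default 0.8/0.1/0.1).
#' @param model_variants Character vector of [model_config()] variants to
#'   train.
#' @param base_channels Stem width for every model.
#' @param train A [train_config()].
#' @param tau Missed-pathology overlap threshold (see
#'   [missed_pathology()]).
#' @param out_dir Run directory.
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(scene = scene_spec(image_size = 64),
                       n_per_grade = 20,
                       rebalance_cap = 500,
                       split_fractions = c(0.8, 0.1, 0.1),
                       model_variants = c("plain", "residual",
                                          "multibranch", "separable"),
                       base_channels = 8,
                       train = train_config(),
                       tau = 0,
                       out_dir = "drsaliency_run",
                       seed = 1L) {
  validate_scene_spec(scene)
  stopifnot(inherits(train, "train_config"))
  assert_that(all(model_variants %in% c("plain", "residual", "multibranch",
                                        "separable")),
              "model_variants", "unknown variant")
  structure(list(scene = scene, n_per_grade = n_per_grade,
                 rebalance_cap = rebalance_cap,
                 split_fractions = split_fractions,
                 model_variants = model_variants,
                 base_channels = as.integer(base_channels),
                 train = train, tau = tau, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_json <- function(config) {
  jsonlite::toJSON(lapply(config, function(x)
    if (inherits(x, "scene_spec") || inherits(x, "train_config"))
      unclass(x) else x), auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the full saliency-evaluation pipeline
#'
#' Executes the stages in order: generate synthetic data, rebalance,
#' split, train one model per variant, compute Grad-CAM heatmaps on the
#' test split, binarize and score them against component masks, compute
#' inter-model agreement and missed-pathology rates, and evaluate the
#' grading metric suite. Every artifact is written under
#' `config$out_dir`; a machine-readable `summary.json` ties the run
#' together. Expensive stages are cached: an existing model checkpoint or
#' heatmap for the same run directory is reused, so post-training stages
#' can be rerun in isolation.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly; side effect: the run directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_open(file.path(out, "run.log"))
  on.exit(log_close())
  writeLines(config_json(config), file.path(out, "config.json"))
  log_info("run start: out_dir=%s seed=%d", out, config$seed)

  stage <- function(name, expr) {
    log_info("stage %s: start", name)
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    log_info("stage %s: done", name)
    res
  }

  ## data
  man_dir <- file.path(out, "manifests")
  dir.create(man_dir, showWarnings = FALSE)
  manifest <- stage("generate", {
    p <- file.path(man_dir, "full.csv")
    if (file.exists(p)) read_manifest(p) else {
      m <- generate_dataset(config$scene, config$n_per_grade,
                            file.path(out, "images"),
                            seed = derive_seed(config$seed, "generate"))
      write_manifest(m, p)
      m
    }
  })
  manifest <- stage("rebalance", {
    m <- rebalance(manifest, cap = config$rebalance_cap,
                   seed = derive_seed(config$seed, "rebalance"))
    write_manifest(m, file.path(man_dir, "rebalanced.csv"))
    m
  })
  manifest <- stage("split", {
    m <- split_manifest(manifest, config$split_fractions,
                        seed = derive_seed(config$seed, "split"))
    write_manifest(m, file.path(man_dir, "split.csv"))
    m
  })
  tr_man <- manifest[manifest$split == "train", ]
  va_man <- manifest[manifest$split == "val", ]
  te_man <- manifest[manifest$split == "test", ]
  ## score each distinct test image once
  te_man <- te_man[!duplicated(te_man$image_id), ]

  ## train the model zoo
  models <- list()
  for (variant in config$model_variants) {
    mdir <- file.path(out, "models", variant)
    dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
    mpath <- file.path(mdir, "model.rds")
    models[[variant]] <- stage(paste0("train_", variant), {
      if (file.exists(mpath)) {
        log_info("cached model for %s", variant)
        load_model(mpath)
      } else {
        cfg <- model_config(variant,
                            input_size = config$scene$image_size,
                            base_channels = config$base_channels,
                            seed = derive_seed(config$seed,
                                               paste0("init_", variant)))
        mod <- build_model(cfg)
        tcfg <- config$train
        tcfg$seed <- derive_seed(config$seed, paste0("train_", variant))
        mod <- train_model(mod, tr_man, va_man, tcfg)
        save_model(mod, mpath)
        utils::write.csv(mod$history, file.path(mdir, "history.csv"),
                         row.names = FALSE)
        writeLines(config_json(mod$config), file.path(mdir,
                                                      "config.json"))
        mod
      }
    })
  }

  ## Grad-CAM heatmaps on the held-out test split
  hm_root <- file.path(out, "heatmaps")
  stage("saliency", {
    for (variant in config$model_variants) {
      hdir <- file.path(hm_root, variant)
      dir.create(hdir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_len(nrow(te_man))) {
        row <- te_man[i, ]
        hpath <- file.path(hdir, paste0(row$image_id, ".png"))
        if (file.exists(hpath)) next
        af <- read_annotated(row)
        sm <- gradcam(models[[variant]], af$image,
                      image_id = row$image_id)
        save_saliency(sm, hpath)
        save_overlay(af$image, sm,
                     file.path(hdir, paste0(row$image_id,
                                            "_overlay.png")))
      }
    }
  })

  ## scoring (shared with score_only)
  score_dir <- file.path(out, "scores")
  scores <- stage("score",
                  score_heatmap_set(te_man, hm_root, score_dir,
                                    tau = config$tau))

  ## grading metrics per model on the test split
  met_dir <- file.path(out, "metrics")
  dir.create(met_dir, showWarnings = FALSE)
  metrics <- stage("metrics", {
    dat <- load_manifest_images(te_man)
    out_m <- list()
    for (variant in config$model_variants) {
      probs <- predict_grades(models[[variant]], dat$x)
      pred <- max.col(probs) - 1L
      cm <- confusion(dat$y, pred)
      rep_ <- overall_metrics(cm, scores = probs, true_grades = dat$y)
      utils::write.csv(as.data.frame(cm),
                       file.path(met_dir, paste0(variant,
                                                 "_confusion.csv")))
      jsonlite::write_json(
        list(accuracy = rep_$accuracy, auc = rep_$auc,
             kappa = rep_$kappa, matthews = rep_$matthews,
             se = rep_$se, sp = rep_$sp, ppv = rep_$ppv, npv = rep_$npv,
             per_grade = rep_$per_grade,
             aggregation = rep_$aggregation),
        file.path(met_dir, paste0(variant, "_report.json")),
        auto_unbox = TRUE, digits = NA, na = "null")
      rp <- roc_points(dat$y, probs)
      utils::write.csv(rp, file.path(met_dir,
                                     paste0(variant, "_roc.csv")),
                       row.names = FALSE)
      out_m[[variant]] <- rep_
    }
    out_m
  })

  ## figures
  stage("plots", {
    plot_dir <- file.path(out, "plots")
    dir.create(plot_dir, showWarnings = FALSE)
    plot_mean_iou(scores$mean_iou, file.path(plot_dir, "mean_iou.png"))
    plot_agreement(scores$agreement$overall,
                   file.path(plot_dir, "agreement.png"))
    plot_missed(scores$missed, file.path(plot_dir, "missed.png"))
    plot_roc_curves(met_dir, config$model_variants,
                    file.path(plot_dir, "roc.png"))
  })

  summary <- list(
    seed = config$seed,
    n_test_images = nrow(te_man),
    mean_iou = scores$mean_iou,
    agreement = scores$agreement$overall,
    missed_pathology_mean = scores$missed_mean,
    metrics = lapply(metrics, function(m)
      list(accuracy = m$accuracy, auc = m$auc, kappa = m$kappa,
           matthews = m$matthews, se = m$se, sp = m$sp)))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  log_info("run complete: summary at %s (md5 %s)",
           file.path(out, "summary.json"),
           content_hash(file.path(out, "summary.json")))
  invisible(summary)
}

#' Score a set of stored heatmaps against stored masks
#'
#' The scoring stage as a standalone entry point: reads heatmap PNGs
#' (`<heatmap_dir>/<model_id>/<image_id>.png` with JSON sidecars),
#' binarizes them with Otsu's method, and writes the IoU records, mean
#' IoU table, agreement matrices (overall and per component) and
#' missed-pathology records as CSV under `out_dir`. Running it on the
#' heatmaps a pipeline run produced reproduces that run's scoring CSVs
#' byte for byte.
#'
#' @param manifest Manifest data.frame (or path to a manifest CSV)
#'   referencing images and masks.
#' @param heatmap_dir Root heatmap directory with one subdirectory per
#'   model.
#' @param out_dir Output directory for the CSVs.
#' @param tau Missed-pathology overlap threshold.
#' @return List with `records`, `mean_iou`, `agreement` (list of
#'   matrices), `missed`, `missed_mean`, invisibly.
#' @export
score_heatmap_set <- function(manifest, heatmap_dir, out_dir, tau = 0) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- manifest[!duplicated(manifest$image_id), ]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  model_ids <- sort(list.dirs(heatmap_dir, recursive = FALSE,
                              full.names = FALSE))
  empty <- data.frame()
  if (length(model_ids) == 0) {
    warning("no heatmap subdirectories under ", heatmap_dir)
    for (f in c("iou_records.csv", "mean_iou.csv",
                "missed_pathology.csv"))
      utils::write.csv(empty, file.path(out_dir, f), row.names = FALSE)
    return(invisible(list(records = empty, mean_iou = empty,
                          agreement = list(), missed = empty,
                          missed_mean = empty)))
  }

  ## load masks once
  fundus_list <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    mask_paths <- unlist(row[manifest_mask_cols()])
    if (!all(file.exists(c(row$path, mask_paths)))) {
      warning("missing image or mask files for ", row$image_id,
              "; skipped")
      next
    }
    fundus_list[[row$image_id]] <- read_annotated(row)
  }

  detections <- list()
  for (m in model_ids) {
    detections[[m]] <- list()
    for (image_id in names(fundus_list)) {
      hp <- file.path(heatmap_dir, m, paste0(image_id, ".png"))
      if (!file.exists(hp)) {
        warning("no heatmap for model ", m, ", image ", image_id,
                "; skipped")
        next
      }
      sm <- load_saliency(hp)
      sm$model_id <- m
      sm$image_id <- image_id
      detections[[m]][[image_id]] <- binarize_otsu(sm)
    }
  }
  ## drop images not covered by every model (agreement needs a common set)
  common <- Reduce(intersect, lapply(detections, names))
  detections <- lapply(detections, function(d) d[common])
  if (length(common) == 0) {
    warning("no image is covered by every model; empty reports")
    for (f in c("iou_records.csv", "mean_iou.csv",
                "missed_pathology.csv"))
      utils::write.csv(empty, file.path(out_dir, f), row.names = FALSE)
    return(invisible(list(records = empty, mean_iou = empty,
                          agreement = list(), missed = empty,
                          missed_mean = empty)))
  }

  records <- compute_iou_records(detections, fundus_list)
  utils::write.csv(records, file.path(out_dir, "iou_records.csv"),
                   row.names = FALSE)
  mean_iou <- mean_iou_by_component(records)
  utils::write.csv(mean_iou, file.path(out_dir, "mean_iou.csv"),
                   row.names = FALSE)

  agreement <- list(overall = pairwise_agreement(detections))
  write_agreement <- function(A, path) {
    utils::write.csv(as.data.frame(unclass(A)), path)
  }
  write_agreement(agreement$overall,
                  file.path(out_dir, "agreement_overall.csv"))
  for (comp in dr_components()) {
    cmasks <- lapply(fundus_list[common],
                     function(af) af$masks[[comp]])
    A <- pairwise_agreement(detections, component_masks = cmasks)
    agreement[[comp]] <- A
    write_agreement(A, file.path(out_dir,
                                 paste0("agreement_", comp, ".csv")))
  }

  missed <- do.call(rbind, unlist(lapply(names(detections), function(m)
    lapply(common, function(im)
      missed_pathology(detections[[m]][[im]], fundus_list[[im]],
                       tau = tau))), recursive = FALSE))
  utils::write.csv(missed, file.path(out_dir, "missed_pathology.csv"),
                   row.names = FALSE)
  ## per-model average over images that contain lesions
  has_les <- missed[missed$lesions_total > 0, ]
  missed_mean <- if (nrow(has_les) > 0) {
    out <- do.call(rbind, lapply(split(has_les, has_les$model_id),
                                 function(g)
      data.frame(model_id = g$model_id[1],
                 mean_percent_missed = mean(g$percent_missed),
                 n_images = nrow(g), stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
  } else empty
  utils::write.csv(missed_mean,
                   file.path(out_dir, "missed_pathology_mean.csv"),
                   row.names = FALSE)

  log_info("scoring: %d records, md5 %s", nrow(records),
           content_hash(file.path(out_dir, "iou_records.csv")))
  invisible(list(records = records, mean_iou = mean_iou,
                 agreement = agreement, missed = missed,
                 missed_mean = missed_mean))
}

#' Score user-supplied images, masks and heatmaps without retraining
#'
#' Applies the scoring stage to an on-disk layout: a manifest CSV
#' referencing images and per-component masks, and a heatmap directory
#' with one subdirectory per model. Supports substituting real annotated
#' data for the synthetic generator.
#'
#' @param manifest_csv Path to a manifest CSV.
#' @param heatmap_dir Heatmap root directory.
#' @param out_dir Output directory.
#' @param tau Missed-pathology overlap threshold.
#' @return The scoring list from [score_heatmap_set()], invisibly.
#' @export
score_only <- function(manifest_csv, heatmap_dir, out_dir, tau = 0) {
  score_heatmap_set(manifest_csv, heatmap_dir, out_dir, tau = tau)
}

## ---- figure analogues (base graphics, PNG device) ----

plot_mean_iou <- function(mean_iou, path) {
  grDevices::png(path, width = 900, height = 500)
  on.exit(grDevices::dev.off())
  tab <- stats::xtabs(mean_iou ~ model_id + component, data = mean_iou)
  graphics::barplot(tab, beside = TRUE, legend.text = rownames(tab),
                    ylab = "mean IoU", las = 2,
                    main = "Mean IoU by ocular component")
  invisible(path)
}

plot_agreement <- function(A, path) {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  A <- unclass(A)
  n <- nrow(A)
  graphics::image(seq_len(n), seq_len(n), t(A[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  zlim = c(0, 1), main = "Inter-model agreement (IoU)")
  graphics::axis(1, seq_len(n), colnames(A), las = 2)
  graphics::axis(2, seq_len(n), rev(rownames(A)), las = 2)
  for (i in seq_len(n)) for (j in seq_len(n))
    graphics::text(j, n - i + 1, sprintf("%.2f", A[i, j]))
  invisible(path)
}

plot_missed <- function(missed, path) {
  grDevices::png(path, width = 700, height = 500)
  on.exit(grDevices::dev.off())
  has <- missed[missed$lesions_total > 0, ]
  if (nrow(has) == 0) {
    graphics::plot.new()
    graphics::title("No lesion-bearing images")
  } else {
    graphics::boxplot(percent_missed ~ model_id, data = has,
                      ylab = "% pathology missed",
                      main = "Missed pathology per model")
  }
  invisible(path)
}

plot_roc_curves <- function(met_dir, variants, path) {
  grDevices::png(path, width = 700, height = 600)
  on.exit(grDevices::dev.off())
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "false positive rate",
                 ylab = "true positive rate",
                 main = "One-vs-rest ROC (grade 0..4)")
  cols <- grDevices::rainbow(length(variants))
  for (k in seq_along(variants)) {
    f <- file.path(met_dir, paste0(variants[k], "_roc.csv"))
    if (!file.exists(f)) next
    rp <- utils::read.csv(f)
    for (g in unique(rp$grade)) {
      sub <- rp[rp$grade == g, ]
      ord <- order(sub$fpr, sub$tpr)
      graphics::lines(sub$fpr[ord], sub$tpr[ord], col = cols[k])
    }
  }
  graphics::legend("bottomright", legend = variants, col = cols, lty = 1)
  invisible(path)
}
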