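#' Run the full cone-localisation pipeline on synthetic data
#'
#' Executes, in order, any subset of the stages `synth`, `train`,
#' `predict`, `calibrate`, `locate`, `evaluate`, reading and writing all
#' artifacts under `out_dir` so that later stages can be re-run from disk
#' alone. Every stage is seeded from the manifest, so a rerun with the same
#' manifest reproduces its outputs.
#'
#' Artifacts: `manifest.json` (paths, specs, split, seeds), per-image float
#' TIFFs and `row,col` CSVs under `images/`, a checkpoint `ckpt.rds` plus
#' training history `history.csv`, probability maps under `prob/`,
#' calibrated recovery parameters `recovery_params.json`, located centroids
#' under `located/`, and `report.json` with per-image and aggregate scores.
#'
#' @param out_dir output directory (created if missing).
#' @param stages character vector of stages to run.
#' @param n_images total synthetic images (split roughly 60/20/20 into
#'   train/val/test, stratified by regime).
#' @param healthy_fraction fraction of dense-regime images.
#' @param seed master seed.
#' @param units MDLSTM units per block.
#' @param train_config optional [training_config()] override.
#' @return (invisibly) the evaluation report when `evaluate` ran, else the
#'   manifest.
#' @export
run_pipeline <- function(out_dir,
                         stages = c("synth", "train", "predict",
                                    "calibrate", "locate", "evaluate"),
                         n_images = 30, healthy_fraction = 0.5, seed = 1L,
                         units = 8L, train_config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mpath <- file.path(out_dir, "manifest.json")
  need <- function(stage, path) {
    if (!file.exists(path))
      stop("missing artifact ", path, ": run stage '", stage, "' first")
  }

  if ("synth" %in% stages) {
    ds <- generate_dataset(n_images, healthy_fraction, seed = seed)
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    split <- .stratified_split(ds$regime, seed)
    entries <- lapply(seq_along(ds$samples), function(i) {
      s <- ds$samples[[i]]
      base <- sprintf("img%03d", i)
      write_image(s$image, file.path(img_dir, paste0(base, ".tiff")))
      write_image(s$mask, file.path(img_dir, paste0(base, "_mask.png")))
      write_centroids(s$centroids,
                      file.path(img_dir, paste0(base, ".csv")))
      list(id = base, image = file.path("images", paste0(base, ".tiff")),
           mask = file.path("images", paste0(base, "_mask.png")),
           centroids = file.path("images", paste0(base, ".csv")),
           regime = ds$regime[i], split = split[i],
           disk_radius = s$disk_radius, spec = unclass(s$spec))
    })
    jsonlite::write_json(list(seed = seed, units = units,
                              n_images = n_images,
                              healthy_fraction = healthy_fraction,
                              entries = entries),
                         mpath, auto_unbox = TRUE, digits = NA)
  }

  need("synth", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  entry_set <- function(which) Filter(function(e) e$split == which,
                                      man$entries)
  load_entry <- function(e)
    list(image = read_image(file.path(out_dir, e$image)),
         mask = round(read_image(file.path(out_dir, e$mask))),
         centroids = read_centroids(file.path(out_dir, e$centroids)),
         regime = e$regime, id = e$id)

  ckpt <- file.path(out_dir, "ckpt.rds")
  if ("train" %in% stages) {
    cfg <- train_config
    if (is.null(cfg))
      cfg <- training_config(units = units, seed = man$seed,
                             crop_size = 64L, epoch_size = 4L,
                             patience = 10L, max_epochs = 60L)
    fit <- train(lapply(entry_set("train"), load_entry),
                 lapply(entry_set("val"), load_entry), cfg)
    save_checkpoint(fit$params, ckpt)
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  }

  prob_dir <- file.path(out_dir, "prob")
  if ("predict" %in% stages) {
    need("train", ckpt)
    params <- load_checkpoint(ckpt)
    dir.create(prob_dir, showWarnings = FALSE)
    for (e in c(entry_set("val"), entry_set("test"))) {
      img <- read_image(file.path(out_dir, e$image))
      pm <- cone_probability(forward(preprocess(img), params))
      write_image(pm, file.path(prob_dir, paste0(e$id, "_prob.tiff")))
    }
  }

  rp_path <- file.path(out_dir, "recovery_params.json")
  if ("calibrate" %in% stages) {
    ves <- entry_set("val")
    stopifnot(length(ves) >= 1)
    maps <- truths <- list(); regime <- character()
    for (e in ves) {
      p <- file.path(prob_dir, paste0(e$id, "_prob.tiff"))
      need("predict", p)
      maps[[length(maps) + 1]] <- read_image(p)
      truths[[length(truths) + 1]] <-
        read_centroids(file.path(out_dir, e$centroids))
      regime <- c(regime, e$regime)
    }
    sub <- function(keep) {
      if (!any(keep)) keep <- rep(TRUE, length(maps))
      calibrate(maps[keep], truths[keep])
    }
    triple <- list(both = sub(rep(TRUE, length(maps))),
                   healthy = sub(regime == "healthy"),
                   sparse = sub(regime == "disease"))
    jsonlite::write_json(lapply(triple, function(p)
      list(sigma = p$sigma, threshold = p$threshold,
           dice = attr(p, "dice"))),
      rp_path, auto_unbox = TRUE, digits = NA)
  }

  loc_dir <- file.path(out_dir, "located")
  if ("locate" %in% stages) {
    need("calibrate", rp_path)
    rp <- jsonlite::read_json(rp_path, simplifyVector = TRUE)
    mk <- function(x) recovery_params(x$sigma, x$threshold)
    dir.create(loc_dir, showWarnings = FALSE)
    for (e in entry_set("test")) {
      p <- file.path(prob_dir, paste0(e$id, "_prob.tiff"))
      need("predict", p)
      est <- adaptive_localise(read_image(p), mk(rp$both),
                               mk(rp$healthy), mk(rp$sparse))
      write_centroids(est, file.path(loc_dir, paste0(e$id, "_est.csv")))
    }
  }

  if ("evaluate" %in% stages) {
    tes <- entry_set("test")
    ests <- truths <- list(); regime <- character()
    for (e in tes) {
      p <- file.path(loc_dir, paste0(e$id, "_est.csv"))
      need("locate", p)
      ests[[length(ests) + 1]] <- read_centroids(p)
      truths[[length(truths) + 1]] <-
        read_centroids(file.path(out_dir, e$centroids))
      regime <- c(regime, e$regime)
    }
    rep_all <- evaluate_batch(ests, truths)
    report <- list(
      overall = rep_all$summary,
      healthy = if (any(regime == "healthy"))
        evaluate_batch(ests[regime == "healthy"],
                       truths[regime == "healthy"])$summary,
      disease = if (any(regime == "disease"))
        evaluate_batch(ests[regime == "disease"],
                       truths[regime == "disease"])$summary)
    report$overall$agreement <- unclass(report$overall$agreement)
    if (!is.null(report$healthy))
      report$healthy$agreement <- unclass(report$healthy$agreement)
    if (!is.null(report$disease))
      report$disease$agreement <- unclass(report$disease$agreement)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(rep_all$per_image,
                     file.path(out_dir, "per_image.csv"),
                     row.names = FALSE)
    return(invisible(report))
  }
  invisible(man)
}

# Stratified 60/20/20 split by regime, deterministic in the seed.
.stratified_split <- function(regime, seed) {
  set.seed(seed + 7L)
  split <- character(length(regime))
  for (rg in unique(regime)) {
    idx <- sample(which(regime == rg))
    n <- length(idx)
    n_tr <- max(1, round(0.6 * n)); n_va <- max(1, round(0.2 * n))
    split[idx[seq_len(n_tr)]] <- "train"
    split[idx[n_tr + seq_len(min(n_va, n - n_tr))]] <- "val"
    split[idx[split[idx] == ""]] <- "test"
  }
  split
}
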