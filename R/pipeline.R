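# Orchestration: train -> classify -> organize -> fit over directories of
# wells, with a single config object, reproducibility metadata and delegated
# group statistics (one-way ANOVA + Tukey HSD).

#' Pipeline configuration
#'
#' Returns the full parameter set with every documented default; values the
#' original workflow states (decision thresholds 0.8 / 0.10 / 0.05 / 0.4,
#' 200 superpixels, sigma = 5 Gaussians, 2.5% training fraction) are the
#' defaults.  Pass overrides as named arguments.
#'
#' @param ... named overrides of any listed parameter.
#' @return Named list of parameters (class `myotype_config`).
#' @export
myotype_config <- function(...) {
  cfg <- list(
    # texture features / training
    entropy_window = 9, std_window = 5, range_window = 5, feature_sigma = 5,
    training_fraction = 0.025,
    tree_search = list(max_depth = c(4, 6, 8, 12, 16),
                       min_leaf = c(1, 5, 20, 100)),
    cv_folds = 5,
    # striation detection
    diffusion_iter = 15, diffusion_tau = 0.15, diffusion_alpha = 0.01,
    diffusion_contrast_quantile = 0.8, diffusion_rho = 2,
    tophat_radius = 4, adaptive_window = 15, adaptive_offset = 0,
    superpixel_n = 200, superpixel_compactness = 0.1,
    object_sigma = 5, object_coherence_cutoff = 0.1,
    dot_thresh = 0.8, perp_cover = 0.10, global_cover = 0.05,
    min_foreground = 0.10,
    # nuclei
    nucleus_threshold = 0.4,
    # orientation metrics
    orient_sigma = 2, block_size = 8, coherence_cutoff = 0.2,
    stretch_angle_deg = 0, oop_convention = "normalized",
    actin_foreground_method = "otsu",  # or "model"
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  structure(modifyList(cfg, over), class = c("myotype_config", "list"))
}

#' Hash a configuration
#'
#' MD5 of the canonical JSON serialization; embedded in every output manifest
#' so runs can be matched to their exact parameters.
#'
#' @param config a [myotype_config()] list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Actin foreground mask
#'
#' Marks actin-positive pixels either by Otsu thresholding the smoothed actin
#' channel (default) or with the texture classifier applied to actin-channel
#' features (`method = "model"`).
#'
#' @param actin actin [channel_image] or matrix.
#' @param config parameter list.
#' @param model `pixel_classifier`, required for `method = "model"`.
#' @return Logical matrix.
#' @export
actin_foreground_mask <- function(actin, config = myotype_config(),
                                  model = NULL) {
  m <- if (inherits(actin, "channel_image")) actin$pixels else as.matrix(actin)
  if (config$actin_foreground_method == "model") {
    if (is.null(model)) stop("model required for actin_foreground_method = 'model'")
    tf <- compute_texture_features(m, entropy_window = config$entropy_window,
                                   std_window = config$std_window,
                                   range_window = config$range_window,
                                   sigma = config$feature_sigma)
    classify_foreground(model, tf) != 0
  } else {
    sm <- cpp_gaussian_blur(m, config$orient_sigma)
    sm > otsu_threshold(as.vector(sm))
  }
}

#' Full semantic classification of an alpha-actinin image
#'
#' Runs the two-stage classifier: texture features + decision tree for
#' Background vs Foreground, then diffusion, top-hat, dual binarization,
#' superpixels and the perpendicular-striation rule to resolve Striated
#' Myocyte vs Other.
#'
#' @param actinin alpha-actinin [channel_image] or matrix.
#' @param model a `pixel_classifier`.
#' @param config a [myotype_config()] list.
#' @return List with `class_map` (codes 0/1/2), `foreground`, `superpixels`,
#'   `adaptive_mask`, `global_mask`, `object_orientation`.
#' @export
classify_actinin <- function(actinin, model, config = myotype_config()) {
  m <- if (inherits(actinin, "channel_image")) actinin$pixels
       else as.matrix(actinin)
  tf <- compute_texture_features(m, entropy_window = config$entropy_window,
                                 std_window = config$std_window,
                                 range_window = config$range_window,
                                 sigma = config$feature_sigma)
  fgmap <- classify_foreground(model, tf)
  if (!any(fgmap != 0)) {
    codes <- class_codes()
    empty <- matrix(codes[["background"]], nrow(m), ncol(m))
    storage.mode(empty) <- "integer"
    return(list(class_map = empty, foreground = fgmap, superpixels = NULL,
                adaptive_mask = NULL, global_mask = NULL,
                object_orientation = NULL))
  }
  diff <- coherence_diffuse(m, n_iter = config$diffusion_iter,
                            tau = config$diffusion_tau,
                            alpha = config$diffusion_alpha,
                            contrast_quantile = config$diffusion_contrast_quantile,
                            rho = config$diffusion_rho)
  th <- tophat_striations(diff, selem_radius = config$tophat_radius)
  amask <- binarize(th, "adaptive_local_mean", window = config$adaptive_window,
                    offset = config$adaptive_offset)
  gmask <- binarize(th, "global_otsu", roi = fgmap)
  sp <- compute_superpixels(m, n = config$superpixel_n,
                            compactness = config$superpixel_compactness)
  oo <- object_orientation_map(m, fgmap, sigma = config$object_sigma,
                               block_size = config$block_size,
                               coherence_cutoff = config$object_coherence_cutoff)
  striae <- if (any(amask)) striation_orientations(amask) else
    list(labels = matrix(0L, nrow(m), ncol(m)),
         angle_deg = setNames(numeric(0), character(0)),
         size = integer(0), pixel_angle = matrix(NA_real_, nrow(m), ncol(m)))
  cmap <- classify_striated_superpixels(sp, fgmap, oo, striae, gmask,
                                        dot_thresh = config$dot_thresh,
                                        perp_cover = config$perp_cover,
                                        global_cover = config$global_cover,
                                        min_foreground = config$min_foreground)
  list(class_map = cmap, foreground = fgmap, superpixels = sp,
       adaptive_mask = amask, global_mask = gmask, object_orientation = oo)
}

#' Process one well directory
#'
#' Reads `actin.tif` and `alpha_actinin.tif` (plus `truth_nuclei.tif` or
#' `nuclei.tif` if present), classifies the alpha-actinin image, estimates
#' the actin orientation field and writes the per-cell-type organization
#' metrics, the class map and a manifest carrying the config hash and seed.
#' Re-running with the same config and seed is byte-identical.
#'
#' @param config a [myotype_config()].
#' @param well_dir directory with the channel TIFFs.
#' @param model trained `pixel_classifier`.
#' @param out_dir where to write artifacts (default: the well directory).
#' @param well,group identifiers recorded in the summary rows.
#' @return List with `metrics` (data frame), `class_map`, `nuclei` (data
#'   frame or NULL) and `paths`.
#' @export
run_well <- function(config, well_dir, model, out_dir = well_dir,
                     well = basename(well_dir), group = "all") {
  actin_path <- file.path(well_dir, "actin.tif")
  actinin_path <- file.path(well_dir, "alpha_actinin.tif")
  if (!file.exists(actin_path) || !file.exists(actinin_path))
    stop("well directory must contain actin.tif and alpha_actinin.tif: ",
         well_dir)
  actin <- load_channel(actin_path, "actin")
  actinin <- load_channel(actinin_path, "alpha_actinin")
  cls <- classify_actinin(actinin, model, config)
  field <- estimate_orientation_field(actin, sigma_smooth = config$orient_sigma,
                                      block_size = config$block_size,
                                      coherence_cutoff = config$coherence_cutoff)
  afg <- actin_foreground_mask(actin, config, model = model)
  metrics <- organization_metrics(field, cls$class_map, afg,
                                  stretch_angle_deg = config$stretch_angle_deg,
                                  oop_convention = config$oop_convention)
  metrics <- cbind(well = well, group = group, metrics)
  nuclei <- NULL
  nuc_lab_path <- file.path(well_dir, "truth_nuclei.tif")
  nuc_img_path <- file.path(well_dir, "nuclei.tif")
  if (file.exists(nuc_lab_path)) {
    nl <- load_class_map(nuc_lab_path, semantic = FALSE)
    nuclei <- assign_nucleus_labels(nl, cls$class_map,
                                    threshold = config$nucleus_threshold)
  } else if (file.exists(nuc_img_path)) {
    nl <- segment_nuclei(load_channel(nuc_img_path, "nuclei"))
    if (max(nl) > 0)
      nuclei <- assign_nucleus_labels(nl, cls$class_map,
                                      threshold = config$nucleus_threshold)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(class_map = file.path(out_dir, "class_map.tif"),
                metrics = file.path(out_dir, "metrics.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  save_class_map(cls$class_map, paths$class_map)
  write_well_summary(metrics, paths$metrics)
  jsonlite::write_json(list(config_hash = config_hash(config),
                            seed = config$seed,
                            package_version = as.character(
                              utils::packageVersion("myotype")),
                            well = well, group = group),
                       paths$manifest, auto_unbox = TRUE)
  if (!is.null(nuclei))
    write.csv(nuclei, file.path(out_dir, "nuclei.csv"), row.names = FALSE)
  list(metrics = metrics, class_map = cls$class_map, nuclei = nuclei,
       paths = paths)
}

#' Run a whole experiment tree
#'
#' `root_dir` holds one subdirectory per group, each holding well
#' directories.  Every well is processed with [run_well()]; the combined
#' table is written, the cardiomyocyte OOP vs actin-fraction log-normal
#' regression is fitted (when at least 5 wells with positive fraction exist),
#' and groups are compared by one-way ANOVA with Tukey's HSD on the
#' angle-to-stretch (significance at p < 0.05), delegated to the standard
#' library routines.
#'
#' @param config a [myotype_config()].
#' @param root_dir experiment root.
#' @param model trained `pixel_classifier`.
#' @param out_dir output directory (default `root_dir`).
#' @return List with `summary` (combined data frame), `fit`
#'   (`lognormal_fit` or NULL), `tukey` (per-cell-type TukeyHSD tables or
#'   NULL) and `paths`.
#' @export
run_experiment <- function(config, root_dir, model, out_dir = root_dir) {
  groups <- list.dirs(root_dir, recursive = FALSE)
  if (length(groups) == 0) stop("empty experiment: no group directories")
  rows <- list()
  for (g in groups) {
    wells <- list.dirs(g, recursive = FALSE)
    for (w in wells) {
      res <- run_well(config, w, model, well = basename(w),
                      group = basename(g))
      rows[[length(rows) + 1L]] <- res$metrics
    }
  }
  if (length(rows) == 0) stop("empty experiment: no well directories")
  summary_df <- do.call(rbind, rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_well_summary(summary_df, file.path(out_dir, "combined.csv"))
  # log-normal fit on cardiomyocyte rows
  cm <- summary_df[summary_df$cell_type == "cardiomyocyte" &
                     is.finite(summary_df$oop), ]
  fit <- NULL
  spread <- diff(range(cm$actin_fraction[cm$actin_fraction > 0]))
  if (sum(cm$actin_fraction > 0) >= 5 && isTRUE(spread >= 0.2)) {
    fit <- tryCatch(fit_lognormal(cm$actin_fraction, cm$oop),
                    error = function(e) {
                      warning("log-normal fit failed: ", conditionMessage(e))
                      NULL
                    })
  }
  if (!is.null(fit)) {
    cf <- coef(fit)
    jsonlite::write_json(list(a = cf[["a"]], b = cf[["b"]], x0 = cf[["x0"]],
                              y0 = cf[["y0"]], r_squared = fit$r_squared,
                              p_values = as.list(fit$p_values),
                              converged = fit$converged,
                              n_iterations = fit$n_iterations,
                              config_hash = config_hash(config)),
                         file.path(out_dir, "fit.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  # group comparison (delegated): one-way ANOVA + Tukey per cell type
  tukey <- NULL
  if (length(unique(summary_df$group)) < 2) {
    warning("only one group: comparison skipped")
  } else {
    tukey <- lapply(split(summary_df, summary_df$cell_type), function(d) {
      d <- d[is.finite(d$angle_to_stretch_deg), ]
      if (length(unique(d$group)) < 2 || nrow(d) < 3) return(NULL)
      if (sd(d$angle_to_stretch_deg) == 0) return(NULL)  # degenerate
      av <- aov(angle_to_stretch_deg ~ group, data = d)
      tk <- as.data.frame(TukeyHSD(av)$group)
      tk$pair <- rownames(tk)
      tk$significant <- tk$`p adj` < 0.05
      tk
    })
    tk_all <- do.call(rbind, lapply(names(tukey), function(ct) {
      t <- tukey[[ct]]
      if (is.null(t)) return(NULL)
      cbind(cell_type = ct, t)
    }))
    if (!is.null(tk_all))
      write.csv(tk_all, file.path(out_dir, "tukey.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(config = unclass(config),
                            config_hash = config_hash(config),
                            n_wells = length(rows),
                            groups = basename(groups)),
                       file.path(out_dir, "experiment_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(summary = summary_df, fit = fit, tukey = tukey,
       paths = list(combined = file.path(out_dir, "combined.csv")))
}
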