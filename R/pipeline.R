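# Pipeline stages orchestrating the full workflow over a run directory:
# phantom -> preprocess -> pca -> segment -> evaluate. Each stage is
# idempotent, reads only declared upstream artifacts, and writes a JSON
# manifest (inputs, outputs, config hash, seed, package version) so runs can
# be reproduced exactly.

#' Assemble a pipeline run configuration
#'
#' Missing fields are filled with defaults; the result drives every
#' `pipeline_*` stage. Configurations can also be read from YAML via
#' [read_run_config()].
#'
#' @param ... named fields overriding the defaults, see Details.
#' @details Fields: `seed` (integer, all randomness), `input` (path to imzML
#'   or TSV; `NULL` means "use the phantom stage's output"), `bin_width`
#'   (processed-mode imzML), `specs` (character vector of preprocessing
#'   names), `segmentation_spec` (spec whose PCA scores feed segmentation,
#'   default `"ln"`), `pca` (`n_components`, `feature_components`,
#'   `standardize`), `segment` (`n_iterations`, `smooth_factor`, `hole_fill`,
#'   `min_object_px`, `erosion_px`, `shift_px`), `opls` (`n_predictive`,
#'   `n_orthogonal`, `n_blocks`, `q2_cutoff`), `phantom` (arguments for
#'   [phantom_config()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  def <- list(
    seed = 1L, input = NULL, bin_width = NULL,
    specs = c("raw", "tic", "median", "rms", "max", "ln", "ln-median", "sqrt"),
    segmentation_spec = "ln",
    pca = list(n_components = 25L, feature_components = 1:5,
               standardize = TRUE),
    segment = list(n_iterations = 30L, smooth_factor = 0.2, hole_fill = TRUE,
                   min_object_px = 5L, erosion_px = 2L, shift_px = 2L),
    opls = list(n_predictive = NULL, n_orthogonal = 1L, n_blocks = 7L,
                q2_cutoff = 0.01),
    phantom = list())
  cfg <- utils::modifyList(def, user)
  for (sp in cfg$specs) parse_spec(sp)  # fail early on bad names
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  run_config(yaml::read_yaml(path))
}

# stable 64-bit-ish FNV-1a hash of the serialized config, hex string
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                      digits = NA, null = "null"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

write_manifest <- function(run_dir, stage, cfg, inputs, outputs) {
  man <- list(stage = stage, config_hash = config_hash(cfg), seed = cfg$seed,
              package_version = as.character(utils::packageVersion("imschemo")),
              inputs = as.list(inputs), outputs = as.list(outputs),
              config = unclass(cfg))
  path <- file.path(run_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing upstream artifact '", basename(path),
         "'; run the '", producer, "' stage first", call. = FALSE)
  path
}

write_class_map_tsv <- function(class_map, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(class_map$labels, collapse = "\t"), con, sep = "\n")
  m <- class_map$map
  m[is.na(m)] <- 0L
  writeLines(apply(m, 1L, paste, collapse = "\t"), con, sep = "\n")
  invisible(path)
}

read_class_map_tsv <- function(path) {
  labels <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  m <- as.matrix(utils::read.table(path, skip = 1L, sep = "\t"))
  dimnames(m) <- NULL
  m[m == 0L] <- NA_integer_
  storage.mode(m) <- "integer"
  structure(list(map = m, labels = labels,
                 counts = stats::setNames(tabulate(m, length(labels)), labels),
                 grid = dim(m)),
            class = "class_map")
}

#' Pipeline stage: generate the phantom dataset
#'
#' Writes `phantom.imzML`/`.ibd`, the ground-truth class map
#' (`truth_classmap.tsv`), per-region truth masks as PNG, and the phantom
#' configuration as YAML.
#'
#' @param run_dir run directory (created if absent).
#' @param cfg a [run_config()].
#' @return list of written paths, invisibly.
#' @export
pipeline_phantom <- function(run_dir, cfg = run_config()) {
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  pc <- do.call(phantom_config, cfg$phantom)
  ph <- generate_phantom(pc, seed = cfg$seed)
  paths <- c(imzml = file.path(run_dir, "phantom.imzML"),
             truth = file.path(run_dir, "truth_classmap.tsv"),
             config = file.path(run_dir, "phantom_config.yaml"))
  write_imzml(ph$cube, paths[["imzml"]], uuid_seed = cfg$seed)
  write_class_map_tsv(ph$truth, paths[["truth"]])
  yaml::write_yaml(list(grid_shape = pc$grid_shape, n_peaks = pc$n_peaks,
                        w_pcl = pc$w_pcl, sigma_gain = pc$sigma_gain,
                        sigma_mult = pc$sigma_mult, sigma_add = pc$sigma_add,
                        center = pc$center, radii = pc$radii,
                        seed = cfg$seed),
                   paths[["config"]])
  mask_paths <- vapply(names(ph$masks), function(lab) {
    p <- file.path(run_dir, sprintf("truth_mask_%s.png", lab))
    write_mask_png(ph$masks[[lab]], p)
    p
  }, character(1))
  outs <- c(paths, mask_paths)
  write_manifest(run_dir, "phantom", cfg, character(), outs)
  invisible(as.list(outs))
}

pipeline_load_raw <- function(run_dir, cfg) {
  if (!is.null(cfg$input)) {
    path <- cfg$input
    if (!file.exists(path)) stop("input file not found: ", path)
    if (grepl("\\.imzml$", tolower(path))) read_imzml(path, cfg$bin_width)
    else read_ims_tsv(path)
  } else {
    read_imzml(require_artifact(file.path(run_dir, "phantom.imzML"), "phantom"))
  }
}

#' Pipeline stage: preprocess and export
#'
#' Applies every configured preprocessing spec to the raw cube and writes one
#' pixel-spectrum TSV per spec (`processed_<spec>.tsv`).
#'
#' @inheritParams pipeline_phantom
#' @return list of written paths, invisibly.
#' @export
pipeline_preprocess <- function(run_dir, cfg = run_config()) {
  raw <- pipeline_load_raw(run_dir, cfg)
  outs <- vapply(cfg$specs, function(name) {
    cube <- suppressWarnings(apply_preprocess(raw, name))
    p <- file.path(run_dir, sprintf("processed_%s.tsv", name))
    write_ims_tsv(cube, p)
    p
  }, character(1))
  write_manifest(run_dir, "preprocess", cfg,
                 if (is.null(cfg$input)) file.path(run_dir, "phantom.imzML")
                 else cfg$input, outs)
  invisible(as.list(outs))
}

#' Pipeline stage: image PCA
#'
#' Fits mean-centered PCA on the segmentation spec's processed cube; writes
#' the score matrix (`pca_scores.tsv`: x, y, then one column per component),
#' the component table (`pca_r2x.tsv`) and score-image PNGs for the feature
#' components.
#'
#' @inheritParams pipeline_phantom
#' @return the fitted `ims_pca`, invisibly.
#' @export
pipeline_pca <- function(run_dir, cfg = run_config()) {
  src <- require_artifact(
    file.path(run_dir, sprintf("processed_%s.tsv", cfg$segmentation_spec)),
    "preprocess")
  cube <- read_ims_tsv(src)
  fit <- ims_pca(cube, cfg$pca$n_components)
  sc <- as.data.frame(fit$scores)
  names(sc) <- sprintf("t%d", seq_len(ncol(sc)))
  tab <- cbind(data.frame(x = cube$coords$x, y = cube$coords$y), sc)
  p_scores <- file.path(run_dir, "pca_scores.tsv")
  write_table_tsv(tab, p_scores)
  p_r2 <- file.path(run_dir, "pca_r2x.tsv")
  write_table_tsv(data.frame(component = seq_len(fit$n_components),
                             r2x = fit$r2x, r2x_cum = cumsum(fit$r2x)), p_r2)
  pngs <- vapply(cfg$pca$feature_components, function(a) {
    p <- file.path(run_dir, sprintf("pca_score_t%d.png", a))
    write_score_png(score_image(fit, a), p)
    p
  }, character(1))
  write_manifest(run_dir, "pca", cfg, src, c(p_scores, p_r2, pngs))
  invisible(fit)
}

#' Pipeline stage: active-contour segmentation
#'
#' Builds the feature stack from the PCA scores, obtains seeds (for phantom
#' runs: the ground truth degraded by [perturb_seeds()]), evolves one contour
#' per ROI, refines the masks, assembles the class map
#' (`segmented_classmap.tsv`, masks as PNG) and, when ground truth is
#' available, writes the per-region overlap table (`overlap.tsv`).
#'
#' @inheritParams pipeline_phantom
#' @return the segmented `class_map`, invisibly.
#' @export
pipeline_segment <- function(run_dir, cfg = run_config()) {
  p_scores <- require_artifact(file.path(run_dir, "pca_scores.tsv"), "pca")
  sc <- utils::read.table(p_scores, header = TRUE, sep = "\t")
  truth_path <- file.path(run_dir, "truth_classmap.tsv")
  truth <- if (file.exists(truth_path)) read_class_map_tsv(truth_path) else NULL
  if (is.null(truth))
    stop("no seeds available: this build derives seeds from the phantom ",
         "ground truth; run the 'phantom' stage first")
  coords <- list(x = sc$x, y = sc$y, grid = truth$grid)
  comps <- cfg$pca$feature_components
  chans <- lapply(comps, function(a) {
    v <- sc[[sprintf("t%d", a)]]
    if (isTRUE(cfg$pca$standardize)) v <- v / stats::sd(v)
    vector_to_image(v, coords)
  })
  stack <- array(unlist(chans), dim = c(truth$grid, length(chans)))
  seeds <- perturb_seeds(truth, cfg$segment$erosion_px, cfg$segment$shift_px,
                         seed = cfg$seed)
  params <- acs_params(cfg$segment$n_iterations, cfg$segment$smooth_factor,
                       cfg$segment$hole_fill)
  rois <- lapply(seeds, function(s) {
    m <- evolve_contour(stack, s, params)
    refine_mask(m, hole_fill = cfg$segment$hole_fill,
                min_object_px = cfg$segment$min_object_px)
  })
  cm <- build_class_map(rois)
  p_cm <- file.path(run_dir, "segmented_classmap.tsv")
  write_class_map_tsv(cm, p_cm)
  mask_paths <- vapply(names(rois), function(lab) {
    p <- file.path(run_dir, sprintf("roi_mask_%s.png", lab))
    write_mask_png(rois[[lab]], p)
    p
  }, character(1))
  outs <- c(p_cm, mask_paths)
  tmasks <- masks_from_class_map(truth)
  ov <- data.frame(
    roi = names(rois),
    jaccard = vapply(names(rois), function(l)
      overlap_ratio(rois[[l]], tmasks[[l]]), numeric(1)),
    dice = vapply(names(rois), function(l)
      dice_coefficient(rois[[l]], tmasks[[l]]), numeric(1)))
  p_ov <- file.path(run_dir, "overlap.tsv")
  write_table_tsv(ov, p_ov)
  outs <- c(outs, p_ov)
  write_manifest(run_dir, "segment", cfg, p_scores, outs)
  invisible(cm)
}

#' Pipeline stage: OPLS-DA evaluation of preprocessing methods
#'
#' Ranks every configured preprocessing spec by seven-block cross-validated
#' Q2Y on the segmented classes (`ranking.tsv`), and writes S-plot and
#' per-ROI diagnostics tables for the best spec.
#'
#' @inheritParams pipeline_phantom
#' @return the ranking table, invisibly.
#' @export
pipeline_evaluate <- function(run_dir, cfg = run_config()) {
  raw <- pipeline_load_raw(run_dir, cfg)
  p_cm <- require_artifact(file.path(run_dir, "segmented_classmap.tsv"),
                           "segment")
  cm <- read_class_map_tsv(p_cm)
  tab <- evaluate_preprocessing(raw, as.list(cfg$specs), cm,
                                n_predictive = cfg$opls$n_predictive,
                                n_orthogonal = cfg$opls$n_orthogonal,
                                n_blocks = cfg$opls$n_blocks)
  p_rank <- file.path(run_dir, "ranking.tsv")
  write_table_tsv(as.data.frame(tab), p_rank)
  outs <- p_rank

  best <- tab$spec[which(!is.na(tab$q2y))[1]]
  if (!is.na(best)) {
    cube_b <- suppressWarnings(apply_preprocess(raw, best))
    yb <- make_yblock(cm, raw$coords, min_class_size = 2L * cfg$opls$n_blocks)
    fit <- fit_oplsda(cube_b$intensities[yb$pixel_index, , drop = FALSE], yb,
                      cfg$opls$n_predictive, cfg$opls$n_orthogonal)
    sp <- s_plot(fit, 1)
    sp$mz <- cube_b$mz
    p_sp <- file.path(run_dir, "splot_t1.tsv")
    write_table_tsv(sp, p_sp)
    diag_rows <- do.call(rbind, lapply(cm$labels, function(lab) {
      prof_raw <- roi_noise_profile(raw, cm, lab)
      prof_b <- roi_noise_profile(cube_b, cm, lab)
      data.frame(roi = lab,
                 hetero_raw = heteroscedasticity_index(prof_raw),
                 hetero_best = heteroscedasticity_index(prof_b))
    }))
    p_diag <- file.path(run_dir, "diagnostics.tsv")
    write_table_tsv(diag_rows, p_diag)
    outs <- c(outs, p_sp, p_diag)
  }
  write_manifest(run_dir, "evaluate", cfg, p_cm, outs)
  invisible(tab)
}

#' Run the full pipeline
#'
#' phantom -> preprocess -> pca -> segment -> evaluate, in order.
#'
#' @inheritParams pipeline_phantom
#' @return the ranking table, invisibly.
#' @export
pipeline_run_all <- function(run_dir, cfg = run_config()) {
  pipeline_phantom(run_dir, cfg)
  pipeline_preprocess(run_dir, cfg)
  pipeline_pca(run_dir, cfg)
  pipeline_segment(run_dir, cfg)
  pipeline_evaluate(run_dir, cfg)
}
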