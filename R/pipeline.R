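#' Build a run configuration
#'
#' Merges a structured YAML/JSON configuration file with programmatic
#' overrides (overrides win) and fills in defaults. The configuration
#' drives the pipeline entry points [run_simulate()], [run_fit_lfpca()],
#' [run_fit_vbm()] and [run_report()]; every run writes a manifest
#' recording inputs, parameters, seed and stage order so it can be
#' reproduced.
#'
#' @param file optional path to a YAML (`.yml`/`.yaml`) or JSON
#'   configuration file.
#' @param ... named overrides of configuration entries. Recognized
#'   entries: `output_dir`, `seed`, `design` (path), `mask` (path),
#'   `fwhm_mm` (optional smoothing), `recenter_times`, `n_x`, `n_w`,
#'   `pve`, `max_comp`, `fdr_level`, `min_extent`, `connectivity`,
#'   `covariates` (path), `fit` (path of an LFPCA archive, for reports),
#'   and a `phantom` sub-list of [phantom_params()] overrides.
#' @return list of class `run_config`.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) stop_io(sprintf("config file not found: %s", file))
    cfg <- if (grepl("\\.json$", file, ignore.case = TRUE))
      jsonlite::read_json(file, simplifyVector = TRUE)
    else yaml::read_yaml(file)
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  defaults <- list(output_dir = "longvbm_out", seed = 1L,
                   recenter_times = TRUE, pve = 0.9, max_comp = 10L,
                   fdr_level = 0.05, min_extent = 21L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  class(cfg) <- "run_config"
  cfg
}

write_manifest <- function(dir, stage, cfg, stages, extra = list()) {
  manifest <- c(list(stage = stage,
                     package_version = as.character(packageVersion("longvbm")),
                     seed = cfg$seed,
                     stages = stages,
                     config = unclass(cfg),
                     timestamp = format(Sys.time(), tz = "UTC")),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

prepare_output_dir <- function(cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$output_dir))
    stop_io(sprintf("cannot create output directory %s", cfg$output_dir))
  cfg$output_dir
}

#' Simulate a phantom study to disk
#'
#' Draws a phantom stack from the configured parameters (seeded), and
#' writes the volumes, design table, truth table, the parameters and a
#' manifest into the output directory.
#'
#' @param cfg a [run_config()].
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(cfg = run_config()) {
  dir <- prepare_output_dir(cfg)
  pargs <- cfg$phantom
  pargs$seed <- cfg$seed
  if (!is.null(pargs$grid)) pargs$grid <- as.integer(pargs$grid)
  params <- do.call(phantom_params, pargs[names(pargs) %in%
                                            names(formals(phantom_params))])
  sim <- simulate_phantom(params)
  write_stack(sim$stack, dir, prefix = "phantom")
  write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  keep <- setdiff(names(unclass(params)), "geometry")
  yaml::write_yaml(unclass(params)[keep], file.path(dir, "phantom_params.yaml"))
  write_manifest(dir, "simulate", cfg, stages = "simulate_phantom",
                 extra = list(n_images = ncol(sim$stack$data)))
  invisible(dir)
}

load_configured_stack <- function(cfg) {
  if (is.null(cfg$design)) stop_validation("config needs a 'design' table path")
  if (is.null(cfg$mask)) stop_validation("config needs a 'mask' path")
  if (!file.exists(cfg$mask)) stop_io(sprintf("mask not found: %s", cfg$mask))
  stack <- load_stack(mask_path = cfg$mask, design = cfg$design,
                      recenter_times = isTRUE(cfg$recenter_times))
  stages <- "load_stack"
  if (!is.null(cfg$fwhm_mm) && cfg$fwhm_mm > 0) {
    stack <- smooth_stack(stack, cfg$fwhm_mm)
    stages <- c(stages, "smooth_stack")
  }
  list(stack = stack, stages = stages)
}

#' Fit LFPCA from a configuration
#'
#' Loads (and optionally smooths) the configured stack, runs the LFPCA
#' pipeline, and writes the fit archive, the variance table, the
#' back-projected component maps and a manifest.
#'
#' @param cfg a [run_config()] naming `design` and `mask`.
#' @return the `lfpca_fit`, invisibly.
#' @export
run_fit_lfpca <- function(cfg) {
  dir <- prepare_output_dir(cfg)
  inp <- load_configured_stack(cfg)
  fit <- lfpca(inp$stack, n_x = cfg$n_x, n_w = cfg$n_w, pve = cfg$pve,
               max_comp = cfg$max_comp)
  write_lfpca(fit, file.path(dir, "lfpca_fit.json"))
  write.csv(variance_table(fit), file.path(dir, "variance_table.csv"),
            row.names = FALSE)
  if (length(fit$lambda_x)) {
    maps <- backproject(fit, "subject")
    for (k in seq_along(fit$lambda_x)) {
      write_map_nifti(maps$phi_x0[, k], inp$stack,
                      file.path(dir, sprintf("phi_x0_%02d.nii.gz", k)))
      write_map_nifti(maps$phi_x1[, k], inp$stack,
                      file.path(dir, sprintf("phi_x1_%02d.nii.gz", k)))
    }
  }
  write_manifest(dir, "fit-lfpca", cfg,
                 stages = c(inp$stages, "demean", "reduce_stack",
                            "build_moment_design", "estimate_cov_blocks",
                            "eigendecompose", "estimate_scores"))
  invisible(fit)
}

#' Voxelwise mixed-model VBM from a configuration
#'
#' Loads (and optionally smooths) the configured stack, fits the voxelwise
#' linear mixed model, applies BY-FDR and cluster-extent thresholding, and
#' writes the statistic maps, the cluster table and a manifest.
#'
#' @param cfg a [run_config()] naming `design` and `mask`.
#' @return the `vbm_result`, invisibly.
#' @export
run_fit_vbm <- function(cfg) {
  dir <- prepare_output_dir(cfg)
  inp <- load_configured_stack(cfg)
  res <- vbm(inp$stack, q = cfg$fdr_level, min_extent = cfg$min_extent,
             connectivity = cfg$connectivity)
  for (nm in c("beta0", "beta1", "t1", "p1", "q1"))
    write_map_nifti(res[[nm]], inp$stack,
                    file.path(dir, sprintf("vbm_%s.nii.gz", nm)))
  write_map_nifti(as.numeric(res$reject), inp$stack,
                  file.path(dir, "vbm_reject.nii.gz"))
  write_cluster_table(res$clusters, file.path(dir, "clusters.tsv"))
  write_manifest(dir, "fit-vbm", cfg,
                 stages = c(inp$stages, "fit_voxelwise", "by_fdr",
                            "cluster_extent"))
  invisible(res)
}

#' Score report from a configuration
#'
#' Reads a serialized LFPCA fit and an optional covariate table, writes the
#' variance table, the association grid (CSV) and, when plotting is
#' enabled and ggplot2 is installed, scatter panels (PNG).
#'
#' @param cfg a [run_config()] naming `fit` (LFPCA archive) and optionally
#'   `covariates`.
#' @return the `score_report`, invisibly.
#' @export
run_report <- function(cfg) {
  dir <- prepare_output_dir(cfg)
  if (is.null(cfg$fit)) stop_validation("config needs a 'fit' archive path")
  if (!file.exists(cfg$fit)) stop_io(sprintf("fit archive not found: %s", cfg$fit))
  fit <- read_lfpca(cfg$fit)
  covariates <- if (!is.null(cfg$covariates)) read_table_file(cfg$covariates)
  rep <- score_report(fit, covariates, alpha = cfg$fdr_level,
                      plot = isTRUE(cfg$plot))
  write.csv(rep$variance, file.path(dir, "variance_table.csv"),
            row.names = FALSE)
  if (!is.null(rep$associations))
    write.csv(as.data.frame(rep$associations),
              file.path(dir, "associations.csv"), row.names = FALSE)
  if (!is.null(rep$panels)) {
    grDevices::png(file.path(dir, "score_panels.png"), width = 1600,
                   height = 1200, res = 150)
    print(rep$panels)
    grDevices::dev.off()
  }
  write_manifest(dir, "report", cfg, stages = c("read_lfpca", "score_report"))
  invisible(rep)
}
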