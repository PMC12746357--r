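#' Run configuration for the simulate / fit pipelines
#'
#' @param protocol preset name (see [dmi_protocol()]) or a
#'   [protocol_spec()].
#' @param metabolite_set `"in_vivo"` or `"phantom"`.
#' @param method fitting method: `"ideal"` (on complex-averaged cycles),
#'   `"ideal_modes"` or `"linear"`.
#' @param seed integer seed recorded in all outputs.
#' @param out_dir output directory.
#' @param layout scene layout for simulation.
#' @param grid simulation grid (defaults to the protocol matrix scaled
#'   down is NOT done automatically; pass a grid matching your protocol).
#' @return object of class `run_config`.
#' @export
run_config <- function(protocol = "csi_pc_bssfp",
                       metabolite_set = c("phantom", "in_vivo"),
                       method = c("ideal_modes", "linear", "ideal"),
                       seed = 1L, out_dir = tempfile("pcdmi_"),
                       layout = c("vials", "ellipsoid_brain"),
                       grid = NULL) {
  metabolite_set <- match.arg(metabolite_set)
  method <- match.arg(method)
  layout <- match.arg(layout)
  if (is.character(protocol)) protocol <- dmi_protocol(protocol)
  structure(list(protocol = protocol, metabolite_set = metabolite_set,
                 method = method, seed = as.integer(seed),
                 out_dir = out_dir, layout = layout,
                 grid = grid %||% protocol$matrix),
            class = "run_config")
}

#' Simulate an acquisition and write raw data plus ground truth
#'
#' Builds a scene, simulates the raw acquisition, and writes the raw
#' container, ground-truth concentration maps (NIfTI) and a manifest with
#' checksums. Deterministic for a fixed config and seed.
#'
#' @param config a [run_config()].
#' @return list with the output paths (`raw`, `truth`, `manifest`).
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mets <- dmi_metabolites(config$metabolite_set)
  scene <- build_scene(config$layout, metabolites = mets,
                       grid = config$grid,
                       fov_mm = config$protocol$fov_mm,
                       seed = config$seed)
  proto <- config$protocol
  if (!all(scene$grid == proto$matrix)) {
    proto$matrix <- scene$grid
  }
  raw <- simulate_acquisition(scene, proto, seed = config$seed)
  raw_path <- file.path(config$out_dir, "raw.pcdmi")
  write_dmi_raw(raw, raw_path)
  truth <- lapply(seq_along(mets), function(j) scene$conc_maps_mM[, , , j])
  names(truth) <- paste0("truth_", names(mets))
  truth_files <- write_metabolite_nifti(truth, config$out_dir,
                                        fov_mm = proto$fov_mm)
  manifest <- write_manifest(
    config$out_dir, c(raw_path, truth_files),
    config = list(protocol = proto$name, layout = config$layout,
                  metabolite_set = config$metabolite_set),
    seed = config$seed)
  list(raw = raw_path, truth = truth_files, manifest = manifest)
}

#' Reconstruct and fit a raw acquisition
#'
#' Dispatches prewhitening, SNR-unit reconstruction, adaptive coil
#' combination, B0 estimation and the chosen spectral fitter, scales the
#' metabolite maps to SNR units and writes NIfTI volumes plus a JSON
#' report (off-resonance statistics, condition numbers, SNR scales).
#'
#' @param config a [run_config()].
#' @param raw_path raw container written by [run_simulate()]; defaults to
#'   the one in `config$out_dir`.
#' @return list with `maps` (the `metabolite_maps`), `df0`, output files.
#' @export
run_fit <- function(config, raw_path = file.path(config$out_dir,
                                                 "raw.pcdmi")) {
  raw <- read_dmi_raw(raw_path)
  proto <- raw$protocol
  K <- proto$K_phase_cycles
  if (config$method %in% c("ideal_modes", "linear") && K < 2)
    stop("method '", config$method,
         "' needs phase-cycled data (K >= 2); this acquisition has K = ", K)
  series <- adaptive_combine(reconstruct(prewhiten(raw)))
  mets <- dmi_metabolites(config$metabolite_set)
  basis <- metabolite_basis(mets, proto, raw$nucleus)
  img <- series$img  # [x, y, z, t, K]
  d <- dim(img)
  if (config$method == "ideal" || K == 1) {
    avg <- array(rowMeans(matrix(img, ncol = K)), d[1:4])
    maps <- ideal_fit(avg, basis)
    df0 <- maps$df0_map_Hz
  } else {
    b0fit <- estimate_b0_from_f0(img, basis)
    df0 <- b0fit$df0_map_Hz
    if (config$method == "ideal_modes") {
      modes <- dft_phase_cycles(img)
      mf <- ideal_modes_fit(modes, basis, df0)
      maps <- combine_modes_principal(mf)
      maps$df0_map_Hz <- df0
      maps$cond <- mf$cond
    } else {
      maps <- linear_fit(img, basis, df0)
    }
  }
  maps <- scale_to_snr(maps)
  maps$spatial_dim <- d[1:3]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- write_metabolite_nifti(maps, config$out_dir,
                                  spatial_dim = d[1:3],
                                  fov_mm = proto$fov_mm)
  report <- list(
    method = config$method, seed = config$seed,
    protocol = proto$name,
    df0_stats = list(min = min(df0, na.rm = TRUE),
                     max = max(df0, na.rm = TRUE),
                     alias_limit_Hz = 500 / proto$TR_ms),
    snr_scale = as.list(stats::setNames(maps$snr_scale,
                                        maps$metabolites)),
    condition_numbers = if (!is.null(maps$cond))
      as.numeric(maps$cond[is.finite(maps$cond)]))
  report_path <- file.path(config$out_dir, "fit_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  manifest <- write_manifest(config$out_dir, c(files, report_path),
                             config = list(method = config$method),
                             seed = config$seed)
  list(maps = maps, df0 = df0, files = files, report = report_path,
       manifest = manifest)
}
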