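RAW_CONTAINER_VERSION <- 1L

#' Write a raw acquisition container
#'
#' Serializes a [dmi_raw()] object (complex data, noise samples, weights
#' and metadata) losslessly to a single versioned container file.
#'
#' @param raw a [dmi_raw()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_dmi_raw <- function(raw, path) {
  stopifnot(inherits(raw, "dmi_raw"))
  obj <- list(version = RAW_CONTAINER_VERSION, raw = raw)
  obj$checksum <- digest_raw_payload(obj$raw)
  saveRDS(obj, path)
  invisible(path)
}

digest_raw_payload <- function(raw) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(raw$data, tmp)
  unname(tools::md5sum(tmp))
}

#' Read a raw acquisition container
#'
#' @param path file written by [write_dmi_raw()].
#' @return the stored [dmi_raw()].
#' @export
read_dmi_raw <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, RAW_CONTAINER_VERSION))
    stop("raw container version mismatch: file has ", obj$version,
         ", reader expects ", RAW_CONTAINER_VERSION)
  if (!identical(obj$checksum, digest_raw_payload(obj$raw)))
    stop("raw container checksum failure: file corrupted")
  obj$raw
}

#' Write metabolite maps as NIfTI volumes
#'
#' One magnitude volume per metabolite (plus the off-resonance map if
#' present), with the voxel size taken from the field of view.
#'
#' @param maps a `metabolite_maps` object with `spatial_dim` set, or a
#'   named list of 3-D arrays.
#' @param dir output directory (created if missing).
#' @param spatial_dim 3-vector of voxel counts (needed when `maps` is a
#'   `metabolite_maps` whose `spatial_dim` is unset).
#' @param fov_mm 3-vector field of view for the voxel size.
#' @return character vector of files written.
#' @export
write_metabolite_nifti <- function(maps, dir, spatial_dim = NULL,
                                   fov_mm = c(208, 208, 208)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- list()
  if (inherits(maps, "metabolite_maps")) {
    sd3 <- spatial_dim %||% maps$spatial_dim
    if (is.null(sd3)) stop("spatial_dim needed to reshape the maps")
    for (j in seq_along(maps$metabolites))
      vols[[maps$metabolites[j]]] <- array(Mod(maps$amplitudes[, j]), sd3)
    if (!is.null(maps$df0_map_Hz))
      vols[["b0_Hz"]] <- array(as.numeric(maps$df0_map_Hz), sd3)
  } else vols <- maps
  vox <- fov_mm / dim(vols[[1]])
  files <- character(0)
  for (nm in names(vols)) {
    f <- file.path(dir, paste0(nm, ".nii"))
    img <- RNifti::asNifti(vols[[nm]], pixdim = vox)
    RNifti::writeNifti(img, f, compression = 0)
    files <- c(files, f)
  }
  files
}

write_manifest <- function(dir, files, config, seed) {
  manifest <- list(
    package = "pcdmi",
    version = as.character(utils::packageVersion("pcdmi")),
    seed = seed,
    config = config,
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}
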