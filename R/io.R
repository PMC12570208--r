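## Readers/writers: MRC/CCP4 density maps (MRC2014, mode 2, cubic voxels),
## pattern-stack containers (RDS serialization of the documented layout),
## match-result tables, and the YAML run configuration.
##
## Array conventions, fixed package-wide: images are stored
## fast-axis-major (an n_fast x n_slow matrix per image); Fourier volumes
## are centered (zero frequency at index M/2 + 1); density voxel centers
## sit at integer grid coordinates. MRC headers carry lengths in Angstrom.

#' Write / read a density map in MRC/CCP4 2014 format
#'
#' Mode-2 (float32) maps with cubic voxels and a standard 1024-byte
#' header; axis order is column-major X fastest (MAPC/MAPR/MAPS = 1,2,3).
#' Values survive a round trip to float32 storage precision; the voxel
#' size (written in Angstrom in the cell field) round-trips exactly for
#' sizes representable in float32.
#'
#' @param model a [density_model()] (or bare cubic array with
#'   \code{voxel} given).
#' @param path output file.
#' @param voxel voxel size in meters (taken from the model when omitted).
#' @export
write_mrc <- function(model, path, voxel = NULL) {
  if (inherits(model, "density_model")) {
    arr <- model$rho
    voxel <- model$voxel
  } else arr <- model
  if (is.null(voxel)) stop_param("voxel size is required")
  dm <- dim(arr)
  if (length(dm) != 3L) stop_param("map must be a 3D array")
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  cella <- dm * voxel * 1e10               # Angstrom
  wi(dm)                                   # NX NY NZ
  wi(2L)                                   # MODE 2: float32
  wi(c(0L, 0L, 0L))                        # NXSTART..
  wi(dm)                                   # MX MY MZ
  wf(cella)                                # CELLA
  wf(c(90, 90, 90))                        # CELLB
  wi(c(1L, 2L, 3L))                        # MAPC MAPR MAPS
  wf(c(min(arr), max(arr), mean(arr)))     # DMIN DMAX DMEAN
  wi(c(1L, 0L))                            # ISPG, NSYMBT
  wi(rep(0L, 25))                          # EXTRA (words 26-50)
  wf(c(0, 0, 0))                           # ORIGIN (52.. MRC2014 words 50-52)
  writeBin(charToRaw("MAP "), con)         # MAP stamp
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(arr))                       # RMS
  wi(0L)                                   # NLABL
  writeBin(raw(800), con)                  # labels
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_mrc
#' @return \code{read_mrc}: a [density_model()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  dm <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop_format(sprintf("unsupported MRC MODE %d (only float32 mode 2)", mode))
  ri(3)                                    # NXSTART
  mgrid <- ri(3)
  cella <- rf(3)
  rf(3); ri(3); rf(3)                      # CELLB, MAPC/R/S, DMIN/MAX/MEAN
  ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  vox <- cella / mgrid * 1e-10
  if (max(abs(vox - vox[1])) > 1e-6 * vox[1])
    stop_format(sprintf(
      "non-cubic voxels are unsupported (CELLA/MX = %.6g, CELLA/MY = %.6g, CELLA/MZ = %.6g Angstrom)",
      cella[1] / mgrid[1], cella[2] / mgrid[2], cella[3] / mgrid[3]))
  vals <- readBin(con, "numeric", prod(dm), size = 4, endian = "little")
  if (length(vals) != prod(dm)) stop_format("truncated MRC data section")
  density_model(array(pmax(vals, 0), dm), vox[1])
}

#' Write / read a diffraction pattern stack
#'
#' Serializes the documented stack layout - \code{images}
#' (n_fast x n_slow x D counts), optional simulation-truth
#' \code{orientations} (D x 4 quaternions) and \code{conformations} (D),
#' \code{fluence} (D), plus the detector geometry as attributes - using R
#' serialization. Round trips are bitwise; optional fields that were
#' absent read back as absent. A truncated or corrupt file is reported as
#' a format error, never silently loaded.
#'
#' @param stack a \code{pattern_stack}.
#' @param path output file.
#' @export
write_pattern_stack <- function(stack, path) {
  if (!inherits(stack, "pattern_stack")) stop_param("stack must be a pattern_stack")
  payload <- list(
    format = "spimtip-stack", version = 1L,
    images = stack$images,
    orientations = if (!is.null(stack$true_orientation))
      do.call(rbind, stack$true_orientation),
    conformations = stack$true_conformation,
    fluence = stack$fluence,
    geometry = unclass(stack$geom))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_pattern_stack
#' @return \code{read_pattern_stack}: a \code{pattern_stack}.
#' @export
read_pattern_stack <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop_format(sprintf("cannot read pattern stack '%s': %s", path, conditionMessage(e))))
  if (!is.list(payload) || !identical(payload$format, "spimtip-stack"))
    stop_format("not a spimtip pattern stack")
  if (is.null(payload$images)) stop_format("stack is missing the images dataset")
  g <- payload$geometry
  geom <- detector_geometry(g$n_fast, g$n_slow, g$pixel_size, g$distance,
                            g$wavelength, g$beam_center)
  oris <- if (!is.null(payload$orientations))
    lapply(seq_len(nrow(payload$orientations)), function(i) payload$orientations[i, ])
  structure(list(images = payload$images,
                 true_orientation = oris,
                 true_conformation = payload$conformations,
                 fluence = payload$fluence,
                 geom = geom, noise = NULL),
            class = "pattern_stack")
}

#' Export a match result as a tabular text file
#'
#' One row per image: image index, assigned quaternion (w, x, y, z),
#' conformation, distance and fitted scale.
#'
#' @param result a \code{match_result} from [match_orientations()].
#' @param refs the \code{reference_set} (or list) the result refers to.
#' @param path output TSV path.
#' @export
write_match_table <- function(result, refs, path) {
  if (inherits(refs, "reference_set")) refs <- list(refs)
  qs <- t(vapply(seq_len(nrow(result)), function(i)
    refs[[result$conformation[i]]]$orientations[[result$orientation[i]]],
    numeric(4)))
  tab <- data.frame(image = result$image,
                    qw = qs[, 1], qx = qs[, 2], qy = qs[, 3], qz = qs[, 4],
                    conformation = result$conformation,
                    distance = result$distance, scale = result$scale)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- run configuration -----------------------------------------------------

run_config_defaults <- function() {
  list(
    version = 1L,
    simulate = list(
      grid_n = 32L, voxel = 1e-9,
      phantom = list(kind = "blobs", n_blobs = 6L, blob_sigma = NULL,
                     conformation_shift = NULL, seed = 7L),
      detector = list(n_pixels = 64L, wavelength = 1e-10, pixel_size = 1e-4,
                      margin = 0.9),
      n_patterns = 2000L, photons_per_pattern = 20000,
      orientation_seed = 11L,
      noise = list(poisson = TRUE, fluence_mean = NULL, fluence_jitter_cv = 0.15,
                   miscenter_sigma = 0, background_slope = c(0, 0, 0), seed = 42L)),
    reconstruct = list(
      grid_n = 32L, n_ref = 400L, ref_scheme = "quasi_uniform",
      n_conformations = 1L, metric = "weighted_l2",
      n_generations_max = 12L, convergence_tol = 0.02, seed = 1L,
      oversample = 2L, lambdas_rel = c(1e-4, 1e-3, 1e-2),
      merge_tol = 1e-3, merge_max_iter = 25L, nufft_tol = 1e-3,
      phasing = list(hio_iterations = 100L, er_iterations = 30L, beta = 0.9,
                     n_starts = 2L, shrinkwrap_sigma = 1.5,
                     shrinkwrap_threshold = 0.12, shrinkwrap_interval = 20L)),
    output = list(dir = "spimtip-run"))
}

# Recursive default merge; unknown keys are rejected so typos cannot
# silently fall back to defaults.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop_format(sprintf("unknown config key(s)%s: %s",
                        if (nzchar(path)) paste0(" under ", path) else "",
                        paste(unknown, collapse = ", ")))
  for (k in names(user))
    defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                  paste0(path, if (nzchar(path)) "." else "", k))
  defaults
}

#' Read a run configuration (YAML) with materialized defaults
#'
#' Loads the YAML mapping, rejects unknown keys, and fills every missing
#' field (including all seeds) from the package defaults, so the returned
#' object fully determines a run.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  cfg <- merge_config(run_config_defaults(), user)
  structure(cfg, class = "run_config")
}

#' Write a fully resolved run configuration
#'
#' @param cfg a \code{run_config}.
#' @param path output YAML path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
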