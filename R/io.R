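#' Write an image set as NIfTI + JSON sidecar
#'
#' Volumes are stored power-major (power index varying fastest within each
#' offset).  The sidecar records per-volume (flip angle, offset), the
#' acquisition timing block, and provenance (seed, noise sigma).  Truth
#' maps, when present, are written as one NIfTI per parameter next to the
#' main image.
#'
#' @param images A \code{phantom_image_set}.
#' @param path Output NIfTI path (".nii" or ".nii.gz").
#' @param sidecar Output JSON sidecar path (default: path with ".json").
#' @param write_truth Write truth-map NIfTIs alongside.
#' @return Invisibly, a list of written paths.
#' @export
write_stack <- function(images, path, sidecar = NULL, write_truth = TRUE) {
  stopifnot(inherits(images, "phantom_image_set"))
  if (is.null(sidecar)) sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  d <- dim(images$signal)
  np <- d[3]; no <- d[4]
  vols <- array(images$signal, dim = c(d[1], d[2], 1, np * no))
  RNifti::writeNifti(vols, path)
  proto <- images$protocol
  grid <- expand.grid(power = seq_len(np), offset = seq_len(no))
  truth_files <- list()
  if (write_truth && !is.null(images$truth_maps)) {
    for (nm in names(images$truth_maps)) {
      tf <- sub("\\.nii(\\.gz)?$", sprintf("_truth_%s.nii\\1", nm), path)
      RNifti::writeNifti(images$truth_maps[[nm]], tf)
      truth_files[[nm]] <- basename(tf)
    }
  }
  meta <- list(
    volumes = lapply(seq_len(nrow(grid)), function(i) list(
      flip_angle_deg = proto$powers_deg[grid$power[i]],
      offset_hz = proto$offsets_hz[grid$offset[i]])),
    acquisition = list(tr_s = proto$timing$tr_s,
                       n_spokes = proto$timing$n_spokes,
                       inter_spoke_tr_s = proto$timing$inter_spoke_tr_s,
                       excitation_fa_deg = proto$timing$excitation_fa_deg,
                       pulse_duration_s = proto$pulse_duration_s,
                       pulse_shape = proto$pulse_shape,
                       lineshape = proto$lineshape),
    provenance = list(seed = images$seed, noise_sigma = images$noise_sigma,
                      generator = paste0("uteqmt ",
                        as.character(utils::packageVersion("uteqmt")))),
    truth_maps = truth_files)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(nifti = path, sidecar = sidecar, truth = truth_files))
}

#' Read an image stack written by [write_stack()] (or hand-authored)
#'
#' Volumes are reordered to the canonical \code{[y, x, power, offset]}
#' axes from the sidecar metadata, regardless of on-disk volume order.
#'
#' @param path NIfTI path.
#' @param sidecar JSON sidecar path.
#' @return A \code{phantom_image_set}.
#' @export
read_stack <- function(path, sidecar) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  vols <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sidecar)
  req <- c("volumes", "acquisition")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("sidecar missing fields: ",
                         paste(miss, collapse = ", "))
  d <- dim(vols)
  nvol <- d[length(d)]
  if (length(meta$volumes) != nvol)
    stop(sprintf("sidecar lists %d volumes but NIfTI has %d",
                 length(meta$volumes), nvol))
  fa <- vapply(meta$volumes, function(v) as.numeric(v$flip_angle_deg),
               numeric(1))
  off <- vapply(meta$volumes, function(v) as.numeric(v$offset_hz),
                numeric(1))
  if (anyDuplicated(paste(fa, off)))
    stop("duplicate (power, offset) pairs in sidecar")
  powers <- sort(unique(fa))
  offsets <- sort(unique(off))
  if (length(powers) * length(offsets) != nvol)
    stop("volumes do not form a complete (power x offset) grid")
  acq <- meta$acquisition
  proto <- mt_protocol(
    powers_deg = powers, offsets_hz = offsets,
    timing = sequence_timing(tr_s = acq$tr_s, n_spokes = acq$n_spokes,
                             inter_spoke_tr_s = acq$inter_spoke_tr_s,
                             excitation_fa_deg = acq$excitation_fa_deg),
    pulse_duration_s = acq$pulse_duration_s %||% 8e-3,
    pulse_shape = acq$pulse_shape %||% "fermi",
    lineshape = acq$lineshape %||% "gaussian")
  arr <- array(as.numeric(vols), dim = c(prod(d[-length(d)]), nvol))
  signal <- array(0, dim = c(d[1], d[2], length(powers), length(offsets)))
  for (v in seq_len(nvol)) {
    i <- match(fa[v], powers); j <- match(off[v], offsets)
    signal[, , i, j] <- array(arr[, v], dim = d[-length(d)])[, , 1]
  }
  truth <- NULL
  if (!is.null(meta$truth_maps) && length(meta$truth_maps)) {
    truth <- lapply(meta$truth_maps, function(f) {
      fp <- file.path(dirname(path), f)
      if (file.exists(fp)) {
        m <- RNifti::readNifti(fp)
        matrix(as.numeric(m), nrow = dim(m)[1])
      } else NULL
    })
    truth <- truth[!vapply(truth, is.null, logical(1))]
    if (!length(truth)) truth <- NULL
  }
  prov <- meta$provenance
  structure(list(signal = signal, truth_maps = truth, protocol = proto,
                 noise_sigma = as.numeric(prov$noise_sigma %||% 0),
                 seed = prov$seed %||% NA_integer_),
            class = "phantom_image_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a run configuration (YAML)
#'
#' Recognized top-level blocks: \code{phantom} (chip_size, mmf, k_ab,
#' t1_obs, t2a, m0a), \code{protocol} (powers_deg, offsets_hz, timing,
#' pulse, lineshape), \code{noise} (target_snr, seed), \code{fit}
#' (init_mode, powers, t1obs), \code{denoise} (method, window, sd),
#' \code{experiment}, plus \code{seed} and \code{outdir}.  Unknown keys
#' are rejected.
#'
#' @param path YAML file path.
#' @return Named list of validated blocks.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("phantom", "protocol", "noise", "fit", "denoise",
             "experiment", "seed", "outdir")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg
}

# protocol from a config block (all fields optional)
protocol_from_config <- function(cfg) {
  pr <- cfg$protocol %||% list()
  tm <- pr$timing %||% list()
  mt_protocol(
    powers_deg = unlist(pr$powers_deg) %||% c(400, 800, 1200),
    offsets_hz = unlist(pr$offsets_hz) %||% (c(2, 5, 10, 20, 50) * 1e3),
    timing = sequence_timing(
      tr_s = tm$tr_s %||% 0.086, n_spokes = tm$n_spokes %||% 13,
      inter_spoke_tr_s = tm$inter_spoke_tr_s %||% 0.005,
      excitation_fa_deg = tm$excitation_fa_deg %||% 10),
    pulse_duration_s = pr$pulse_duration_s %||% 8e-3,
    pulse_shape = pr$pulse_shape %||% "fermi",
    lineshape = pr$lineshape %||% "gaussian")
}
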