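# Shared fixtures: the midpoint bone chip, a small multi-chip phantom, and
# compact protocols for fast tests.

midpoint_params <- function(m0a = 100) {
  tissue_params(mmf = 0.50, k_ab = 25, t1_obs = 0.240, t2a = 0.8e-3,
                m0a = m0a)
}

# 2 x 2 arrangement of contrasting chips (corner cases of the bone grid)
small_phantom_spec <- function(chip_size = 8, protocol = mt_protocol()) {
  phantom_spec(
    chips = list(tissue_params(0.30, 10, 0.24, 0.8e-3),
                 tissue_params(0.60, 60, 0.24, 0.8e-3),
                 midpoint_params(),
                 tissue_params(0.40, 35, 0.24, 0.8e-3)),
    chip_size = chip_size, layout = c(2, 2), protocol = protocol)
}

single_chip_spec <- function(p = midpoint_params(), chip_size = 18,
                             protocol = mt_protocol()) {
  phantom_spec(chips = list(p), chip_size = chip_size, layout = c(1, 1),
               protocol = protocol)
}

# fit the one distinct spectrum of each chip of a noiseless set (voxels
# within a chip are identical, so one voxel per chip suffices)
fit_noiseless_chips <- function(spec, config, powers = "all") {
  images <- generate_phantom(spec)
  cs <- spec$chip_size
  lay <- spec$layout
  res <- list()
  for (ci in seq_along(spec$chips)) {
    r <- ((ci - 1) %/% lay[2]) * cs + 1
    cl <- ((ci - 1) %% lay[2]) * cs + 1
    sub <- uteqmt:::subset_protocol(images$protocol, powers)
    spec_mat <- matrix(images$signal[r, cl, sub$idx, ],
                       nrow = length(sub$idx))
    init <- if (config$init_mode == "ground_truth") {
      p <- spec$chips[[ci]]
      list(mmf = p$mmf, k_ab = p$k_ab, t1_obs = p$t1_obs, t2a = p$t2a)
    } else config$fixed_init
    res[[ci]] <- fit_voxel(spec_mat, sub$protocol, config, init)
  }
  res
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
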