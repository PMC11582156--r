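test_that("R1a derivation matches the closed form and its limits", {
  # no exchange: collapses to R1obs
  p0 <- tissue_params(0.5, 0, 0.25, 0.8e-3)
  expect_equal(derive_r1a(p0), 4.0, tolerance = 1e-12)
  # R1b == R1obs: numerator vanishes for any mmf, k_ab
  for (kab in c(5, 25, 80)) {
    p <- tissue_params(0.35, kab, 0.25, 0.8e-3, r1b = 4.0)
    expect_equal(derive_r1a(p), 4.0, tolerance = 1e-12)
  }
  # midpoint bone chip: direct evaluation of the formula
  expect_equal(derive_r1a(midpoint_params()), 7.7926, tolerance = 1e-4)
})

test_that("slow eigenvalue of the relaxation-exchange matrix equals R1obs", {
  # the derivation inverts the two-pool eigenvalue problem: check the
  # round trip on a spread of parameter sets
  cases <- expand.grid(mmf = c(0.3, 0.5, 0.6), kab = c(10, 25, 60),
                       t1 = c(0.22, 0.28))
  for (i in seq_len(nrow(cases))) {
    p <- tissue_params(cases$mmf[i], cases$kab[i], cases$t1[i], 0.8e-3)
    r1a <- derive_r1a(p)
    kba <- derive_kba(p)
    A <- matrix(c(-(r1a + p$k_ab), p$k_ab, kba, -(p$r1b + kba)), 2, 2)
    slow <- max(eigen(A, only.values = TRUE)$values)
    expect_equal(-slow, 1 / p$t1_obs, tolerance = 1e-6)
  }
  # midpoint chip: R1obs = 4.1667 s^-1
  p <- midpoint_params()
  A <- matrix(c(-(derive_r1a(p) + 25), 25, 25, -(1 + 25)), 2, 2)
  expect_equal(-max(eigen(A)$values), 4.1667, tolerance = 1e-4)
})

test_that("k_ba follows detailed balance and pool-swap symmetry", {
  expect_equal(derive_kba(midpoint_params()), 25)
  expect_equal(derive_kba(tissue_params(0.3, 10, 0.24, 8e-4)), 23.3333,
               tolerance = 1e-4)
  # k_ba * mmf == k_ab * (1 - mmf) to machine precision
  for (mmf in c(0.05, 0.37, 0.93)) {
    p <- tissue_params(mmf, 17.3, 0.24, 8e-4)
    expect_equal(derive_kba(p) * mmf, p$k_ab * (1 - mmf))
    # swapping pool labels (mmf -> 1-mmf, k_ab <- k_ba) is an involution
    q <- tissue_params(1 - mmf, derive_kba(p), 0.24, 8e-4)
    expect_equal(derive_kba(q), p$k_ab, tolerance = 1e-12)
  }
  expect_lt(derive_kba(tissue_params(0.999, 40, 0.24, 8e-4)), 0.05)
  expect_error(tissue_params(1.2, 10, 0.24, 8e-4), "mmf")
})

test_that("absorption lineshapes match their closed forms", {
  # gaussian at Delta=0: t2/sqrt(2*pi)
  expect_equal(absorption_lineshape(0, 15e-6, "gaussian"), 5.984e-6,
               tolerance = 1e-3)
  # lorentzian at Delta=0: t2/pi
  expect_equal(absorption_lineshape(0, 0.8e-3, "lorentzian"), 2.546e-4,
               tolerance = 1e-3)
  # vanish at large offset, monotone decreasing in |offset|
  offs <- c(0, 1e3, 5e3, 2e4, 1e5)
  for (kind in c("gaussian", "lorentzian")) {
    v <- absorption_lineshape(offs, 15e-6, kind)
    expect_true(all(diff(v) < 0))
    expect_lt(absorption_lineshape(1e7, 15e-6, kind),
              1e-5 * absorption_lineshape(0, 15e-6, kind))
  }
  # super-Lorentzian: divergence guard near resonance
  expect_error(absorption_lineshape(500, 15e-6, "super_lorentzian"),
               "super-Lorentzian")
  expect_gt(absorption_lineshape(500, 15e-6, "super_lorentzian",
                                 sl_extrapolate = TRUE), 0)
  expect_gt(absorption_lineshape(2e3, 15e-6, "super_lorentzian"),
            absorption_lineshape(5e4, 15e-6, "super_lorentzian"))
})

test_that("saturation rates scale with power and lineshape", {
  p <- midpoint_params()
  z <- saturation_rates(saturation_pulse(0, 5e3), p)
  expect_equal(unname(z), c(0, 0))
  w1 <- saturation_rates(saturation_pulse(400, 5e3, shape = "rect"), p)
  w2 <- saturation_rates(saturation_pulse(800, 5e3, shape = "rect"), p)
  expect_equal(unname(w2 / w1), c(4, 4), tolerance = 1e-10)
  # offset dependence follows the gaussian lineshape ratio at t2b
  wb2k <- saturation_rates(saturation_pulse(400, 2e3, shape = "rect"), p)["w_b"]
  wb50k <- saturation_rates(saturation_pulse(400, 5e4, shape = "rect"), p)["w_b"]
  gratio <- absorption_lineshape(2e3, p$t2b, "gaussian") /
    absorption_lineshape(5e4, p$t2b, "gaussian")
  expect_equal(unname(wb2k / wb50k), gratio, tolerance = 1e-10)
  expect_gt(wb2k, wb50k)
})

test_that("rms Rabi frequency honors the envelope power ratio", {
  # rect: theta / tau exactly
  expect_equal(omega1_rms(400, 8e-3, "rect"), (400 * pi / 180) / 8e-3)
  # shaped pulses need higher rms than their mean to deliver the flip
  expect_gt(omega1_rms(400, 8e-3, "gaussian"), omega1_rms(400, 8e-3, "rect"))
  expect_gt(omega1_rms(400, 8e-3, "fermi"), omega1_rms(400, 8e-3, "rect"))
})

test_that("steady-state signal has the expected structure over the grid", {
  p <- midpoint_params()
  proto <- mt_protocol()
  S <- simulate_spectrum(p, proto)
  expect_equal(dim(S), c(3, 5))
  expect_true(all(S > 0))
  # non-increasing in power at fixed offset; non-decreasing in offset
  for (j in 1:5) expect_true(all(diff(S[, j]) < 0))
  for (i in 1:3) expect_true(all(diff(S[i, ]) > 0))
  # zero power: baseline independent of offset
  S0 <- simulate_spectrum(p, mt_protocol(powers_deg = 0))
  expect_equal(max(S0) - min(S0), 0, tolerance = 1e-12 * max(S0))
  # 1x1 grid equals simulate_signal
  one <- simulate_signal(p, saturation_pulse(800, 1e4))
  expect_equal(one, simulate_spectrum(
    p, mt_protocol(powers_deg = 800, offsets_hz = 1e4))[1, 1])
})

test_that("decoupled-pool limit matches the single-pool closed form", {
  # k_ab = 0 and a vanishing bound pool: the free pool is a single pool
  # with rates (R1obs, W_a); its periodic steady state has a scalar
  # closed form assembled here independently
  p <- tissue_params(1e-4, 0, 0.25, 0.8e-3, m0a = 100)
  pulse <- saturation_pulse(800, 5e4, shape = "rect")
  tm <- sequence_timing()
  sig <- simulate_signal(p, pulse, tm)

  r1 <- 1 / p$t1_obs
  wa <- pi * omega1_rms(800, pulse$duration_s, "rect")^2 *
    absorption_lineshape(5e4, p$t2a, "lorentzian")
  fa <- tm$excitation_fa_deg * pi / 180
  dts <- tm$inter_spoke_tr_s
  t_rec <- tm$tr_s - pulse$duration_s - (tm$n_spokes - 1) * dts
  # scalar affine flows m -> e*m + (1-e)*m_p
  seg <- function(m, rate, forcing, tt) {
    mp <- forcing / rate
    e <- exp(-rate * tt)
    e * m + (1 - e) * mp
  }
  cyc <- function(m) {
    m <- seg(m, r1 + wa, r1 * p$m0a, pulse$duration_s)
    for (k in seq_len(tm$n_spokes)) {
      m <- m * cos(fa)
      if (k < tm$n_spokes) m <- seg(m, r1, r1 * p$m0a, dts)
    }
    seg(m, r1, r1 * p$m0a, t_rec)
  }
  m <- p$m0a
  for (i in 1:400) m <- cyc(m)       # converge to the periodic state
  m <- seg(m, r1 + wa, r1 * p$m0a, pulse$duration_s)
  acc <- 0
  for (k in seq_len(tm$n_spokes)) {
    acc <- acc + m
    m <- m * cos(fa)
    if (k < tm$n_spokes) m <- seg(m, r1, r1 * p$m0a, dts)
  }
  expect_equal(sig, sin(fa) * acc / tm$n_spokes, tolerance = 1e-3)
})

test_that("matrix-exponential signal agrees with fine-step integration", {
  # spot check here (the full-grid comparison runs in the acceptance
  # suite): midpoint chip, strongest saturation, closest offset
  p <- midpoint_params()
  proto <- mt_protocol(powers_deg = 1200, offsets_hz = 2e3)
  expect_equal(simulate_spectrum(p, proto)[1, 1],
               oracle_spectrum(p, proto, dt = 1e-5)[1, 1],
               tolerance = 5e-3)
})
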