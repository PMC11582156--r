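# Independent forward-model oracle: fine-step RK4 integration of the
# piecewise-constant two-pool longitudinal ODE, with the periodic steady
# state obtained by numerically propagating the affine cycle map (basis
# vectors + zero vector) rather than by matrix exponentials.
#
# Vectorized across measurement conditions: the state is an
# (n_conditions x 3) matrix per pool, columns = initial conditions
# (1,0), (0,1), (0,0) used to assemble P_cycle and c_cycle.

oracle_rk4_segment <- function(m1, m2, a11, a12, a21, a22, b1, b2, tt, dt) {
  n <- max(1L, ceiling(tt / dt))
  h <- tt / n
  for (i in seq_len(n)) {
    k1a <- a11 * m1 + a12 * m2 + b1
    k1b <- a21 * m1 + a22 * m2 + b2
    x1 <- m1 + h / 2 * k1a; x2 <- m2 + h / 2 * k1b
    k2a <- a11 * x1 + a12 * x2 + b1
    k2b <- a21 * x1 + a22 * x2 + b2
    x1 <- m1 + h / 2 * k2a; x2 <- m2 + h / 2 * k2b
    k3a <- a11 * x1 + a12 * x2 + b1
    k3b <- a21 * x1 + a22 * x2 + b2
    x1 <- m1 + h * k3a; x2 <- m2 + h * k3b
    k4a <- a11 * x1 + a12 * x2 + b1
    k4b <- a21 * x1 + a22 * x2 + b2
    m1 <- m1 + h / 6 * (k1a + 2 * k2a + 2 * k3a + k4a)
    m2 <- m2 + h / 6 * (k1b + 2 * k2b + 2 * k3b + k4b)
  }
  list(m1 = m1, m2 = m2)
}

oracle_spectrum <- function(p, protocol, dt = 1e-5,
                            first_spoke_only = FALSE) {
  r1a <- derive_r1a(p)
  kba <- derive_kba(p)
  m0b <- p$m0a * p$mmf / (1 - p$mmf)
  b1 <- r1a * p$m0a
  b2 <- p$r1b * m0b
  tm <- protocol$timing
  tau <- protocol$pulse_duration_s
  dts <- tm$inter_spoke_tr_s
  t_rec <- tm$tr_s - tau - (tm$n_spokes - 1) * dts
  fa <- tm$excitation_fa_deg * pi / 180

  w1 <- vapply(protocol$powers_deg, omega1_rms, numeric(1),
               duration_s = tau, shape = protocol$pulse_shape)
  gb <- absorption_lineshape(protocol$offsets_hz, p$t2b, protocol$lineshape)
  ga <- absorption_lineshape(protocol$offsets_hz, p$t2a, "lorentzian")
  wb <- as.numeric(pi * outer(w1^2, gb))
  wa <- as.numeric(pi * outer(w1^2, ga))
  nc <- length(wa)

  a12 <- kba; a21 <- p$k_ab
  free11 <- -(r1a + p$k_ab); free22 <- -(p$r1b + kba)
  sat11 <- free11 - wa; sat22 <- free22 - wb   # per-condition vectors

  run_cycle <- function(m1, m2, record = FALSE) {
    s <- oracle_rk4_segment(m1, m2, sat11, a12, a21, sat22, b1, b2, tau, dt)
    m1 <- s$m1; m2 <- s$m2
    acc <- 0
    for (k in seq_len(tm$n_spokes)) {
      if (record) {
        if (first_spoke_only) {
          if (k == 1) acc <- m1
        } else acc <- acc + m1
      }
      m1 <- m1 * cos(fa)
      if (k < tm$n_spokes) {
        s <- oracle_rk4_segment(m1, m2, free11, a12, a21, free22,
                                b1, b2, dts, dt)
        m1 <- s$m1; m2 <- s$m2
      }
    }
    s <- oracle_rk4_segment(m1, m2, free11, a12, a21, free22,
                            b1, b2, t_rec, dt)
    list(m1 = s$m1, m2 = s$m2,
         acc = if (first_spoke_only) acc else acc / tm$n_spokes)
  }

  # cycle map from three initial conditions (columns): e1, e2, 0
  m1_0 <- cbind(rep(1, nc), rep(0, nc), rep(0, nc))
  m2_0 <- cbind(rep(0, nc), rep(1, nc), rep(0, nc))
  r <- run_cycle(m1_0, m2_0)
  c1 <- r$m1[, 3]; c2 <- r$m2[, 3]
  p11 <- r$m1[, 1] - c1; p12 <- r$m1[, 2] - c1
  p21 <- r$m2[, 1] - c2; p22 <- r$m2[, 2] - c2
  det <- (1 - p11) * (1 - p22) - p12 * p21
  ss1 <- ((1 - p22) * c1 + p12 * c2) / det
  ss2 <- (p21 * c1 + (1 - p11) * c2) / det
  # one recorded pass from the steady state
  rec <- run_cycle(ss1, ss2, record = TRUE)
  matrix(sin(fa) * rec$acc, nrow = length(protocol$powers_deg))
}
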