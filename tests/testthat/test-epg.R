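wm <- tissue_params("WM", 1220, 45.9, 0.69, 0.70e-3)
csf <- tissue_params("CSF", 3350, 1000, 1, 3.0e-3)

test_that("equilibrium state holds Z(0) = PD and nothing else", {
  s <- equilibrium_state(wm, 200)
  expect_equal(s$Z[1], 0.69 + 0i)
  expect_equal(sum(Mod(s$Fp)) + sum(Mod(s$Fm)) + sum(Mod(s$Z[-1])), 0)
  s1 <- equilibrium_state(tissue_params("X", 1000, 100, 1), 5)
  expect_equal(s1$Z[1], 1 + 0i)
})

test_that("tissue parameter invariants are enforced", {
  expect_error(tissue_params("X", -1, 50, 0.7), "T1")
  expect_error(tissue_params("X", 1000, 2000, 0.7), "T2")
  expect_error(tissue_params("X", 1000, 50, 1.5), "PD")
  expect_error(tissue_params("X", 1000, 50, 0.7, -1), "D")
})

test_that("rf rotation reproduces known special cases", {
  s <- equilibrium_state(tissue_params("X", 1000, 100, 1), 10)
  expect_equal(rf_rotation(s, 0, 123), s)
  tipped <- rf_rotation(s, 90, 0)
  expect_equal(Mod(tipped$Fp[1]), 1, tolerance = 1e-12)
  expect_equal(Mod(tipped$Z[1]), 0, tolerance = 1e-12)
  expect_error(rf_rotation(s, 400, 0), "flip")
})

test_that("rf rotation matches a brute-force Bloch isochromat ensemble", {
  # single 30 deg pulse at 50 deg phase on equilibrium
  s <- rf_rotation(equilibrium_state(tissue_params("X", 1e3, 1e2, 1), 4),
                   30, 50)
  ens <- bloch_pulse(bloch_ensemble(360), 30, 50)
  cfg <- bloch_config(ens, 0)
  expect_equal(s$Fp[1], cfg$Fp, tolerance = 1e-12)
  expect_equal(s$Z[1], cfg$Z, tolerance = 1e-12)
})

test_that("rf rotation conserves the Bloch norm of every order triple", {
  # per isochromat |M+|^2 + |M-|^2 + 2 Mz^2 is rotation-invariant, so the
  # configuration triple carries the weighted norm |F+|^2 + |F-|^2 + 2|Z|^2
  set.seed(42)
  s <- equilibrium_state(wm, 6)
  s$Fp <- complex(real = rnorm(7), imaginary = rnorm(7))
  s$Fm[1] <- Conj(s$Fp[1])
  s$Fm[-1] <- complex(real = rnorm(6), imaginary = rnorm(6))
  s$Z <- complex(real = rnorm(7), imaginary = rnorm(7))
  for (case in 1:20) {
    flip <- runif(1, 0, 359.9)
    phase <- runif(1, 0, 360)
    r <- rf_rotation(s, flip, phase)
    n0 <- Mod(s$Fp)^2 + Mod(s$Fm)^2 + 2 * Mod(s$Z)^2
    n1 <- Mod(r$Fp)^2 + Mod(r$Fm)^2 + 2 * Mod(r$Z)^2
    expect_equal(n1, n0, tolerance = 1e-12)
  }
})

test_that("relaxation recovers to equilibrium and nulls at T1*ln(2)", {
  s <- equilibrium_state(wm, 5)
  expect_equal(relax_recover(s, 0, wm), s)
  tipped <- rf_rotation(s, 35, 10)
  rec <- relax_recover(tipped, 50 * wm$T1, wm)
  expect_equal(rec$Z[1], wm$PD + 0i, tolerance = 1e-14)
  expect_lt(max(Mod(rec$Fp), Mod(rec$Fm), Mod(rec$Z[-1])), 1e-15)
  inv <- invert_state(s, 1)
  nulled <- relax_recover(inv, wm$T1 * log(2), wm)
  expect_equal(Mod(nulled$Z[1]), 0, tolerance = 1e-12)
  expect_error(relax_recover(s, -1, wm), "dt")
})

test_that("gradient shift moves orders and composes", {
  s <- equilibrium_state(wm, 8)
  expect_equal(gradient_shift(s)$Z, s$Z)       # no transverse: Z untouched
  expect_equal(sum(Mod(gradient_shift(s)$Fp)), 0)
  # a lone F+(0) amplitude moves to F+(1); F+(0) refills from F-(1) only
  s1 <- s
  s1$Fp[1] <- 0.3 + 0.1i
  s1$Fm[1] <- Conj(s1$Fp[1])
  sh <- gradient_shift(s1)
  expect_equal(sh$Fp[2], 0.3 + 0.1i)
  expect_equal(sh$Fp[1], 0 + 0i)  # F-(1) was empty
  # two successive shifts equal the directly constructed 2-order advance
  set.seed(7)
  s2 <- s
  s2$Fp <- complex(real = rnorm(9), imaginary = rnorm(9))
  s2$Fm[1] <- Conj(s2$Fp[1])
  s2$Fm[-1] <- complex(real = rnorm(8), imaginary = rnorm(8))
  s2$Z <- complex(real = rnorm(9), imaginary = rnorm(9))
  twice <- gradient_shift(gradient_shift(s2))
  expect_equal(twice$Fp[1], Conj(s2$Fm[3]))
  expect_equal(twice$Fp[2], Conj(s2$Fm[2]))
  expect_equal(twice$Fp[3:9], s2$Fp[1:7])
  expect_equal(twice$Fm[1:7], s2$Fm[3:9])
  expect_equal(twice$Z, s2$Z)
})

test_that("diffusion attenuation follows the quadrature b-factor", {
  sp <- spoiling_schedule(dephasing_per_tr = 1, voxel_size = 0.65)
  s <- equilibrium_state(csf, 6)
  s$Fp[1:4] <- 0.1
  s$Fm[1] <- Conj(s$Fp[1])
  s$Z[3] <- 0.2
  d0 <- diffusion_attenuate(s, 9, tissue_params("X", 3350, 1000, 1, 0), sp)
  expect_equal(d0, s)                       # D = 0 is the identity
  att <- diffusion_attenuate(s, 9, csf, sp)
  expect_equal(att$Z[1], s$Z[1])            # Z(0) never attenuated
  # numeric quadrature of the linearly growing dephasing moment for k=0->1
  kg <- 2 * pi * sp$dephasing_per_tr / sp$voxel_size
  dt_s <- 9 / 1000
  b_num <- integrate(function(u) (kg * u)^2, 0, 1)$value * dt_s
  expect_equal(Mod(att$Fp[1]) / Mod(s$Fp[1]), exp(-b_num * csf$D),
               tolerance = 1e-10)
  # and for a higher transverse order, k=2 -> 3
  b2 <- integrate(function(u) (kg * (2 + u))^2, 0, 1)$value * dt_s
  expect_equal(Mod(att$Fp[3]) / Mod(s$Fp[3]), exp(-b2 * csf$D),
               tolerance = 1e-10)
  # longitudinal order k attenuates with k^2 (no transition)
  expect_equal(Mod(att$Z[3]) / Mod(s$Z[3]), exp(-kg^2 * dt_s * 4 * csf$D),
               tolerance = 1e-10)
})

test_that("inversion scales Z by -eff and crushes the transverse", {
  s <- equilibrium_state(tissue_params("X", 1000, 100, 1), 4)
  expect_equal(invert_state(s, 1)$Z[1], -1 + 0i)
  expect_equal(invert_state(s, 0.96)$Z[1], -0.96 + 0i)
  expect_equal(invert_state(s, 0)$Z[1], 0 + 0i)
  tipped <- rf_rotation(s, 45, 30)
  inv <- invert_state(tipped, 0.8)
  expect_equal(sum(Mod(inv$Fp)) + sum(Mod(inv$Fm)), 0)
  expect_error(invert_state(s, 1.2), "eff")
})

test_that("quadratic phase schedule follows inc * n(n+1)/2 mod 360", {
  expect_equal(rf_spoil_phase(0, 50), 0)
  expect_equal(rf_spoil_phase(3, 50), 300)
  expect_equal(rf_spoil_phase(2, 117), 351)
  expect_error(rf_spoil_phase(-1), "pulse_index")
})

test_that("EPG agrees with a 720-isochromat Bloch oracle on a spoiled train", {
  tis <- tissue_params("X", 1000, 80, 0.9)
  n_pulse <- 10
  dt <- 8
  state <- equilibrium_state(tis, n_pulse + 2)
  ens <- bloch_ensemble(720, tis$PD)
  for (n in seq_len(n_pulse) - 1L) {
    phi <- rf_spoil_phase(n, 50)
    state <- rf_rotation(state, 14, phi)
    ens <- bloch_pulse(ens, 14, phi)
    state <- relax_recover(state, dt, tis)
    state <- gradient_shift(state)
    ens <- bloch_relax(ens, dt, tis$T1, tis$T2)
    ens <- bloch_gradient(ens)
  }
  for (k in 0:n_pulse) {
    cfg <- bloch_config(ens, k)
    expect_equal(state$Fp[k + 1], cfg$Fp, tolerance = 1e-8)
    expect_equal(state$Z[k + 1], cfg$Z, tolerance = 1e-8)
  }
})

test_that("rotate-then-fully-relax returns to equilibrium", {
  s <- equilibrium_state(wm, 12)
  out <- relax_recover(rf_rotation(s, 70, 33), 60 * wm$T1, wm)
  expect_equal(out$Z[1], wm$PD + 0i, tolerance = 1e-13)
  expect_lt(max(Mod(out$Fp), Mod(out$Fm), Mod(out$Z[-1])), 1e-14)
})
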