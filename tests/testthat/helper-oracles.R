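# Independent oracles used across the test files.

# Brute-force Bloch simulation of n_iso uniformly dephased isochromats.
# Each isochromat carries (M+ = Mx + iMy, Mz); pulses apply the 3x3 rotation
# pointwise, the per-TR gradient advances each isochromat's phase by its
# voxel position, and configuration amplitudes are extracted by a discrete
# Fourier transform over the ensemble.  Entirely independent of the EPG
# operator bookkeeping (no shift/order logic).
bloch_ensemble <- function(n_iso = 720, PD = 1) {
  theta <- 2 * pi * (seq_len(n_iso) - 1) / n_iso
  list(theta = theta, Mp = complex(n_iso), Mz = rep(PD + 0i, n_iso), PD = PD)
}

bloch_pulse <- function(ens, flip, phase) {
  a <- flip * pi / 180
  p <- phase * pi / 180
  eip <- exp(1i * p)
  Mp <- ens$Mp
  Mm <- Conj(Mp)
  Mz <- ens$Mz
  ens$Mp <- cos(a / 2)^2 * Mp + eip^2 * sin(a / 2)^2 * Mm -
    1i * eip * sin(a) * Mz
  ens$Mz <- -0.5i * Conj(eip) * sin(a) * Mp + 0.5i * eip * sin(a) * Mm +
    cos(a) * Mz
  ens
}

bloch_relax <- function(ens, dt, T1, T2) {
  e1 <- exp(-dt / T1)
  ens$Mp <- ens$Mp * exp(-dt / T2)
  ens$Mz <- ens$Mz * e1 + ens$PD * (1 - e1)
  ens
}

bloch_gradient <- function(ens) {
  ens$Mp <- ens$Mp * exp(1i * ens$theta)
  ens
}

bloch_config <- function(ens, k) {
  list(Fp = mean(ens$Mp * exp(-1i * k * ens$theta)),
       Z = mean(ens$Mz * exp(-1i * k * ens$theta)))
}

# Small feasible protocol for exact engine cross-checks.
short_seq <- function(alpha1 = 6, alpha2 = 8, eff = 1) {
  sequence_params(TR_MP2RAGE = 800, TR_GRE = 8, TI1 = 156, TI2 = 380,
                  alpha1 = alpha1, alpha2 = alpha2, nExc = 20, kCenter = 7,
                  eff = eff)
}

# First-order (delta-method) noise propagation through the UNI ratio:
# variance of u(S1, S2) under independent complex Gaussian noise of SD
# sigma per channel on each of S1 and S2.
uni_delta_var <- function(S1, S2, sigma) {
  x1 <- Re(S1); y1 <- Im(S1); x2 <- Re(S2); y2 <- Im(S2)
  dd <- x1^2 + y1^2 + x2^2 + y2^2
  nm <- x1 * x2 + y1 * y2
  g <- c((x2 * dd - 2 * x1 * nm) / dd^2,
         (y2 * dd - 2 * y1 * nm) / dd^2,
         (x1 * dd - 2 * x2 * nm) / dd^2,
         (y1 * dd - 2 * y2 * nm) / dd^2)
  sigma^2 * sum(g^2)
}
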