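#' RF spoiling schedule
#'
#' Describes the RF phase cycling and the per-TR gradient spoiling used by the
#' EPG simulation.  The quadratic phase schedule is
#' `phase_increment * n * (n + 1) / 2 mod 360` for pulse index `n` (counted
#' from 0, reset at every inversion), and the spoiler gradient is assumed to
#' dephase `dephasing_per_tr` full cycles across one voxel per `TR_GRE`.
#'
#' @param phase_increment RF phase increment in degrees, in \[0, 360).
#' @param dephasing_per_tr Gradient-induced dephasing across one voxel per
#'   GRE repetition, in cycles (> 0).
#' @param voxel_size Voxel size in mm along the spoiling direction.
#'
#' @return An object of class `spoiling_schedule`.
#' @export
spoiling_schedule <- function(phase_increment = 50, dephasing_per_tr = 1,
                              voxel_size = 0.65) {
  if (phase_increment < 0 || phase_increment >= 360)
    stop("phase_increment must lie in [0, 360)")
  if (dephasing_per_tr <= 0) stop("dephasing_per_tr must be positive")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  structure(list(phase_increment = phase_increment,
                 dephasing_per_tr = dephasing_per_tr,
                 voxel_size = voxel_size),
            class = "spoiling_schedule")
}

#' Equilibrium EPG state
#'
#' Constructs the configuration-state representation of a fully relaxed
#' isochromat ensemble: `Z(0) = PD`, all other longitudinal and all
#' transverse configuration amplitudes zero.
#'
#' @param tissue A [tissue_params()] object (supplies the proton density).
#' @param max_order Highest configuration order to carry (>= 0).
#'
#' @return An object of class `epg_state` with complex vectors `Fp`, `Fm`,
#'   `Z` indexed by order `k = 0..max_order` and the equilibrium magnitude
#'   `PD`.
#' @export
equilibrium_state <- function(tissue, max_order) {
  stopifnot(inherits(tissue, "tissue_params"))
  if (max_order < 0) stop("max_order must be >= 0")
  n <- max_order + 1L
  z <- complex(n)
  z[1] <- tissue$PD
  structure(list(Fp = complex(n), Fm = complex(n), Z = z,
                 PD = tissue$PD, max_order = as.integer(max_order)),
            class = "epg_state")
}

#' @export
print.epg_state <- function(x, ...) {
  kact <- max(c(0L, which(Mod(x$Fp) > 0 | Mod(x$Fm) > 0 | Mod(x$Z) > 0))) - 1L
  cat(sprintf("<epg_state>  max order %d (active %d)  |F+(0)| %.4g  Z(0) %.4g%+.4gi\n",
              x$max_order, kact, Mod(x$Fp[1]), Re(x$Z[1]), Im(x$Z[1])))
  invisible(x)
}

#' Quadratic RF-spoiling phase
#'
#' Phase of the n-th excitation pulse under quadratic cycling:
#' `increment * n * (n + 1) / 2` reduced modulo 360 degrees.
#'
#' @param pulse_index Pulse counter `n` (integer >= 0; vectorized).
#' @param increment Phase increment in degrees.
#'
#' @return Phase in degrees, in \[0, 360).
#' @export
#' @examples
#' rf_spoil_phase(0:3, 50)  # 0, 50, 150, 300
rf_spoil_phase <- function(pulse_index, increment = 50) {
  if (any(pulse_index < 0)) stop("pulse_index must be >= 0")
  (increment * pulse_index * (pulse_index + 1) / 2) %% 360
}

#' EPG RF rotation operator
#'
#' Applies the standard EPG rotation matrix for a pulse of the given flip
#' angle and phase to every configuration order.  The caller is responsible
#' for any B1+ scaling of the flip angle.
#'
#' @param state An `epg_state`.
#' @param flip Flip angle in degrees, in \[0, 360).
#' @param phase Pulse phase in degrees.
#'
#' @return The rotated `epg_state`.
#' @export
rf_rotation <- function(state, flip, phase = 0) {
  stopifnot(inherits(state, "epg_state"))
  if (flip < 0 || flip >= 360) stop("flip must lie in [0, 360)")
  a <- flip * pi / 180
  p <- phase * pi / 180
  eip <- exp(1i * p)
  e2ip <- eip^2
  c2 <- cos(a / 2)^2
  s2 <- sin(a / 2)^2
  sa <- sin(a)
  fp <- state$Fp
  fm <- state$Fm
  z <- state$Z
  state$Fp <- c2 * fp + e2ip * s2 * fm - 1i * eip * sa * z
  state$Fm <- Conj(e2ip) * s2 * fp + c2 * fm + 1i * Conj(eip) * sa * z
  state$Z <- -0.5i * Conj(eip) * sa * fp + 0.5i * eip * sa * fm + cos(a) * z
  state
}

#' EPG relaxation and recovery operator
#'
#' Scales transverse configurations by `exp(-dt/T2)` and longitudinal ones by
#' `exp(-dt/T1)`; `Z(0)` additionally recovers toward the proton density.
#'
#' @param state An `epg_state`.
#' @param dt Interval in ms (>= 0).
#' @param tissue A [tissue_params()] object.
#'
#' @return The relaxed `epg_state`.
#' @export
relax_recover <- function(state, dt, tissue) {
  stopifnot(inherits(state, "epg_state"), inherits(tissue, "tissue_params"))
  if (dt < 0) stop("dt must be >= 0")
  e1 <- exp(-dt / tissue$T1)
  e2 <- exp(-dt / tissue$T2)
  state$Fp <- state$Fp * e2
  state$Fm <- state$Fm * e2
  state$Z <- state$Z * e1
  state$Z[1] <- state$Z[1] + state$PD * (1 - e1)
  state
}

#' EPG gradient shift operator
#'
#' Advances every transverse configuration by one order: `F+(k) -> F+(k+1)`,
#' `F-(k) -> F-(k-1)`, with the order-crossing `F+(0) <- Conj(F-(1))`.
#' Longitudinal configurations are unaffected; amplitudes shifted beyond
#' `max_order` are dropped.
#'
#' @param state An `epg_state`.
#'
#' @return The shifted `epg_state`.
#' @export
gradient_shift <- function(state) {
  stopifnot(inherits(state, "epg_state"))
  n <- state$max_order + 1L
  fp <- state$Fp
  fm <- state$Fm
  new_fp <- c(if (n >= 2) Conj(fm[2]) else Conj(complex(1)),
              fp[seq_len(n - 1)])
  new_fm <- c(fm[-1], complex(1))
  state$Fp <- new_fp
  state$Fm <- new_fm
  state
}

#' EPG diffusion attenuation operator
#'
#' Attenuates configuration amplitudes by the diffusion b-factor accumulated
#' over one spoiling interval during which the dephasing moment grows
#' linearly by one order.  With `kg = 2*pi*dephasing_per_tr/voxel_size`
#' (rad/mm), a transverse state at signed order k picks up
#' `b = kg^2 * dt * (k^2 + k + 1/3)` and a longitudinal state
#' `b = kg^2 * dt * k^2` (dt in seconds), each attenuated by `exp(-b * D)`.
#' For the stored `F-` amplitudes (signed order -k) the transverse factor
#' evaluates to `k^2 - k + 1/3`.
#'
#' @param state An `epg_state`.
#' @param dt Interval in ms (>= 0).
#' @param tissue A [tissue_params()] object (supplies `D` in mm^2/s).
#' @param spoiling A [spoiling_schedule()].
#'
#' @return The attenuated `epg_state`.
#' @export
diffusion_attenuate <- function(state, dt, tissue, spoiling = spoiling_schedule()) {
  stopifnot(inherits(state, "epg_state"), inherits(tissue, "tissue_params"),
            inherits(spoiling, "spoiling_schedule"))
  if (dt < 0) stop("dt must be >= 0")
  if (tissue$D == 0 || dt == 0) return(state)
  kg <- 2 * pi * spoiling$dephasing_per_tr / spoiling$voxel_size
  base <- kg^2 * (dt / 1000) * tissue$D
  k <- 0:state$max_order
  state$Fp <- state$Fp * exp(-base * (k^2 + k + 1 / 3))
  state$Fm <- state$Fm * exp(-base * (k^2 - k + 1 / 3))
  state$Z <- state$Z * exp(-base * k^2)
  state
}

#' EPG inversion operator
#'
#' Adiabatic inversion with efficiency `eff` followed by a crusher gradient:
#' all longitudinal configurations are scaled by `-eff` and all transverse
#' configurations are destroyed.
#'
#' @param state An `epg_state`.
#' @param eff Inversion efficiency in \[0, 1].
#'
#' @return The inverted `epg_state`.
#' @export
invert_state <- function(state, eff = 1) {
  stopifnot(inherits(state, "epg_state"))
  if (eff < 0 || eff > 1) stop("eff must lie in [0, 1]")
  state$Z <- -eff * state$Z
  state$Fp <- complex(state$max_order + 1L)
  state$Fm <- complex(state$max_order + 1L)
  state
}
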