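#' MP2RAGE sequence parameters
#'
#' Full description of an MP2RAGE protocol: cycle and excitation repetition
#' times, the two inversion times (measured from the inversion pulse to the
#' excitation of the k-space-center line of each GRE block), nominal flip
#' angles, block length, center-line index, spoiling schedule and inversion
#' efficiency.
#'
#' @param TR_MP2RAGE Time between successive inversion pulses, ms.
#' @param TR_GRE Time between successive excitations within a block, ms.
#' @param TI1,TI2 Inversion times of the two GRE blocks, ms
#'   (`TI1 < TI2 < TR_MP2RAGE`).
#' @param alpha1,alpha2 Nominal flip angles of the two blocks, degrees.
#' @param nExc Excitations per GRE block (>= 1).
#' @param kCenter 0-based index of the center-of-k-space excitation within
#'   each block (`0 <= kCenter < nExc`); see [center_index()].
#' @param spoiling A [spoiling_schedule()].
#' @param eff Inversion efficiency in \[0, 1].
#' @param TE Echo time, ms (recorded only; both images share it and it
#'   cancels in the ratio contrasts).
#'
#' @return An object of class `sequence_params`.
#' @export
#' @examples
#' seq <- sequence_params(TR_MP2RAGE = 4000, TR_GRE = 7.9, TI1 = 650,
#'                        TI2 = 2280, alpha1 = 4, alpha2 = 5, nExc = 192,
#'                        kCenter = 64)
sequence_params <- function(TR_MP2RAGE, TR_GRE, TI1, TI2, alpha1, alpha2,
                            nExc, kCenter, spoiling = spoiling_schedule(),
                            eff = 1, TE = NA_real_) {
  if (TR_MP2RAGE <= 0 || TR_GRE <= 0 || TI1 <= 0 || TI2 <= 0)
    stop("all times must be positive")
  if (!(TI1 < TI2 && TI2 < TR_MP2RAGE))
    stop("require TI1 < TI2 < TR_MP2RAGE")
  if (nExc < 1) stop("nExc must be >= 1")
  if (kCenter < 0 || kCenter >= nExc) stop("require 0 <= kCenter < nExc")
  if (alpha1 < 0 || alpha2 < 0) stop("flip angles must be >= 0")
  if (eff < 0 || eff > 1) stop("eff must lie in [0, 1]")
  stopifnot(inherits(spoiling, "spoiling_schedule"))
  structure(list(TR_MP2RAGE = TR_MP2RAGE, TR_GRE = TR_GRE, TI1 = TI1,
                 TI2 = TI2, alpha1 = alpha1, alpha2 = alpha2,
                 nExc = as.integer(nExc), kCenter = as.integer(kCenter),
                 spoiling = spoiling, eff = eff, TE = TE),
            class = "sequence_params")
}

#' @export
print.sequence_params <- function(x, ...) {
  cat(sprintf(
    "<MP2RAGE protocol>  TR %g ms  TR_GRE %g ms  TI %g/%g ms  alpha %g/%g deg\n",
    x$TR_MP2RAGE, x$TR_GRE, x$TI1, x$TI2, x$alpha1, x$alpha2))
  cat(sprintf("  %d excitations/block, k-center index %d, eff %g\n",
              x$nExc, x$kCenter, x$eff))
  invisible(x)
}

# flat list for the compiled engine
seq_to_cpp <- function(seq) {
  list(TR_MP2RAGE = seq$TR_MP2RAGE, TR_GRE = seq$TR_GRE, TI1 = seq$TI1,
       TI2 = seq$TI2, nExc = seq$nExc, kCenter = seq$kCenter,
       phase_increment = seq$spoiling$phase_increment,
       dephasing_per_tr = seq$spoiling$dephasing_per_tr,
       voxel_size = seq$spoiling$voxel_size, eff = seq$eff)
}

#' Inter-block timing of an MP2RAGE cycle
#'
#' Decomposes the cycle into the delays around the two GRE blocks:
#' `TA` (inversion to first excitation), `TB` (end of block 1 to first
#' excitation of block 2) and `TC` (end of block 2 to the next inversion),
#' with each block occupying `nExc * TR_GRE`.
#'
#' @param seq A [sequence_params()] object.
#'
#' @return A list with components `TA`, `TB`, `TC` (ms), class
#'   `block_timing`.  Errors with "infeasible TI/TR combination" if any
#'   component would be negative; the optimizer uses this to mask TI grids.
#' @export
block_timing <- function(seq) {
  stopifnot(inherits(seq, "sequence_params"))
  TA <- seq$TI1 - seq$kCenter * seq$TR_GRE
  TB <- seq$TI2 - seq$TI1 - seq$nExc * seq$TR_GRE
  TC <- seq$TR_MP2RAGE - seq$TI2 - (seq$nExc - seq$kCenter) * seq$TR_GRE
  if (min(TA, TB, TC) < -1e-9) stop("infeasible TI/TR combination")
  structure(list(TA = max(TA, 0), TB = max(TB, 0), TC = max(TC, 0)),
            class = "block_timing")
}

#' Center-of-k-space line index under partial Fourier
#'
#' With linear phase-encode ordering and asymmetric (partial Fourier)
#' sampling of the inner direction, the k-space center is acquired at line
#' `round(nInner * (partialFourier - 1/2))` (0-based) of the
#' `nInner * partialFourier` acquired lines.
#'
#' @param nInner Full matrix size in the inner phase-encoding direction.
#' @param partialFourier Sampled fraction, in (0.5, 1].
#'
#' @return Integer 0-based index of the center line.
#' @export
#' @examples
#' center_index(240, 6 / 8)  # 60 of 180 acquired lines
center_index <- function(nInner, partialFourier) {
  if (partialFourier <= 0.5 || partialFourier > 1)
    stop("partialFourier must lie in (0.5, 1]")
  as.integer(round(nInner * (partialFourier - 0.5)))
}

#' Steady-state MP2RAGE EPG simulation
#'
#' Propagates the EPG state through repeated MP2RAGE cycles
#' (inversion, delay TA, first GRE block at `alpha1`, delay TB, second block
#' at `alpha2`, delay TC) until the recorded center-of-k-space signals are
#' periodic, and returns the demodulated complex signals of the
#' `kCenter`-th excitation of each block.  Signals are demodulated by the
#' transmit phase of their pulse and rotated so that positive longitudinal
#' magnetization maps to a positive real signal.
#'
#' @param seq A [sequence_params()] object.
#' @param tissue A [tissue_params()] object.
#' @param b1_scale Transmit field scale applied to both flip angles (> 0).
#' @param toggles List of logical switches `useT2`, `useDiffusion`,
#'   `useRFSpoiling`.  Disabling T2 annihilates the transverse
#'   configurations every TR (ideal spoiling); disabling RF spoiling uses a
#'   constant pulse phase.
#' @param engine `"compiled"` (C++ core) or `"reference"` (pure-R operator
#'   chain; slow, used for cross-checking).
#' @param max_cycles Maximum MP2RAGE cycles before giving up.
#' @param tol Relative change in the recorded signals that counts as
#'   converged.
#'
#' @return An object of class `signal_pair`: complex `S1`, `S2`, the tissue
#'   label, `b1_scale`, cycle count and convergence flag.
#' @export
simulate_steady_state <- function(seq, tissue, b1_scale = 1,
                                  toggles = list(useT2 = TRUE,
                                                 useDiffusion = TRUE,
                                                 useRFSpoiling = TRUE),
                                  engine = c("compiled", "reference"),
                                  max_cycles = 50, tol = 1e-9) {
  stopifnot(inherits(seq, "sequence_params"), inherits(tissue, "tissue_params"))
  if (b1_scale <= 0) stop("b1_scale must be positive")
  engine <- match.arg(engine)
  tg <- list(useT2 = TRUE, useDiffusion = TRUE, useRFSpoiling = TRUE)
  tg[names(toggles)] <- toggles
  block_timing(seq)  # validates feasibility
  if (engine == "compiled") {
    res <- epg_simulate_cpp(seq_to_cpp(seq),
                            c(tissue$T1, tissue$T2, tissue$PD, tissue$D),
                            seq$alpha1, seq$alpha2, b1_scale,
                            tg$useT2, tg$useDiffusion, tg$useRFSpoiling,
                            as.integer(max_cycles), tol)
  } else {
    res <- simulate_reference(seq, tissue, b1_scale, tg, max_cycles, tol)
  }
  if (!res$converged)
    stop(sprintf(
      "MP2RAGE steady state not reached after %d cycles (tissue %s, b1 %.2f)",
      max_cycles, tissue$name, b1_scale))
  structure(list(S1 = res$S1, S2 = res$S2, tissue = tissue$name,
                 b1_scale = b1_scale, cycles = res$cycles,
                 converged = res$converged),
            class = "signal_pair")
}

#' @export
print.signal_pair <- function(x, ...) {
  cat(sprintf("<signal_pair %s @ B1 %.2f>  S1 %.5g%+.2gi  S2 %.5g%+.2gi  (%d cycles)\n",
              x$tissue, x$b1_scale, Re(x$S1), Im(x$S1), Re(x$S2), Im(x$S2),
              x$cycles))
  invisible(x)
}

# Pure-R sequence loop built from the exported EPG operators; mirrors the
# compiled engine step for step (without amplitude truncation).
simulate_reference <- function(seq, tissue, b1_scale, tg, max_cycles, tol) {
  bt <- block_timing(seq)
  state <- equilibrium_state(tissue, 2L * seq$nExc + 2L)
  a <- c(seq$alpha1, seq$alpha2) * b1_scale
  S1 <- S2 <- S1p <- S2p <- 0 + 0i
  converged <- FALSE
  cycles <- 0L
  zero_transverse <- function(s) {
    s$Fp <- complex(s$max_order + 1L)
    s$Fm <- complex(s$max_order + 1L)
    s
  }
  for (cyc in seq_len(max_cycles)) {
    cycles <- cyc
    state <- invert_state(state, seq$eff)
    state <- relax_recover(state, bt$TA, tissue)
    if (!tg$useT2) state <- zero_transverse(state)
    for (blk in 1:2) {
      for (j in seq_len(seq$nExc) - 1L) {
        n <- (blk - 1L) * seq$nExc + j
        phi <- if (tg$useRFSpoiling)
          rf_spoil_phase(n, seq$spoiling$phase_increment) else 0
        state <- rf_rotation(state, a[blk], phi)
        if (j == seq$kCenter) {
          sig <- 1i * state$Fp[1] * exp(-1i * phi * pi / 180)
          if (blk == 1) S1 <- sig else S2 <- sig
        }
        state <- relax_recover(state, seq$TR_GRE, tissue)
        if (tg$useT2) {
          if (tg$useDiffusion)
            state <- diffusion_attenuate(state, seq$TR_GRE, tissue,
                                         seq$spoiling)
          state <- gradient_shift(state)
        } else {
          state <- zero_transverse(state)
        }
      }
      state <- relax_recover(state, if (blk == 1) bt$TB else bt$TC, tissue)
      if (!tg$useT2) state <- zero_transverse(state)
    }
    if (cyc > 1 &&
        Mod(S1 - S1p) + Mod(S2 - S2p) <=
          tol * (Mod(S1) + Mod(S2) + 1e-30)) {
      converged <- TRUE
      break
    }
    S1p <- S1
    S2p <- S2
  }
  list(S1 = S1, S2 = S2, cycles = cycles, converged = converged)
}

#' Closed-form ideal-spoiling MP2RAGE signal
#'
#' Longitudinal-only recursion assuming perfect spoiling: the cycle is a
#' composition of affine maps on Mz (inversion `-eff`, exponential recovery
#' over the delays, `cos(alpha*b1) * E1` per excitation), whose periodic
#' steady state is the fixed point of the one-cycle affine map.  The signal
#' is `sin(alpha*b1) * Mz` immediately before the `kCenter`-th pulse of each
#' block.  Serves as the independent oracle for the EPG path in the
#' vanishing-T2 limit.
#'
#' @inheritParams simulate_steady_state
#' @param eff Inversion efficiency (defaults to the protocol's).
#'
#' @return An object of class `signal_pair` (real-valued signals).
#' @export
closed_form_signal <- function(seq, tissue, b1_scale = 1, eff = seq$eff) {
  stopifnot(inherits(seq, "sequence_params"), inherits(tissue, "tissue_params"))
  bt <- block_timing(seq)
  PD <- tissue$PD
  E1g <- exp(-seq$TR_GRE / tissue$T1)
  a <- c(seq$alpha1, seq$alpha2) * b1_scale * pi / 180
  # affine map m -> A*m + B composed left to right
  A <- 1; B <- 0
  comp_delay <- function(t) {
    E <- exp(-t / tissue$T1)
    A <<- A * E; B <<- B * E + PD * (1 - E)
  }
  rec <- matrix(0, 2, 2)  # rows: block; cols: (A, B) at the recorded instant
  A <- -eff; B <- 0       # inversion applied to the pre-inversion Mz
  comp_delay(bt$TA)
  for (blk in 1:2) {
    ca <- cos(a[blk])
    for (j in seq_len(seq$nExc) - 1L) {
      if (j == seq$kCenter) rec[blk, ] <- c(A, B)
      A <- A * ca
      A <- A * E1g; B <- B * ca * E1g + PD * (1 - E1g)
    }
    comp_delay(if (blk == 1) bt$TB else bt$TC)
  }
  m_star <- B / (1 - A)  # periodic steady state (|A| < 1 always)
  s <- sin(a) * (rec[, 1] * m_star + rec[, 2])
  structure(list(S1 = complex(real = s[1], imaginary = 0),
                 S2 = complex(real = s[2], imaginary = 0),
                 tissue = tissue$name, b1_scale = b1_scale,
                 cycles = NA_integer_, converged = TRUE),
            class = "signal_pair")
}

#' Scan duration of a GRAPPA-accelerated, partial-Fourier acquisition
#'
#' One outer phase-encode line is acquired per MP2RAGE cycle, so the scan
#' lasts `TR_MP2RAGE` times the number of acquired outer lines:
#' `ceil(nOuter * pfOuter / grappa) + acsLines * (1 - 1/grappa)`, rounded up.
#' The autocalibration lines are counted as the extra acquisitions beyond
#' the regular undersampled grid.
#'
#' @param seq A [sequence_params()] object.
#' @param nOuter Full matrix size in the outer phase-encoding direction.
#' @param grappa GRAPPA acceleration factor (>= 1).
#' @param acsLines Autocalibration lines (fully sampled center).
#' @param pfOuter Partial Fourier fraction in the outer direction.
#'
#' @return Scan duration in seconds.
#' @export
#' @examples
#' seq <- sequence_params(4000, 7.26, 650, 2220, 5, 4, 180, 60)
#' scan_duration(seq, nOuter = 320, grappa = 3, acsLines = 40, pfOuter = 6/8)
scan_duration <- function(seq, nOuter, grappa = 1, acsLines = 0, pfOuter = 1) {
  stopifnot(inherits(seq, "sequence_params"))
  if (grappa < 1) stop("grappa must be >= 1")
  lines <- ceiling(ceiling(nOuter * pfOuter / grappa) +
                     acsLines * (1 - 1 / grappa))
  lines * seq$TR_MP2RAGE / 1000
}
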