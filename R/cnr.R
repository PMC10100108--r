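#' Monte-Carlo noise model
#'
#' Complex Gaussian noise of SD `sigma` per channel is added to the INV1 and
#' INV2 center-of-k-space signals of every tissue, independently, `n_reps`
#' times.  When `sigma` is `NULL` it is calibrated with [calibrate_sigma()]
#' so that the INV2 image of the reference tissue has the target SNR; the
#' calibrated value is then held constant across a flip-angle grid acquired
#' at the same `TR_GRE`.
#'
#' @param sigma Noise SD in signal units, or `NULL` to calibrate.
#' @param target_snr Target SNR in the INV2 image of the reference tissue.
#' @param reference_tissue Tissue whose INV2 signal anchors the SNR.
#' @param n_reps Monte-Carlo repetitions (>= 1).
#' @param seed RNG seed used by all Monte-Carlo CNR estimators.
#'
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = NULL, target_snr = 20,
                        reference_tissue = "WM", n_reps = 100000,
                        seed = 20221109) {
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be positive")
  if (target_snr <= 0) stop("target_snr must be positive")
  if (n_reps < 1) stop("n_reps must be >= 1")
  structure(list(sigma = sigma, target_snr = target_snr,
                 reference_tissue = reference_tissue,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "noise_model")
}

#' Transmit-field scale grid
#'
#' @param scales Positive B1+ scaling factors applied to the nominal flip
#'   angles; the default covers 50\%-140\% in steps of 10\%.
#'
#' @return An object of class `b1_grid`.
#' @export
b1_grid <- function(scales = seq(0.5, 1.4, by = 0.1)) {
  if (any(scales <= 0)) stop("all B1 scales must be positive")
  structure(list(scales = as.numeric(scales)), class = "b1_grid")
}

#' Calibrate the noise SD from a reference INV2 signal
#'
#' `sigma = |S2(reference tissue, B1 = 1, reference flip angles)| /
#' target_snr`.  The same sigma is then used for every flip-angle
#' combination scanned at the same `TR_GRE`.
#'
#' @param seq A [sequence_params()] object (the reference protocol).
#' @param tissues Named list of [tissue_params()] including the reference
#'   tissue.
#' @param reference_fa Flip-angle pair used for calibration; defaults to the
#'   protocol's nominal `alpha1`/`alpha2`.
#' @param noise A [noise_model()].
#'
#' @return The calibrated `sigma` (signal units).
#' @export
calibrate_sigma <- function(seq, tissues = default_tissues(),
                            reference_fa = NULL, noise = noise_model()) {
  stopifnot(inherits(seq, "sequence_params"), inherits(noise, "noise_model"))
  if (!is.null(reference_fa)) {
    seq$alpha1 <- reference_fa[1]
    seq$alpha2 <- reference_fa[2]
  }
  tis <- tissues[[noise$reference_tissue]]
  if (is.null(tis)) stop("reference tissue not found in tissue set")
  s <- simulate_steady_state(seq, tis, b1_scale = 1)
  ref <- Mod(s$S2)
  if (ref <= 0) stop("reference INV2 signal is zero; cannot calibrate sigma")
  ref / noise$target_snr
}

#' Monte-Carlo CNR between two tissues for one combiner
#'
#' Draws `n_reps` independent complex Gaussian perturbations of the INV1 and
#' INV2 signals of both tissues, applies the combiner (UNI on the noisy
#' complex pairs, FLAWS minimum on the noisy magnitudes), and returns the
#' signed contrast-to-noise ratio `mean(cA - cB) / SD(cA - cB)`.
#'
#' @param pairA,pairB `signal_pair` objects (see [simulate_steady_state()]).
#' @param combiner `"uni"` or `"flaws_min"`.
#' @param noise A [noise_model()] with `sigma` set (see
#'   [calibrate_sigma()]).
#'
#' @return Signed CNR (dimensionless).
#' @export
mc_contrast_cnr <- function(pairA, pairB, combiner = c("uni", "flaws_min"),
                            noise) {
  combiner <- match.arg(combiner)
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(noise$sigma)) stop("noise$sigma must be calibrated first")
  n <- noise$n_reps
  set.seed(noise$seed)
  noisy <- function(pair) {
    s1 <- pair$S1 + noise$sigma * complex(real = rnorm(n), imaginary = rnorm(n))
    s2 <- pair$S2 + noise$sigma * complex(real = rnorm(n), imaginary = rnorm(n))
    if (combiner == "uni") uni(s1, s2) else flaws_min(Mod(s1), Mod(s2))
  }
  d <- noisy(pairA) - noisy(pairB)
  mean(d) / sd(d)
}

#' B1-averaged Monte-Carlo CNR channels at one flip-angle pair
#'
#' Simulates the WM/GM/CSF signal pairs at every B1 scale, runs the
#' Monte-Carlo noise propagation, and averages the signed per-B1 CNRs of the
#' four contrast channels (UNI WM-GM, UNI GM-CSF, FLAWS_min GM-WM,
#' FLAWS_min GM-CSF) over the grid.
#'
#' @param seq A [sequence_params()] object.
#' @param tissues Named list with `WM`, `GM`, `CSF` [tissue_params()].
#' @param fa_pair Optional `c(alpha1, alpha2)` overriding the protocol's
#'   nominal flip angles.
#' @param b1 A [b1_grid()].
#' @param noise A [noise_model()]; if `sigma` is `NULL` it is calibrated
#'   from this protocol's nominal flip angles.
#' @param toggles Passed to the EPG engine (see [simulate_steady_state()]).
#'
#' @return A list with `channels` (named length-4 vector of B1-averaged
#'   CNRs), `per_b1` (4 x nB1 matrix), `uni_total`, `flaws_total`,
#'   `cnr_total` (per sqrt(ms)), and the `sigma` used.
#' @export
b1_averaged_cnr <- function(seq, tissues = default_tissues(), fa_pair = NULL,
                            b1 = b1_grid(), noise = noise_model(),
                            toggles = list()) {
  stopifnot(inherits(seq, "sequence_params"), inherits(b1, "b1_grid"))
  if (!is.null(fa_pair)) {
    seq$alpha1 <- fa_pair[1]
    seq$alpha2 <- fa_pair[2]
  }
  if (is.null(noise$sigma)) noise$sigma <- calibrate_sigma(seq, tissues,
                                                           noise = noise)
  tg <- list(useT2 = TRUE, useDiffusion = TRUE, useRFSpoiling = TRUE)
  tg[names(toggles)] <- toggles
  S <- epg_grid_cpp(seq_to_cpp(seq), tissue_matrix(tissues), seq$alpha1,
                    seq$alpha2, b1$scales, tg$useT2, tg$useDiffusion,
                    tg$useRFSpoiling, 50L, 1e-9)
  dim(S) <- c(2L, 3L, length(b1$scales))
  set.seed(noise$seed)
  per_b1 <- mc_cnr_cell_cpp(S, noise$sigma, noise$n_reps)
  rownames(per_b1) <- c("uni_wm_gm", "uni_gm_csf", "flaws_gm_wm",
                        "flaws_gm_csf")
  colnames(per_b1) <- format(b1$scales)
  channels <- rowMeans(per_b1)
  list(channels = channels,
       per_b1 = per_b1,
       uni_total = channels[["uni_wm_gm"]] + channels[["uni_gm_csf"]],
       flaws_total = channels[["flaws_gm_wm"]] + channels[["flaws_gm_csf"]],
       cnr_total = cnr_total(channels, seq$TR_MP2RAGE),
       sigma = noise$sigma)
}

#' Joint UNI + FLAWS objective per unit time
#'
#' `(FLAWS_min GM-CSF + FLAWS_min GM-WM + UNI WM-GM + UNI GM-CSF) /
#' sqrt(TR_MP2RAGE)` with the TR in ms, i.e. a CNR per sqrt(ms).
#'
#' @param channels Named numeric vector containing `uni_wm_gm`,
#'   `uni_gm_csf`, `flaws_gm_wm`, `flaws_gm_csf`.
#' @param TR_MP2RAGE Cycle TR in ms.
#'
#' @return The objective value (per sqrt(ms)).
#' @export
cnr_total <- function(channels, TR_MP2RAGE) {
  need <- c("uni_wm_gm", "uni_gm_csf", "flaws_gm_wm", "flaws_gm_csf")
  if (!all(need %in% names(channels)))
    stop("channels must contain ", paste(need, collapse = ", "))
  sum(channels[need]) / sqrt(TR_MP2RAGE)
}

# Large-n approximation to the Monte-Carlo standard error of a CNR estimate
# (delta method on mean/SD of i.i.d. differences).
cnr_mc_se <- function(cnr, n_reps) sqrt((1 + cnr^2 / 2) / n_reps)
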