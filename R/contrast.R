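#' Image combination configuration
#'
#' @param beta Background-regularization constant in intensity units
#'   (>= 0); the background-suppressed FLAWS ratios divide by
#'   `INV1 + INV2 + 2*beta` so that empty voxels map to -0.5 instead of
#'   amplified noise.
#' @param intensity_scale Common range maximum to which INV1/INV2 are
#'   rescaled before combination (the joint 99.9th percentile is mapped to
#'   this value).
#'
#' @return An object of class `combiner_config`.
#' @export
combiner_config <- function(beta = 70, intensity_scale = 4095) {
  if (beta < 0) stop("beta must be >= 0")
  if (intensity_scale <= 0) stop("intensity_scale must be positive")
  structure(list(beta = beta, intensity_scale = intensity_scale),
            class = "combiner_config")
}

#' MP2RAGE UNI combination
#'
#' The uniform T1-weighted ratio `Re(Conj(S1) * S2) / (|S1|^2 + |S2|^2)`,
#' bounded in \[-0.5, 0.5\] and invariant under any common complex scaling
#' of the two signals (hence insensitive to receive field, proton density
#' and T2* factors shared by both images).
#'
#' @param S1,S2 Complex (or signed real) INV1/INV2 signals; vectorized.
#'
#' @return Dimensionless values in \[-0.5, 0.5\]; all-zero inputs give 0.
#' @export
#' @examples
#' uni(0.2, 0.2)   #  0.5
#' uni(-0.2, 0.2)  # -0.5
uni <- function(S1, S2) {
  den <- Mod(S1)^2 + Mod(S2)^2
  num <- Re(Conj(S1) * S2)
  out <- ifelse(den > 0, num / den, 0)
  if (is.array(S1)) array(out, dim(S1)) else out
}

#' FLAWS minimum-intensity combination
#'
#' `min(I1, I2) / (I1 + I2)`: the minimum of the WM-suppressed (INV1) and
#' CSF-suppressed (INV2) magnitudes normalized by their sum, giving a
#' GM-dominant contrast in \[0, 0.5\].
#'
#' @param I1,I2 Non-negative magnitudes; vectorized.
#'
#' @return Values in \[0, 0.5\]; all-zero inputs give 0.
#' @export
flaws_min <- function(I1, I2) {
  if (any(I1 < 0, na.rm = TRUE) || any(I2 < 0, na.rm = TRUE))
    stop("FLAWS inputs must be non-negative magnitudes")
  s <- I1 + I2
  out <- ifelse(s > 0, pmin(I1, I2) / s, 0)
  if (is.array(I1)) array(out, dim(I1)) else out
}

#' FLAWS high-contrast ratios
#'
#' `flaws_hco` is `(I2 - I1 - beta) / (I1 + I2 + 2*beta)` (contrast similar
#' to UNI); `flaws_hc` is its opposite-contrast sibling
#' `(I1 - I2 - beta) / (I1 + I2 + 2*beta)`.  With `beta > 0`, empty
#' background voxels map to -0.5 (suppressed) instead of ratio noise.
#'
#' @param I1,I2 Non-negative magnitudes; vectorized.
#' @param beta Regularization constant in the same intensity units.
#'
#' @return Values in \[-1, 1\]; all-zero inputs with `beta = 0` give 0.
#' @export
flaws_hco <- function(I1, I2, beta = 70) {
  if (beta < 0) stop("beta must be >= 0")
  if (any(I1 < 0, na.rm = TRUE) || any(I2 < 0, na.rm = TRUE))
    stop("FLAWS inputs must be non-negative magnitudes")
  den <- I1 + I2 + 2 * beta
  out <- ifelse(den > 0, (I2 - I1 - beta) / den, 0)
  if (is.array(I1)) array(out, dim(I1)) else out
}

#' @rdname flaws_hco
#' @export
flaws_hc <- function(I1, I2, beta = 70) {
  if (beta < 0) stop("beta must be >= 0")
  if (any(I1 < 0, na.rm = TRUE) || any(I2 < 0, na.rm = TRUE))
    stop("FLAWS inputs must be non-negative magnitudes")
  den <- I1 + I2 + 2 * beta
  out <- ifelse(den > 0, (I1 - I2 - beta) / den, 0)
  if (is.array(I1)) array(out, dim(I1)) else out
}

#' FLAWS minimum from the high-contrast pair
#'
#' Minimum-intensity projection of `flaws_hc` and `flaws_hco`.  At
#' `beta = 0` this equals `2 * flaws_min(I1, I2) - 1` exactly; with
#' `beta > 0` it retains the FLAWS-minimum contrast while pushing empty
#' background to -0.5.
#'
#' @inheritParams flaws_hco
#'
#' @return Values in \[-1, 0\] for beta = 0.
#' @export
flaws_min_from_hc <- function(I1, I2, beta = 70) {
  pmin(flaws_hc(I1, I2, beta), flaws_hco(I1, I2, beta))
}

#' Voxelwise image combination
#'
#' Applies one of the MP2RAGE combinations to a pair of volumes after
#' rescaling both to a common intensity range (the joint 99.9th percentile
#' of the magnitudes maps to `cfg$intensity_scale`, so that `beta` acts on a
#' defined scale).  For mode `"uni"`, signed data are reconstructed from the
#' polarity maps attached to the volumes when present; otherwise a
#' magnitude-only UNI is computed and flagged with attribute
#' `magnitude_only`.
#'
#' @param inv1,inv2 [image_volume()] objects (or plain arrays) on matching
#'   grids; magnitudes for the FLAWS modes.
#' @param mode One of `"uni"`, `"flaws_min"`, `"flaws_hc"`, `"flaws_hco"`.
#' @param cfg A [combiner_config()].
#'
#' @return An [image_volume()] with the input grid and spacing.
#' @export
combine_volume <- function(inv1, inv2, mode = c("uni", "flaws_min",
                                                "flaws_hc", "flaws_hco"),
                           cfg = combiner_config()) {
  mode <- match.arg(mode)
  v1 <- as_image_volume(inv1)
  v2 <- as_image_volume(inv2)
  if (!identical(dim(v1$data), dim(v2$data)))
    stop("INV1 and INV2 grids do not match")
  m1 <- abs(v1$data)
  m2 <- abs(v2$data)
  if (mode != "uni" && (any(v1$data < 0) || any(v2$data < 0)))
    stop("FLAWS modes require non-negative magnitude volumes")
  ref <- quantile(c(m1, m2), 0.999, names = FALSE)
  sc <- if (ref > 0) cfg$intensity_scale / ref else 1
  m1 <- m1 * sc
  m2 <- m2 * sc
  magnitude_only <- FALSE
  out <- switch(mode,
    uni = {
      p1 <- if (!is.null(v1$polarity)) v1$polarity else NULL
      p2 <- if (!is.null(v2$polarity)) v2$polarity else NULL
      if (is.null(p1) && is.null(p2)) magnitude_only <- TRUE
      s1 <- if (is.null(p1)) m1 else m1 * p1
      s2 <- if (is.null(p2)) m2 else m2 * p2
      uni(s1, s2)
    },
    flaws_min = if (cfg$beta > 0) flaws_min_from_hc(m1, m2, cfg$beta)
                else flaws_min(m1, m2),
    flaws_hc = flaws_hc(m1, m2, cfg$beta),
    flaws_hco = flaws_hco(m1, m2, cfg$beta))
  res <- image_volume(array(out, dim(v1$data)), spacing = v1$spacing)
  attr(res, "magnitude_only") <- magnitude_only
  res
}
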