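#' Image volume container
#'
#' A thin wrapper around a 3D numeric array with voxel spacing and an
#' optional polarity map (sign of the underlying signed signal, used to
#' reconstruct signed data from magnitude images for the UNI combination).
#'
#' @param data 3D numeric array of finite values.
#' @param spacing Voxel spacing in mm (length 3, positive).
#' @param polarity Optional array of -1/+1 matching `data`.
#'
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), polarity = NULL) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("data must be a 3D array")
  if (any(!is.finite(data))) stop("volume contains non-finite values")
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  if (!is.null(polarity) && !identical(dim(polarity), dim(data)))
    stop("polarity grid does not match data")
  structure(list(data = data, spacing = as.numeric(spacing),
                 polarity = polarity),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s>  spacing %s mm  range [%.4g, %.4g]%s\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data),
              if (!is.null(x$polarity)) "  (+polarity)" else ""))
  invisible(x)
}

as_image_volume <- function(x) {
  if (inherits(x, "image_volume")) return(x)
  if (is.array(x) && length(dim(x)) == 3) return(image_volume(x))
  stop("expected an image_volume or 3D array")
}

#' Read / write NIfTI volumes
#'
#' Round-trips an [image_volume()] through NIfTI-1 with double-precision
#' data, preserving voxel values and spacing exactly.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param vol An [image_volume()].
#'
#' @return `read_nifti_volume` returns an [image_volume()];
#'   `write_nifti_volume` returns `path` invisibly.
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("not a readable NIfTI volume: ", path, " (",
                         conditionMessage(e), ")", call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3D NIfTI volume: ", path)
  image_volume(arr, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_nifti_volume
#' @export
write_nifti_volume <- function(vol, path) {
  vol <- as_image_volume(vol)
  arr <- vol$data
  attr(arr, "pixdim") <- vol$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path,
                     datatype = "double")
  invisible(path)
}

#' Synthetic brain phantom specification
#'
#' Concentric-shell geometry standing in for anatomy: a WM core with an
#' inner CSF pocket (ventricle-like), a GM shell, a CSF rim and empty
#' background, plus a smooth multiplicative B1+ field spanning a declared
#' range (quantized to `n_b1_levels` values so that each level is simulated
#' exactly) and optional complex Gaussian noise.
#'
#' @param dim Grid size (length 3).
#' @param spacing Voxel spacing in mm.
#' @param b1_range Range of the B1+ map.
#' @param n_b1_levels Number of distinct B1 values in the map.
#' @param sigma Complex-noise SD in signal units.
#' @param seed RNG seed for the noise.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(40, 40, 40), spacing = c(0.65, 0.65, 0.65),
                         b1_range = c(0.5, 1.4), n_b1_levels = 10,
                         sigma = 0, seed = 20221109) {
  if (length(dim) != 3 || any(dim < 8)) stop("dim must be 3 values >= 8")
  if (any(b1_range <= 0) || b1_range[1] > b1_range[2])
    stop("invalid b1_range")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 b1_range = as.numeric(b1_range),
                 n_b1_levels = as.integer(n_b1_levels),
                 sigma = sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_labels <- function(spec) {
  d <- spec$dim
  ax <- function(n) (seq_len(n) - (n + 1) / 2) / ((min(d) - 1) / 2)
  r <- sqrt(outer(outer(ax(d[1])^2, ax(d[2])^2, "+"), ax(d[3])^2, "+"))
  lab <- array("BG", dim = d)
  lab[r < 0.90] <- "CSF"
  lab[r < 0.72] <- "GM"
  lab[r < 0.45] <- "WM"
  lab[r < 0.14] <- "CSF"  # central ventricle-like pocket
  lab
}

# 6-neighborhood erosion: keep voxels whose neighbours share the label
erode_mask <- function(mask) {
  d <- dim(mask)
  m <- mask
  pad <- function(a, dd, s) {
    idx <- lapply(seq_along(d), function(k) seq_len(d[k]))
    idx[[dd]] <- pmin(pmax(idx[[dd]] + s, 1), d[dd])
    do.call(`[`, c(list(a), idx))
  }
  for (dd in 1:3) for (s in c(-1, 1)) m <- m & pad(mask, dd, s)
  m
}

#' Generate a synthetic MP2RAGE phantom
#'
#' Assigns every voxel the steady-state INV1/INV2 signal simulated for its
#' tissue at its local B1+ scale, adds complex Gaussian noise, and returns
#' magnitude volumes with polarity maps plus per-tissue masks (eroded by one
#' voxel so that no partial-volume boundary voxel enters the metrics).
#'
#' @param spec A [phantom_spec()].
#' @param seq A [sequence_params()] object.
#' @param tissues Named list with `WM`, `GM`, `CSF` [tissue_params()].
#'
#' @return A list with [image_volume()]s `inv1` and `inv2` (magnitude, with
#'   polarity), logical `masks` (`WM`, `GM`, `CSF`, `BG`), the `b1_map`,
#'   the tissue `labels`, and `truth` — the noiseless complex signals per
#'   tissue and B1 level.
#' @export
generate_phantom <- function(spec, seq, tissues = default_tissues()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(seq, "sequence_params"))
  lab <- phantom_labels(spec)
  d <- spec$dim
  levels_b1 <- if (spec$n_b1_levels == 1 ||
                   spec$b1_range[1] == spec$b1_range[2])
    mean(spec$b1_range)
  else seq(spec$b1_range[1], spec$b1_range[2],
           length.out = spec$n_b1_levels)
  # smooth left-right gradient, quantized to the simulated levels
  g <- (seq_len(d[1]) - 1) / max(d[1] - 1, 1)
  b1_line <- levels_b1[pmin(length(levels_b1),
                            1 + floor(g * length(levels_b1) * 0.999999))]
  b1_map <- array(rep(b1_line, times = prod(d[2:3])), dim = d)

  truth <- list()
  for (t in c("WM", "GM", "CSF")) {
    truth[[t]] <- lapply(levels_b1, function(b)
      simulate_steady_state(seq, tissues[[t]], b1_scale = b))
  }
  s1 <- array(0 + 0i, dim = d)
  s2 <- array(0 + 0i, dim = d)
  for (t in c("WM", "GM", "CSF")) {
    for (li in seq_along(levels_b1)) {
      sel <- lab == t & b1_map == levels_b1[li]
      if (any(sel)) {
        s1[sel] <- truth[[t]][[li]]$S1
        s2[sel] <- truth[[t]][[li]]$S2
      }
    }
  }
  if (spec$sigma > 0) {
    set.seed(spec$seed)
    n <- prod(d)
    s1 <- s1 + spec$sigma * complex(real = rnorm(n), imaginary = rnorm(n))
    s2 <- s2 + spec$sigma * complex(real = rnorm(n), imaginary = rnorm(n))
  }
  pol <- function(s) array(ifelse(Re(s) >= 0, 1, -1), dim = d)
  masks <- list()
  for (t in c("WM", "GM", "CSF")) masks[[t]] <- erode_mask(lab == t)
  masks$BG <- lab == "BG"
  list(inv1 = image_volume(array(Mod(s1), d), spec$spacing, pol(s1)),
       inv2 = image_volume(array(Mod(s2), d), spec$spacing, pol(s2)),
       masks = masks, b1_map = b1_map, labels = lab,
       truth = list(b1_levels = levels_b1, signals = truth))
}

#' Image-domain CNR
#'
#' The difference between the mean intensities of two tissue masks divided
#' by the raw median absolute deviation (no Gaussian consistency factor) of
#' the UNI signal within the WM mask.
#'
#' @param img An [image_volume()] (or 3D array): the contrast image.
#' @param mask_a,mask_b Logical arrays selecting the two tissues.
#' @param uni_img The UNI [image_volume()] supplying the noise reference.
#' @param wm_mask Logical array: WM voxels in the UNI image.
#'
#' @return Signed CNR (dimensionless).
#' @export
estimate_image_cnr <- function(img, mask_a, mask_b, uni_img, wm_mask) {
  img <- as_image_volume(img)$data
  u <- as_image_volume(uni_img)$data
  if (!any(mask_a) || !any(mask_b) || !any(wm_mask))
    stop("empty tissue mask")
  noise <- mad(u[wm_mask], constant = 1)
  if (noise <= 0) stop("zero MAD in the UNI WM mask; cannot form CNR")
  (mean(img[mask_a]) - mean(img[mask_b])) / noise
}

#' Tissue contrast as a percentage of the UNI WM signal
#'
#' `100 * (mean(img\[A\]) - mean(img\[B\])) / mean(UNI\[WM\])`.
#'
#' @inheritParams estimate_image_cnr
#'
#' @return Signed contrast in percent of the UNI WM intensity.
#' @export
contrast_ratio <- function(img, mask_a, mask_b, uni_img, wm_mask) {
  img <- as_image_volume(img)$data
  u <- as_image_volume(uni_img)$data
  if (!any(mask_a) || !any(mask_b) || !any(wm_mask))
    stop("empty tissue mask")
  ref <- mean(u[wm_mask])
  if (ref == 0) stop("zero mean UNI WM signal")
  100 * (mean(img[mask_a]) - mean(img[mask_b])) / ref
}
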