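#' Tissue relaxation and diffusion parameters
#'
#' Bundles the longitudinal and transverse relaxation times, relative proton
#' density and apparent diffusion coefficient describing one tissue class.
#'
#' @param name Tissue label, e.g. `"WM"`, `"GM"`, `"CSF"`.
#' @param T1 Longitudinal relaxation time in ms (> 0).
#' @param T2 Transverse relaxation time in ms (> 0 and <= `T1`).
#' @param PD Relative proton density in (0, 1].
#' @param D Apparent diffusion coefficient in mm^2/s (>= 0).
#'
#' @return An object of class `tissue_params`.
#' @seealso [default_tissues()]
#' @export
#' @examples
#' wm <- tissue_params("WM", T1 = 1220, T2 = 45.9, PD = 0.69, D = 0.70e-3)
tissue_params <- function(name, T1, T2, PD, D = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(T1) || length(T1) != 1L || T1 <= 0)
    stop("T1 must be a single positive number (ms)")
  if (!is.numeric(T2) || length(T2) != 1L || T2 <= 0)
    stop("T2 must be a single positive number (ms)")
  if (T2 > T1) stop("T2 must not exceed T1")
  if (!is.numeric(PD) || length(PD) != 1L || PD <= 0 || PD > 1)
    stop("PD must lie in (0, 1]")
  if (!is.numeric(D) || length(D) != 1L || D < 0)
    stop("D must be a non-negative diffusion coefficient (mm^2/s)")
  structure(list(name = name, T1 = T1, T2 = T2, PD = PD, D = D),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("<tissue %s>  T1 %g ms  T2 %g ms  PD %g  D %g mm^2/s\n",
              x$name, x$T1, x$T2, x$PD, x$D))
  invisible(x)
}

#' Adult 7T brain tissue parameter set
#'
#' White matter, gray matter and CSF with literature adult T1/T2 values of
#' 1220/45.9, 2132/55 and 3350/1000 ms, proton densities 0.69, 0.82 and 1,
#' and apparent diffusion coefficients of 0.70e-3, 0.80e-3 and 3.0e-3 mm^2/s.
#'
#' @return A named list of [tissue_params()] objects (`WM`, `GM`, `CSF`).
#' @export
default_tissues <- function() {
  list(WM  = tissue_params("WM", 1220, 45.9, 0.69, 0.70e-3),
       GM  = tissue_params("GM", 2132, 55, 0.82, 0.80e-3),
       CSF = tissue_params("CSF", 3350, 1000, 1.00, 3.0e-3))
}

tissue_matrix <- function(tissues) {
  stopifnot(all(c("WM", "GM", "CSF") %in% names(tissues)))
  do.call(rbind, lapply(tissues[c("WM", "GM", "CSF")], function(t)
    c(t$T1, t$T2, t$PD, t$D)))
}
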