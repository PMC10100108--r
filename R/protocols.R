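#' Read protocol configurations
#'
#' Protocols are stored as YAML maps (see
#' `system.file("extdata", "protocols.yaml", package = "flawsopt")` for the
#' shipped presets).  The excitations per block and the k-space-center
#' index are derived from the inner matrix size and partial Fourier
#' fraction via [center_index()].
#'
#' @param path YAML file containing one or more named protocols.
#' @param name Protocol name; required when the file holds several.
#'
#' @return A [sequence_params()] object with additional acquisition fields
#'   (`n_outer`, `pf_outer`, `grappa`, `acs_lines`) stored as attributes
#'   for [scan_duration()].
#' @export
read_protocol <- function(path, name = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$TR_MP2RAGE)) {
    p <- cfg
  } else {
    if (is.null(name))
      stop("file contains several protocols; supply `name` (one of: ",
           paste(names(cfg), collapse = ", "), ")")
    p <- cfg[[name]]
    if (is.null(p)) stop("protocol not found: ", name)
  }
  nExc <- as.integer(round(p$nInner * p$pf_inner))
  kCenter <- center_index(p$nInner, p$pf_inner)
  seq <- sequence_params(
    TR_MP2RAGE = p$TR_MP2RAGE, TR_GRE = p$TR_GRE, TI1 = p$TI1, TI2 = p$TI2,
    alpha1 = p$alpha1, alpha2 = p$alpha2, nExc = nExc, kCenter = kCenter,
    spoiling = spoiling_schedule(voxel_size = p$voxel_size),
    eff = if (is.null(p$eff)) 1 else p$eff,
    TE = if (is.null(p$TE)) NA_real_ else p$TE)
  attr(seq, "acquisition") <- list(
    n_outer = p$n_outer, pf_outer = p$pf_outer, grappa = p$grappa,
    acs_lines = p$acs_lines)
  seq
}

#' Load a shipped protocol preset
#'
#' @param name One of `"screening_tr4000"`, `"screening_tr4500"`,
#'   `"screening_tr5000"`, `"final"`, `"low_b1_sensitive"`,
#'   `"flaws_0p8mm"`.
#'
#' @return A [sequence_params()] object; see [read_protocol()].
#' @export
#' @examples
#' load_protocol("final")
load_protocol <- function(name) {
  read_protocol(system.file("extdata", "protocols.yaml",
                            package = "flawsopt", mustWork = TRUE), name)
}

#' Read a tissue set from YAML
#'
#' @param path YAML file mapping tissue names to `T1`, `T2`, `PD` and
#'   optionally `D`.  Defaults to the shipped adult 7T set.
#'
#' @return A named list of [tissue_params()].
#' @export
read_tissues <- function(path = system.file("extdata", "tissues.yaml",
                                            package = "flawsopt",
                                            mustWork = TRUE)) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    t <- cfg[[nm]]
    tissue_params(nm, T1 = t$T1, T2 = t$T2, PD = t$PD,
                  D = if (is.null(t$D)) 0 else as.numeric(t$D))
  })
  names(out) <- names(cfg)
  out
}
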