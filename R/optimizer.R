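#' Flip-angle search grids
#'
#' `fa_grid()` is the fine search (1-10 degrees in 1-degree steps for both
#' angles); `fa_grid_coarse()` is the screening grid (alpha1 1-9, alpha2
#' 1-17, both in 2-degree steps).
#'
#' @param alpha1,alpha2 Positive flip-angle vectors in degrees.
#'
#' @return An object of class `fa_grid`.
#' @export
fa_grid <- function(alpha1 = 1:10, alpha2 = 1:10) {
  if (length(alpha1) == 0 || length(alpha2) == 0 ||
      any(alpha1 <= 0) || any(alpha2 <= 0))
    stop("flip-angle grids must be non-empty and positive")
  structure(list(alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2)),
            class = "fa_grid")
}

#' @rdname fa_grid
#' @export
fa_grid_coarse <- function() fa_grid(seq(1, 9, by = 2), seq(1, 17, by = 2))

#' Inversion-time search grid
#'
#' TI1 from 600 ms up to `ti1_max` and TI2 from 2000 to 3200 ms, both in
#' 200 ms steps; pairs that do not fit the block timing are masked during
#' the search.
#'
#' @param ti1 TI1 candidate values, ms.
#' @param ti2 TI2 candidate values, ms.
#' @param ti1_max Upper end of the default TI1 range, ms.
#'
#' @return An object of class `ti_grid`.
#' @export
ti_grid <- function(ti1 = seq(600, ti1_max, by = 200),
                    ti2 = seq(2000, 3200, by = 200), ti1_max = 1600) {
  structure(list(ti1 = as.numeric(ti1), ti2 = as.numeric(ti2)),
            class = "ti_grid")
}

#' CNR maps over a flip-angle grid
#'
#' Evaluates all contrast channels at every flip-angle combination of the
#' grid: EPG steady-state signals for WM/GM/CSF at every B1 scale, then the
#' Monte-Carlo CNR of the four channels averaged over B1, plus the UNI
#' total, FLAWS_min total and the joint `cnr_total` objective per
#' sqrt(ms).
#'
#' @param seq A [sequence_params()] object fixing the timing.
#' @param grid An [fa_grid()].
#' @param tissues Named list with `WM`, `GM`, `CSF` [tissue_params()].
#' @param b1 A [b1_grid()].
#' @param noise A [noise_model()]; a `NULL` sigma is calibrated from the
#'   protocol's nominal flip angles at this `TR_GRE`.
#'
#' @return An object of class `cnr_map`: the grid axes and matrices
#'   (`length(alpha1)` x `length(alpha2)`) per channel.
#' @export
fa_cnr_maps <- function(seq, grid = fa_grid(), tissues = default_tissues(),
                        b1 = b1_grid(), noise = noise_model()) {
  stopifnot(inherits(seq, "sequence_params"), inherits(grid, "fa_grid"),
            inherits(b1, "b1_grid"), inherits(noise, "noise_model"))
  block_timing(seq)  # fail early on infeasible timing
  if (is.null(noise$sigma))
    noise$sigma <- calibrate_sigma(seq, tissues, noise = noise)
  n1 <- length(grid$alpha1)
  n2 <- length(grid$alpha2)
  S <- epg_grid_cpp(seq_to_cpp(seq), tissue_matrix(tissues), grid$alpha1,
                    grid$alpha2, b1$scales, TRUE, TRUE, TRUE, 50L, 1e-9)
  set.seed(noise$seed)
  cnr <- mc_cnr_grid_cpp(S, noise$sigma, noise$n_reps)  # 4 x (n2*n1)
  chan <- function(i) matrix(cnr[i, ], nrow = n1, ncol = n2, byrow = TRUE)
  uni_wm_gm <- chan(1)
  uni_gm_csf <- chan(2)
  flaws_gm_wm <- chan(3)
  flaws_gm_csf <- chan(4)
  uni_total <- uni_wm_gm + uni_gm_csf
  flaws_total <- flaws_gm_wm + flaws_gm_csf
  total <- (uni_total + flaws_total) / sqrt(seq$TR_MP2RAGE)
  dn <- list(alpha1 = format(grid$alpha1), alpha2 = format(grid$alpha2))
  maps <- list(uni_wm_gm = uni_wm_gm, uni_gm_csf = uni_gm_csf,
               uni_total = uni_total, flaws_gm_wm = flaws_gm_wm,
               flaws_gm_csf = flaws_gm_csf, flaws_total = flaws_total,
               cnr_total = total)
  maps <- lapply(maps, function(m) { dimnames(m) <- dn; m })
  structure(c(list(alpha1 = grid$alpha1, alpha2 = grid$alpha2,
                   TR_MP2RAGE = seq$TR_MP2RAGE, sigma = noise$sigma,
                   n_reps = noise$n_reps), maps),
            class = "cnr_map")
}

#' @export
print.cnr_map <- function(x, ...) {
  i <- which(x$cnr_total == max(x$cnr_total), arr.ind = TRUE)[1, ]
  cat(sprintf(
    "<cnr_map %dx%d>  TR %g ms  max CNR_total %.4f /sqrt(ms) at %g/%g deg\n",
    length(x$alpha1), length(x$alpha2), x$TR_MP2RAGE, max(x$cnr_total),
    x$alpha1[i[1]], x$alpha2[i[2]]))
  invisible(x)
}

#' Constrained flip-angle selection
#'
#' Among flip-angle pairs retaining at least `uni_fraction` of the maximum
#' total UNI CNR, returns the pair maximizing the total FLAWS_min CNR.
#' Ties are broken toward the smaller `alpha2`, then the smaller `alpha1`
#' (lower SAR).
#'
#' @param map A [fa_cnr_maps()] result.
#' @param uni_fraction Fraction of the maximum UNI total that must be
#'   retained (default 0.85).
#'
#' @return A list with `alpha1`, `alpha2`, `uni_total`, `flaws_total`,
#'   `uni_fraction_achieved` (achieved UNI total relative to the grid
#'   maximum) and `cnr_total`.
#' @export
select_fa <- function(map, uni_fraction = 0.85) {
  stopifnot(inherits(map, "cnr_map"))
  uni_max <- max(map$uni_total)
  feasible <- map$uni_total >= uni_fraction * uni_max
  if (!any(feasible)) stop("no flip-angle pair satisfies the UNI constraint")
  cand <- which(feasible, arr.ind = TRUE)
  # order candidates by alpha2 then alpha1 so which.max keeps the smallest
  ord <- order(map$alpha2[cand[, 2]], map$alpha1[cand[, 1]])
  cand <- cand[ord, , drop = FALSE]
  best <- cand[which.max(map$flaws_total[cand]), ]
  i <- best[1]; j <- best[2]
  list(alpha1 = map$alpha1[i], alpha2 = map$alpha2[j],
       uni_total = map$uni_total[i, j], flaws_total = map$flaws_total[i, j],
       uni_fraction_achieved = map$uni_total[i, j] / uni_max,
       cnr_total = map$cnr_total[i, j])
}

#' TI grid search across MP2RAGE TRs
#'
#' For each TR and each feasible TI pair, evaluates the joint objective over
#' the flip-angle grid and records the maximum and its argmax pair.
#' Infeasible TI pairs (negative inter-block delays) are masked.
#'
#' @param seq_template A [sequence_params()] object supplying `TR_GRE`,
#'   `nExc`, `kCenter`, spoiling and `eff`; its TR and TIs are replaced.
#' @param TRs MP2RAGE TR values to scan, ms.
#' @param tis A [ti_grid()].
#' @param grid An [fa_grid()].
#' @param tissues,b1,noise As in [fa_cnr_maps()]; the sigma (calibrated once
#'   from the template if `NULL`) is shared by every TI/TR cell, matching
#'   the constant-noise-per-TR_GRE convention.
#'
#' @return A data frame with one row per (TR, TI1, TI2): feasibility, the
#'   maximum `cnr_total` and the argmax flip angles.
#' @export
ti_grid_search <- function(seq_template, TRs, tis = ti_grid(),
                           grid = fa_grid(), tissues = default_tissues(),
                           b1 = b1_grid(), noise = noise_model()) {
  stopifnot(inherits(seq_template, "sequence_params"))
  if (is.null(noise$sigma))
    noise$sigma <- calibrate_sigma(seq_template, tissues, noise = noise)
  rows <- list()
  for (TR in TRs) {
    for (ti1 in tis$ti1) {
      for (ti2 in tis$ti2) {
        row <- data.frame(TR_MP2RAGE = TR, TI1 = ti1, TI2 = ti2,
                          feasible = FALSE, max_cnr_total = NA_real_,
                          best_alpha1 = NA_real_, best_alpha2 = NA_real_)
        s <- seq_template
        ok <- ti1 < ti2 && ti2 < TR
        if (ok) {
          s$TR_MP2RAGE <- TR
          s$TI1 <- ti1
          s$TI2 <- ti2
          ok <- !inherits(try(block_timing(s), silent = TRUE), "try-error")
        }
        if (ok) {
          m <- fa_cnr_maps(s, grid, tissues, b1, noise)
          i <- which(m$cnr_total == max(m$cnr_total), arr.ind = TRUE)[1, ]
          row$feasible <- TRUE
          row$max_cnr_total <- max(m$cnr_total)
          row$best_alpha1 <- m$alpha1[i[1]]
          row$best_alpha2 <- m$alpha2[i[2]]
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0) stop("empty TI/TR search space")
  out <- do.call(rbind, rows)
  if (!any(out$feasible)) stop("no feasible TI/TR combination in the grid")
  out
}

#' T1 value range for the sensitivity analysis
#'
#' The Cartesian product of evenly spaced WM and GM T1 values; defaults give
#' the 16 sets spanning WM 800-1150 ms and GM 1550-1900 ms.
#'
#' @param wm,gm T1 values in ms.
#'
#' @return An object of class `t1_range`.
#' @export
t1_range <- function(wm = seq(800, 1150, length.out = 4),
                     gm = seq(1550, 1900, length.out = 4)) {
  structure(list(wm = wm, gm = gm, n_sets = length(wm) * length(gm)),
            class = "t1_range")
}

#' Sensitivity of the optimal flip angles to T1 variation
#'
#' Re-runs the flip-angle optimization for every (WM T1, GM T1) combination
#' and reports the mean and SD of the argmax angles under two objectives:
#' maximum joint `cnr_total` and maximum total UNI CNR.
#'
#' @param seq,grid,tissues,b1,noise As in [fa_cnr_maps()].  The tissue T2,
#'   PD and D values (and CSF) are kept fixed; only the WM and GM T1s vary.
#' @param range A [t1_range()].
#'
#' @return A data frame with one row per objective: mean and SD of the
#'   optimal `alpha1` and `alpha2` over the T1 sets.
#' @export
t1_sensitivity <- function(seq, grid = fa_grid(), range = t1_range(),
                           tissues = default_tissues(), b1 = b1_grid(),
                           noise = noise_model()) {
  if (is.null(noise$sigma))
    noise$sigma <- calibrate_sigma(seq, tissues, noise = noise)
  opt <- expand.grid(wm = range$wm, gm = range$gm)
  res <- matrix(NA_real_, nrow(opt), 4,
                dimnames = list(NULL, c("tot_a1", "tot_a2", "uni_a1",
                                        "uni_a2")))
  for (r in seq_len(nrow(opt))) {
    tis <- tissues
    tis$WM$T1 <- opt$wm[r]
    tis$GM$T1 <- opt$gm[r]
    m <- fa_cnr_maps(seq, grid, tis, b1, noise)
    i <- which(m$cnr_total == max(m$cnr_total), arr.ind = TRUE)[1, ]
    j <- which(m$uni_total == max(m$uni_total), arr.ind = TRUE)[1, ]
    res[r, ] <- c(m$alpha1[i[1]], m$alpha2[i[2]], m$alpha1[j[1]],
                  m$alpha2[j[2]])
  }
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  data.frame(
    objective = c("cnr_total", "uni_total"),
    alpha1_mean = c(mean(res[, "tot_a1"]), mean(res[, "uni_a1"])),
    alpha1_sd = c(sd0(res[, "tot_a1"]), sd0(res[, "uni_a1"])),
    alpha2_mean = c(mean(res[, "tot_a2"]), mean(res[, "uni_a2"])),
    alpha2_sd = c(sd0(res[, "tot_a2"]), sd0(res[, "uni_a2"])))
}

#' Contour figures and CSV export of a CNR map
#'
#' Writes one contour figure (PDF, 8 levels by default) per channel and a
#' long-format CSV of the grid.
#'
#' @param map A [fa_cnr_maps()] result.
#' @param levels Number of contour levels.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#'
#' @return Invisibly, the paths of the files written.
#' @export
contour_report <- function(map, levels = 8, dir = tempdir(),
                           prefix = "cnr_map") {
  stopifnot(inherits(map, "cnr_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- c("uni_wm_gm", "uni_gm_csf", "uni_total", "flaws_gm_wm",
                "flaws_gm_csf", "flaws_total", "cnr_total")
  paths <- character(0)
  for (ch in channels) {
    f <- file.path(dir, sprintf("%s_%s.pdf", prefix, ch))
    grDevices::pdf(f, width = 5, height = 4.5)
    z <- map[[ch]]
    if (diff(range(z)) > 0) {
      graphics::contour(map$alpha1, map$alpha2, z, nlevels = levels,
                        xlab = "alpha1 (deg)", ylab = "alpha2 (deg)",
                        main = ch)
    } else {
      graphics::plot.new()
      graphics::title(main = sprintf("%s (constant %.4g)", ch, z[1, 1]))
    }
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  df <- expand.grid(alpha1 = map$alpha1, alpha2 = map$alpha2)
  for (ch in channels) df[[ch]] <- as.vector(map[[ch]])
  csv <- file.path(dir, sprintf("%s.csv", prefix))
  write.csv(df, csv, row.names = FALSE)
  invisible(c(paths, csv))
}
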