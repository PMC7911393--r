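#' Axis-aligned observer lesion box
#'
#' Voxel-index region of interest, 0-based and half-open: voxel `(i, j, k)`
#' (0-based) is inside iff `low <= (i,j,k) < high` on every axis.
#'
#' @param low,high integer length-3 voxel index bounds.
#' @return object of class `lesion_box`.
#' @export
lesion_box <- function(low, high) {
  low <- as.integer(round(low)); high <- as.integer(round(high))
  if (length(low) != 3L || length(high) != 3L) stop("box bounds must be length 3")
  if (any(low < 0)) stop("box low index must be >= 0")
  if (any(low >= high)) stop("box must satisfy low < high on every axis")
  structure(list(low = low, high = high), class = "lesion_box")
}

#' @export
print.lesion_box <- function(x, ...) {
  cat(sprintf("<lesion_box> [%s) x [%s) x [%s)\n",
              paste(c(x$low[1], x$high[1]), collapse = ", "),
              paste(c(x$low[2], x$high[2]), collapse = ", "),
              paste(c(x$low[3], x$high[3]), collapse = ", ")))
  invisible(x)
}

boxes_intersect <- function(a, b) all(a$low < b$high & b$low < a$high)

check_box_in_grid <- function(box, dimv) {
  if (any(box$high > dimv)) stop("box extends outside the image grid")
  invisible(box)
}

# R 1-based index ranges of a box
box_ranges <- function(box) {
  lapply(1:3, function(a) (box$low[a] + 1L):box$high[a])
}

box_values <- function(vol, box) {
  check_box_in_grid(box, dim(vol$values))
  r <- box_ranges(box)
  vol$values[r[[1]], r[[2]], r[[3]], drop = FALSE]
}

# linear (full-grid) voxel indices of a box, in array order
box_linear_indices <- function(dimv, box) {
  r <- box_ranges(box)
  ix <- r[[1]]; iy <- r[[2]]; iz <- r[[3]]
  nx <- dimv[1]; nxy <- dimv[1] * dimv[2]
  as.vector(outer(outer(ix, (iy - 1L) * nx, "+"), (iz - 1L) * nxy, "+"))
}

new_lesion_mask <- function(indices, box, threshold, method, vol,
                            flags = character(), extra = list()) {
  structure(c(list(indices = as.integer(indices),
                   n_voxels = length(indices),
                   box = box, threshold = threshold, method = method,
                   spacing = vol$spacing, dim = dim(vol$values),
                   flags = flags), extra),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> method %s: %d voxels (%.2f cm3), threshold %.4g SUV%s\n",
              x$method, x$n_voxels, mask_volume_cm3(x),
              x$threshold,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Automatic liver reference statistics
#'
#' Mean, sample SD (n - 1 denominator) and maximum SUV over the voxels whose
#' centres fall inside a spherical liver ROI. Measured once per scan and
#' shared by both observers, as the liver-referenced thresholds require.
#'
#' @param volume an `suv_volume`.
#' @param center_mm,radius_mm liver ROI sphere, in mm.
#' @return list of class `liver_stats` with `suv_mean`, `suv_sd`, `suv_max`.
#' @export
compute_liver_stats <- function(volume, center_mm, radius_mm) {
  ext <- volume$origin + dim(volume$values) * volume$spacing
  if (any(center_mm - radius_mm < volume$origin) ||
      any(center_mm + radius_mm > ext))
    stop("liver ROI extends outside the image grid")
  idx <- sphere_indices(dim(volume$values), volume$spacing, volume$origin,
                        center_mm, radius_mm)
  if (length(idx) < 2L) stop("liver ROI contains fewer than 2 voxels")
  v <- volume$values[idx]
  structure(list(suv_mean = mean(v), suv_sd = stats::sd(v), suv_max = max(v)),
            class = "liver_stats")
}

#' PERCIST lesion-inclusion threshold
#'
#' `1.5 x liver SUVmean + 2 x liver SD`.
#'
#' @param liver a `liver_stats`.
#' @return SUV threshold.
#' @export
percist_threshold <- function(liver) {
  1.5 * liver$suv_mean + 2 * liver$suv_sd
}

#' Absolute SUV thresholding
#'
#' Keeps every voxel in the box with SUV >= `threshold` (ties inclusive).
#' No connectivity filtering is applied. An empty result is a valid mask,
#' not an error.
#'
#' @param volume an `suv_volume`.
#' @param box a `lesion_box`.
#' @param threshold absolute SUV level, >= 0.
#' @param method label recorded in the mask.
#' @return a `lesion_mask`.
#' @export
apply_fixed_threshold <- function(volume, box, threshold, method = "fixed") {
  if (threshold < 0) stop("threshold must be >= 0")
  idx <- box_linear_indices(dim(volume$values), check_box_in_grid(box, dim(volume$values)))
  keep <- idx[volume$values[idx] >= threshold]
  new_lesion_mask(keep, box, threshold, method, volume)
}

#' Percentage-of-maximum thresholding (41% SUVmax method)
#'
#' Thresholds at `fraction` of the maximum SUV found inside the box itself,
#' the property that makes the method sensitive to how the observer drew the
#' box: a merged box around an infiltrative cluster inherits the hottest
#' component's maximum.
#'
#' @inheritParams apply_fixed_threshold
#' @param fraction fraction of the in-box maximum, in (0, 1].
#' @return a `lesion_mask`; an all-zero box yields an empty mask with
#'   threshold 0 flagged `"zero_box"`.
#' @export
apply_percent_max_threshold <- function(volume, box, fraction = 0.41,
                                        method = "percent41") {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  idx <- box_linear_indices(dim(volume$values), check_box_in_grid(box, dim(volume$values)))
  v <- volume$values[idx]
  mx <- max(v)
  if (mx == 0)
    return(new_lesion_mask(integer(0), box, 0, method, volume, flags = "zero_box"))
  thr <- fraction * mx
  new_lesion_mask(idx[v >= thr], box, thr, method, volume)
}

#' Local background estimate around a box
#'
#' Mean SUV over a shell of `shell_width` voxels surrounding the box,
#' excluding voxels inside the box itself or inside any other lesion box.
#' The shell is clipped at the grid edge.
#'
#' @inheritParams apply_fixed_threshold
#' @param shell_width shell thickness in voxels, >= 1.
#' @param exclusion list of other `lesion_box`es whose voxels are excluded.
#' @return mean background SUV.
#' @export
estimate_background <- function(volume, box, shell_width = 2L, exclusion = list()) {
  if (shell_width < 1) stop("shell_width must be >= 1")
  dimv <- dim(volume$values)
  check_box_in_grid(box, dimv)
  outer_box <- lesion_box(pmax(box$low - shell_width, 0),
                          pmin(box$high + shell_width, dimv))
  idx <- setdiff(box_linear_indices(dimv, outer_box),
                 box_linear_indices(dimv, box))
  for (ex in exclusion)
    idx <- setdiff(idx, box_linear_indices(dimv, ex))
  if (!length(idx)) stop("background shell is empty after exclusions")
  mean(volume$values[idx])
}

#' Nestle background-corrected thresholding
#'
#' Threshold `T = beta * (I70 + background)`, where `I70` is the mean SUV of
#' the lesion "core" (box voxels at or above `high_fraction` of the box
#' maximum).
#'
#' @inheritParams apply_fixed_threshold
#' @param beta weighting constant in (0, 1); 0.15 by default.
#' @param high_fraction core definition as a fraction of the box maximum.
#' @param background local background SUV (see [estimate_background()]).
#' @return a `lesion_mask` (threshold recorded; `i70` carried alongside).
#' @export
segment_nestle <- function(volume, box, beta = 0.15, high_fraction = 0.70,
                           background) {
  if (beta <= 0 || beta >= 1) stop("beta must be in (0, 1)")
  idx <- box_linear_indices(dim(volume$values), check_box_in_grid(box, dim(volume$values)))
  v <- volume$values[idx]
  mx <- max(v)
  if (mx <= background) stop("box maximum does not exceed background; lesion indistinguishable")
  i70 <- mean(v[v >= high_fraction * mx])
  thr <- beta * (i70 + background)
  new_lesion_mask(idx[v >= thr], box, thr, "nestle", volume,
                  extra = list(i70 = i70, background = background))
}

#' Black iterative mean-SUV thresholding
#'
#' Starting from the 41%-of-maximum mask, iterates
#' `T <- a * SUVmean(mask) + b` and re-thresholds until the mask reaches a
#' fixed point.
#'
#' @inheritParams apply_fixed_threshold
#' @param a,b affine constants of the threshold update (0.307, 0.588 by
#'   default, configurable).
#' @param max_iter iteration cap; `0` returns the initial 41% mask flagged
#'   `"iteration_cap"` with a warning.
#' @return a `lesion_mask` with the converged threshold and the threshold
#'   trace in `$trace`.
#' @export
segment_black <- function(volume, box, a = 0.307, b = 0.588, max_iter = 100L) {
  idx <- box_linear_indices(dim(volume$values), check_box_in_grid(box, dim(volume$values)))
  v <- volume$values[idx]
  start <- apply_percent_max_threshold(volume, box, 0.41, method = "black")
  if (max_iter == 0L) {
    warning("max_iter = 0: returning the initial 41% mask")
    start$flags <- c(start$flags, "iteration_cap")
    return(start)
  }
  cur <- v >= start$threshold
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    thr <- a * mean(v[cur]) + b
    trace <- c(trace, thr)
    nxt <- v >= thr
    if (!any(nxt)) stop("threshold escaped lesion: mask became empty")
    if (identical(nxt, cur))
      return(new_lesion_mask(idx[cur], box, thr, "black", volume,
                             extra = list(trace = trace, iterations = it)))
    cur <- nxt
  }
  stop(sprintf("Black iteration did not converge in %d iterations (threshold trace: %s)",
               max_iter, paste(sprintf("%.4f", utils::tail(trace, 5)), collapse = ", ")))
}

#' Daisne-type adaptive signal-to-background thresholding
#'
#' Iteratively adapts a fractional threshold to the local signal-to-background
#' ratio (SBR): at each step the threshold fraction is
#' `f = m / SBR + c` (clamped to (0, 1]) with `SBR = SUVmean(mask) /
#' background`, and the mask is re-thresholded at `f x box maximum`. The
#' calibration constants `(m, c)` come from [calibrate_adaptive()].
#'
#' @inheritParams apply_fixed_threshold
#' @param calib numeric `c(m, c)` calibration constants.
#' @param background local background SUV, > 0.
#' @param max_iter iteration cap.
#' @return a `lesion_mask` with `$fraction` (final f) and `$trace`.
#' @export
segment_daisne <- function(volume, box, calib, background, max_iter = 100L) {
  if (background <= 0) stop("background must be > 0")
  m <- calib[[1]]; cc <- calib[[2]]
  idx <- box_linear_indices(dim(volume$values), check_box_in_grid(box, dim(volume$values)))
  v <- volume$values[idx]
  mx <- max(v)
  if (mx <= background) stop("insufficient contrast: box maximum <= background")
  cur <- v >= 0.41 * mx   # initial mask: percentage-threshold start
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    sbr <- mean(v[cur]) / background
    if (sbr <= 1) stop("insufficient contrast: SBR <= 1 during iteration")
    f <- min(max(m / sbr + cc, .Machine$double.eps), 1)
    thr <- f * mx
    trace <- c(trace, thr)
    nxt <- v >= thr
    if (!any(nxt)) stop("threshold escaped lesion: mask became empty")
    if (identical(nxt, cur))
      return(new_lesion_mask(idx[cur], box, thr, "daisne", volume,
                             extra = list(fraction = f, sbr = sbr,
                                          trace = trace, iterations = it)))
    cur <- nxt
  }
  stop(sprintf("Daisne iteration did not converge in %d iterations (threshold trace: %s)",
               max_iter, paste(sprintf("%.4f", utils::tail(trace, 5)), collapse = ", ")))
}

#' Phantom calibration of the adaptive fractional threshold
#'
#' For each noiseless blurred-sphere phantom (diameter, contrast) the fraction
#' of the box maximum whose threshold best recovers the analytic sphere volume
#' is located exactly on the finite lattice of attainable thresholds (the
#' volume-vs-fraction curve is a step function; the fraction is taken at the
#' midpoint of the optimal plateau). The fractions are then regressed on
#' 1/SBR to give the constants `(m, c)` of [segment_daisne()].
#'
#' @param sphere_diameters_mm numeric vector of sphere diameters (mm).
#' @param contrasts numeric vector (same length) of lesion:background
#'   contrast ratios, > 1.
#' @param spacing voxel spacing of the calibration grid (mm).
#' @param psf_fwhm_mm PSF FWHM used for the calibration phantoms.
#' @param background background SUV of the calibration phantoms.
#' @return list with `m`, `c` and the per-phantom calibration table.
#' @export
calibrate_adaptive <- function(sphere_diameters_mm, contrasts,
                               spacing = c(5.3, 5.3, 2.0), psf_fwhm_mm = 4.4,
                               background = 1.0) {
  n <- length(sphere_diameters_mm)
  if (n < 2L || length(contrasts) != n)
    stop("need >= 2 (diameter, contrast) calibration phantoms")
  if (any(contrasts <= 1)) stop("contrasts must exceed 1")
  rows <- lapply(seq_len(n), function(i) {
    ph <- blurred_sphere_phantom(sphere_diameters_mm[i], contrasts[i] * background,
                                 background, spacing, psf_fwhm_mm)
    v <- box_values(ph$volume, ph$box)
    mx <- max(v)
    true_vol <- sphere_volume_cm3(sphere_diameters_mm[i] / 2)
    vox <- voxel_cm3(spacing)
    cand <- sort(unique(as.vector(v)))
    vols <- vapply(cand, function(t) sum(v >= t) * vox, 0)
    best <- which.min(abs(vols - true_vol))
    lower <- if (best == 1L) 0 else cand[best - 1L]
    fstar <- (lower + cand[best]) / (2 * mx)
    sbr <- mean(v[v >= cand[best]]) / background
    data.frame(diameter_mm = sphere_diameters_mm[i], contrast = contrasts[i],
               fraction = fstar, sbr = sbr)
  })
  tab <- do.call(rbind, rows)
  if (stats::sd(tab$sbr) < 1e-12) stop("degenerate calibration design: all SBR equal")
  fit <- stats::lm(fraction ~ I(1 / sbr), data = tab)
  list(m = unname(stats::coef(fit)[2]), c = unname(stats::coef(fit)[1]),
       table = tab)
}

# single noiseless blurred sphere on a minimal grid, with its analysis box
blurred_sphere_phantom <- function(diameter_mm, uptake, background, spacing,
                                   psf_fwhm_mm, margin_mm = NULL) {
  r <- diameter_mm / 2
  if (is.null(margin_mm)) margin_mm <- 3 * psf_fwhm_mm + 4 * max(spacing)
  half <- r + margin_mm
  dimv <- as.integer(ceiling(2 * half / spacing))
  center <- dimv * spacing / 2
  vals <- array(background, dimv)
  vals[sphere_indices(dimv, spacing, c(0, 0, 0), center, r)] <- uptake
  vals <- gaussian_blur3d(vals, psf_fwhm_mm, spacing)
  vol <- suv_volume(vals, spacing)
  mb <- ceiling((psf_fwhm_mm + 4) / spacing)
  box <- sphere_tight_box(dimv, spacing, c(0, 0, 0), center, r)
  box <- lesion_box(pmax(box$low - mb, 0), pmin(box$high + mb, dimv))
  list(volume = vol, box = box, center_mm = center, radius_mm = r)
}

# radial profile of a uniform unit sphere of radius R blurred by an isotropic
# Gaussian of width sigma (closed form)
blurred_sphere_profile <- function(r, R, sigma) {
  s2 <- sqrt(2) * sigma
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  out <- numeric(length(r))
  small <- r < 1e-9
  if (any(small))
    out[small] <- erf(R / s2) -
      R * sqrt(2 / pi) / sigma * exp(-R^2 / (2 * sigma^2))
  rr <- r[!small]
  if (length(rr))
    out[!small] <- 0.5 * (erf((R - rr) / s2) + erf((R + rr) / s2)) -
      sigma / (rr * sqrt(2 * pi)) *
        (exp(-(R - rr)^2 / (2 * sigma^2)) - exp(-(R + rr)^2 / (2 * sigma^2)))
  out
}

#' Model-based sphere fitting segmentation
#'
#' Least-squares fit of a forward model -- a uniform sphere on a uniform
#' background convolved with the isotropic Gaussian PSF (closed-form radial
#' profile) -- to the voxels of the box. The MTV is the analytic volume of
#' the fitted sphere; the returned mask (voxel centres inside the fitted
#' sphere) is for visualisation.
#'
#' @inheritParams apply_fixed_threshold
#' @param psf_fwhm_mm assumed PSF FWHM (mm); a small floor (0.35 of the
#'   finest spacing) keeps the model differentiable when 0 is given.
#' @param background_init optional starting value for the background level.
#' @return a `lesion_mask` with `$fit` (centre, diameter, uptake, background,
#'   residual norm, convergence flag) and `$volume_cm3` (analytic fitted
#'   volume, which is the MTV this method reports).
#' @export
segment_fitting <- function(volume, box, psf_fwhm_mm = 4.4,
                            background_init = NULL) {
  dimv <- dim(volume$values)
  check_box_in_grid(box, dimv)
  idx <- box_linear_indices(dimv, box)
  if (length(idx) < 30L) stop("box must contain at least 30 voxels")
  if (psf_fwhm_mm < 0) stop("PSF FWHM must be >= 0")
  v <- volume$values[idx]
  if (max(v) - min(v) < 1e-8)
    stop("flat box: sphere model unidentifiable")
  sigma <- max(fwhm_to_sigma(psf_fwhm_mm), 0.35 * min(volume$spacing))

  sub <- arrayInd(seq_along(idx), vapply(box_ranges(box), length, 1L))
  xyz <- cbind(volume$origin[1] + (box$low[1] + sub[, 1] - 0.5) * volume$spacing[1],
               volume$origin[2] + (box$low[2] + sub[, 2] - 0.5) * volume$spacing[2],
               volume$origin[3] + (box$low[3] + sub[, 3] - 0.5) * volume$spacing[3])

  b0 <- if (is.null(background_init)) stats::quantile(v, 0.25, names = FALSE) else background_init
  a0 <- max(v)
  w <- pmax(v - b0, 0)
  c0 <- colSums(xyz * w) / sum(w)
  n_half <- sum(v >= (a0 + b0) / 2)
  r0 <- max((3 * n_half * prod(volume$spacing) / (4 * pi))^(1 / 3), min(volume$spacing))

  obj <- function(p) {
    ctr <- p[1:3]; R <- exp(p[4]); A <- p[5]; B <- p[6]
    r <- sqrt(rowSums(sweep(xyz, 2, ctr)^2))
    pred <- B + (A - B) * blurred_sphere_profile(r, R, sigma)
    sum((pred - v)^2)
  }
  p0 <- c(c0, log(r0), a0, b0)
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (!is.finite(fit$value))
    stop("sphere fit failed to converge (non-finite objective)")
  ctr <- fit$par[1:3]; R <- exp(fit$par[4])
  if (2 * R <= max(volume$spacing)) stop("sub-resolution lesion: fitted diameter <= 1 voxel")
  r <- sqrt(rowSums(sweep(xyz, 2, ctr)^2))
  keep <- idx[r <= R]
  mask <- new_lesion_mask(keep, box, NA_real_, "fitting", volume,
                          extra = list(
                            fit = list(center_mm = ctr, diameter_mm = 2 * R,
                                       uptake = fit$par[5], background = fit$par[6],
                                       rss = fit$value,
                                       converged = fit$convergence == 0L),
                            volume_cm3 = sphere_volume_cm3(R)))
  mask
}

#' Segmentation method specification
#'
#' Bundles a method name and its parameters; the eight methods are
#' `suv2.5`, `percent41`, `liver_max`, `percist` (thresholding),
#' and `daisne`, `nestle`, `fitting`, `black` (adaptive).
#'
#' @param name method name.
#' @param ... method parameters overriding the defaults (`fraction`,
#'   `level`, `beta`, `high_fraction`, `a`, `b`, `calib`, `psf_fwhm_mm`,
#'   `max_iter`, `shell_width`).
#' @return object of class `method_spec`.
#' @export
method_spec <- function(name = c("suv2.5", "percent41", "liver_max", "percist",
                                 "daisne", "nestle", "fitting", "black"), ...) {
  name <- match.arg(name)
  params <- utils::modifyList(
    list(fraction = 0.41, level = 2.5, beta = 0.15, high_fraction = 0.70,
         a = 0.307, b = 0.588, calib = NULL, psf_fwhm_mm = 4.4,
         max_iter = 100L, shell_width = 2L),
    list(...))
  if (params$fraction <= 0 || params$fraction > 1) stop("fraction must be in (0, 1]")
  if (params$level <= 0) stop("absolute level must be > 0")
  if (params$beta <= 0 || params$beta >= 1) stop("beta must be in (0, 1)")
  structure(list(name = name, params = params), class = "method_spec")
}

#' The eight default method specifications
#' @param psf_fwhm_mm PSF FWHM passed to the fitting method.
#' @param calib Daisne calibration constants (list with `m`, `c`); computed
#'   via [calibrate_adaptive()] with default phantoms when NULL.
#' @return named list of `method_spec`s.
#' @export
default_methods <- function(psf_fwhm_mm = 4.4, calib = NULL) {
  if (is.null(calib))
    calib <- calibrate_adaptive(rep(c(24, 36, 48, 60), times = 4),
                                rep(c(3, 5, 10, 12), each = 4),
                                psf_fwhm_mm = psf_fwhm_mm)
  ms <- list(
    "suv2.5"    = method_spec("suv2.5"),
    "percent41" = method_spec("percent41"),
    "liver_max" = method_spec("liver_max"),
    "percist"   = method_spec("percist"),
    "daisne"    = method_spec("daisne", calib = c(calib$m, calib$c)),
    "nestle"    = method_spec("nestle"),
    "fitting"   = method_spec("fitting", psf_fwhm_mm = psf_fwhm_mm),
    "black"     = method_spec("black"))
  ms
}

#' Delineate one lesion box with a named method
#'
#' Dispatches to the method implementations, supplying the liver statistics
#' for the liver-referenced thresholds and a shell-based local background for
#' the adaptive methods.
#'
#' @param volume an `suv_volume`.
#' @param box a `lesion_box`.
#' @param spec a [method_spec()].
#' @param liver a `liver_stats` (required by `liver_max` and `percist`).
#' @param background local background SUV; estimated from a shell around the
#'   box (excluding `other_boxes`) when NULL and needed.
#' @param other_boxes other lesion boxes excluded from background estimation.
#' @return a `lesion_mask`.
#' @export
segment_lesion <- function(volume, box, spec, liver = NULL, background = NULL,
                           other_boxes = list()) {
  stopifnot(inherits(spec, "method_spec"))
  p <- spec$params
  need_bg <- spec$name %in% c("nestle", "daisne")
  if (need_bg && is.null(background))
    background <- estimate_background(volume, box, p$shell_width, other_boxes)
  switch(spec$name,
    "suv2.5"    = apply_fixed_threshold(volume, box, p$level, method = "suv2.5"),
    "percent41" = apply_percent_max_threshold(volume, box, p$fraction),
    "liver_max" = {
      if (is.null(liver)) stop("liver_max method requires liver stats")
      apply_fixed_threshold(volume, box, liver$suv_max, method = "liver_max")
    },
    "percist"   = {
      if (is.null(liver)) stop("percist method requires liver stats")
      apply_fixed_threshold(volume, box, percist_threshold(liver), method = "percist")
    },
    "nestle"    = segment_nestle(volume, box, p$beta, p$high_fraction, background),
    "black"     = segment_black(volume, box, p$a, p$b, p$max_iter),
    "daisne"    = {
      if (is.null(p$calib)) stop("daisne method requires calibration constants")
      segment_daisne(volume, box, p$calib, background, p$max_iter)
    },
    "fitting"   = segment_fitting(volume, box, p$psf_fwhm_mm))
}

#' MTV of a single lesion mask in cm^3
#'
#' The fitting method reports the analytic fitted-sphere volume; every other
#' method reports voxel count times voxel volume.
#' @param mask a `lesion_mask`.
#' @return volume in cm^3.
#' @export
lesion_mtv_cm3 <- function(mask) {
  if (!is.null(mask$volume_cm3)) mask$volume_cm3 else mask_volume_cm3(mask)
}
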