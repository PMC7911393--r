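#' Phantom generation parameters
#'
#' Assembles the configuration for a synthetic whole-body-like SUV phantom.
#' Geometry defaults follow a clinical PET acquisition: a 168 x 168 transaxial
#' matrix at 5.3 mm/pixel, 2 mm plane spacing, and a point-spread function of
#' 4.4 mm FWHM. Lesions are spheres; an "infiltrative cluster" is a group of
#' 2-4 overlapping spheres with unequal uptakes sharing a `cluster` id, the
#' situation in which observers may delineate one merged region of interest or
#' several per-lesion ones.
#'
#' @param dim integer length-3 grid size in voxels.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param background soft-tissue background SUV level.
#' @param psf_fwhm_mm isotropic PSF full width at half maximum, mm.
#' @param noise_sd SD of additive Gaussian noise applied after the PSF
#'   (clipped at 0); 0 gives a noiseless phantom.
#' @param liver list with `center_mm` (NULL places the sphere in a fixed
#'   corner region), `radius_mm`, `mean_suv`, `sd_suv` (voxel texture SD
#'   inside the liver sphere).
#' @param lesions explicit lesion list; each element a list with `center_mm`,
#'   `radius_mm`, `uptake`, and optional integer `cluster`. NULL to sample
#'   lesions from `lesion_model` at generation time.
#' @param lesion_model random-lesion model used when `lesions` is NULL: number
#'   of focal lesions, diameter and uptake ranges, probability and composition
#'   of an additional infiltrative cluster.
#' @param spleen,marrow organ involvement descriptors: `state` one of
#'   "absent", "focal", "diffuse"; diffuse spleen carries `ratio_to_liver`.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(168L, 168L, 100L),
                           spacing = c(5.3, 5.3, 2.0),
                           background = 1.0,
                           psf_fwhm_mm = 4.4,
                           noise_sd = 0.15,
                           liver = list(center_mm = NULL, radius_mm = 15,
                                        mean_suv = 2.2, sd_suv = 0.25),
                           lesions = NULL,
                           lesion_model = list(n_focal = c(1L, 4L),
                                               diameter_mm = c(16, 60),
                                               uptake = c(5, 18),
                                               cluster_prob = 0.6,
                                               cluster_size = c(2L, 4L),
                                               cluster_diameter_mm = c(16, 40),
                                               cluster_bright_uptake = c(8, 16),
                                               cluster_dim_uptake = c(3.5, 7)),
                           spleen = list(state = "absent"),
                           marrow = list(state = "absent")) {
  if (psf_fwhm_mm < 0) stop("PSF FWHM must be >= 0")
  if (noise_sd < 0) stop("noise SD must be >= 0")
  if (any(dim < 1) || any(spacing <= 0)) stop("invalid grid geometry")
  cfg <- list(dim = as.integer(dim), spacing = as.numeric(spacing),
              origin = c(0, 0, 0), background = background,
              psf_fwhm_mm = psf_fwhm_mm, noise_sd = noise_sd,
              liver = liver, lesions = lesions, lesion_model = lesion_model,
              spleen = spleen, marrow = marrow)
  class(cfg) <- "phantom_config"
  cfg
}

grid_extent_mm <- function(cfg) cfg$origin + cfg$dim * cfg$spacing

default_liver_center <- function(cfg) {
  # fixed right-upper-quadrant position, clear of the lesion placement region
  ext <- grid_extent_mm(cfg)
  r <- cfg$liver$radius_mm
  c(cfg$origin[1] + r + 2 * cfg$spacing[1],
    cfg$origin[2] + r + 2 * cfg$spacing[2],
    ext[3] - r - 2 * cfg$spacing[3])
}

# linear voxel indices whose centres fall inside the sphere
sphere_indices <- function(dimv, spacing, origin, center, radius) {
  ax <- function(a) origin[a] + (seq_len(dimv[a]) - 0.5) * spacing[a]
  xi <- which(abs(ax(1) - center[1]) <= radius)
  yi <- which(abs(ax(2) - center[2]) <= radius)
  zi <- which(abs(ax(3) - center[3]) <= radius)
  if (!length(xi) || !length(yi) || !length(zi)) return(integer(0))
  dx2 <- (ax(1)[xi] - center[1])^2
  dy2 <- (ax(2)[yi] - center[2])^2
  dz2 <- (ax(3)[zi] - center[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  inside <- which(d2 <= radius^2)
  if (!length(inside)) return(integer(0))
  sub <- arrayInd(inside, dim(d2))
  (xi[sub[, 1]]) + (yi[sub[, 2]] - 1L) * dimv[1] +
    (zi[sub[, 3]] - 1L) * dimv[1] * dimv[2]
}

sphere_volume_cm3 <- function(radius_mm) (4 / 3) * pi * radius_mm^3 / 1000

# 0-based half-open voxel bounding box of a sphere, clamped to the grid
sphere_tight_box <- function(dimv, spacing, origin, center, radius) {
  lo <- floor((center - radius - origin) / spacing)
  hi <- ceiling((center + radius - origin) / spacing)
  lesion_box(pmax(lo, 0), pmin(hi, dimv))
}

check_lesion_inside <- function(cfg, center, radius) {
  ext <- grid_extent_mm(cfg)
  if (any(center - radius < cfg$origin) || any(center + radius > ext))
    stop("lesion extends outside the image grid")
}

sample_lesions <- function(cfg) {
  lm <- cfg$lesion_model
  liver_c <- if (is.null(cfg$liver$center_mm)) default_liver_center(cfg) else cfg$liver$center_mm
  ext <- grid_extent_mm(cfg)
  buf <- 12  # mm edge buffer beyond the lesion radius
  draw_center <- function(r, existing) {
    lo <- cfg$origin + r + buf
    hi <- ext - r - buf
    if (any(lo >= hi))
      stop("lesion of this size cannot be placed inside the grid")
    for (try in 1:200) {
      ctr <- vapply(1:3, function(a) stats::runif(1, lo[a], hi[a]), 0)
      # keep clear of the liver by more than the box margin plus any
      # plausible jitter so observer boxes cannot reach the liver region
      if (sqrt(sum((ctr - liver_c)^2)) < cfg$liver$radius_mm + r + 45) next
      ok <- TRUE
      for (e in existing)
        if (sqrt(sum((ctr - e$center_mm)^2)) < e$radius_mm + r + 15) { ok <- FALSE; break }
      if (ok) return(ctr)
    }
    stop("could not place lesion away from liver and other lesions")
  }
  lesions <- list()
  n_focal <- sample(seq(lm$n_focal[1], lm$n_focal[2]), 1)
  for (i in seq_len(n_focal)) {
    r <- stats::runif(1, lm$diameter_mm[1], lm$diameter_mm[2]) / 2
    lesions[[length(lesions) + 1L]] <-
      list(center_mm = draw_center(r, lesions), radius_mm = r,
           uptake = stats::runif(1, lm$uptake[1], lm$uptake[2]), cluster = NA_integer_)
  }
  if (stats::runif(1) < lm$cluster_prob) {
    m <- sample(seq(lm$cluster_size[1], lm$cluster_size[2]), 1)
    r1 <- stats::runif(1, lm$cluster_diameter_mm[1], lm$cluster_diameter_mm[2]) / 2
    anchor <- draw_center(r1 + 15, lesions)  # reserve room for the whole cluster
    lesions[[length(lesions) + 1L]] <-
      list(center_mm = anchor, radius_mm = r1,
           uptake = stats::runif(1, lm$cluster_bright_uptake[1], lm$cluster_bright_uptake[2]),
           cluster = 1L)
    prev <- anchor; prev_r <- r1
    for (j in seq_len(m - 1L)) {
      r <- stats::runif(1, lm$cluster_diameter_mm[1], lm$cluster_diameter_mm[2]) / 2
      ctr <- NULL
      for (try in 1:50) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        cand <- prev + u * 0.8 * (prev_r + r)   # overlapping neighbours
        cand <- pmin(pmax(cand, cfg$origin + r + buf), ext - r - buf)
        if (sqrt(sum((cand - liver_c)^2)) >= cfg$liver$radius_mm + r + 45) {
          ctr <- cand; break
        }
      }
      if (is.null(ctr)) stop("could not place cluster member away from the liver")
      lesions[[length(lesions) + 1L]] <-
        list(center_mm = ctr, radius_mm = r,
             uptake = stats::runif(1, lm$cluster_dim_uptake[1], lm$cluster_dim_uptake[2]),
             cluster = 1L)
      prev <- ctr; prev_r <- r
    }
  }
  lesions
}

#' Generate a synthetic SUV phantom
#'
#' Rasterises the configured lesion spheres (overlaps take the brighter
#' uptake) and the liver sphere onto a uniform background, convolves the
#' volume with the isotropic Gaussian PSF, and adds clipped Gaussian noise
#' plus liver voxel texture. The ground truth records the analytic sphere
#' volumes, so recovery of the truth by each delineation method can be tested.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed; identical (config, seed) pairs reproduce the
#'   phantom bit-for-bit.
#' @return list with elements `volume` (an `suv_volume`) and `truth`
#'   (a `phantom_truth`: lesion table, liver/spleen/marrow descriptors,
#'   background level and grid geometry).
#' @export
generate_phantom <- function(config, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    cfg <- config
    if (is.null(cfg$liver$center_mm)) cfg$liver$center_mm <- default_liver_center(cfg)
    lesions <- if (is.null(cfg$lesions)) sample_lesions(cfg) else cfg$lesions
    for (le in lesions) check_lesion_inside(cfg, le$center_mm, le$radius_mm)
    # liver must stay disjoint from every lesion
    for (le in lesions)
      if (sqrt(sum((le$center_mm - cfg$liver$center_mm)^2)) <=
          le$radius_mm + cfg$liver$radius_mm)
        stop("liver region overlaps a lesion")

    vals <- array(cfg$background, cfg$dim)
    liver_idx <- sphere_indices(cfg$dim, cfg$spacing, cfg$origin,
                                cfg$liver$center_mm, cfg$liver$radius_mm)
    vals[liver_idx] <- cfg$liver$mean_suv

    organ <- function(desc, default_suv) {
      if (identical(desc$state, "absent")) return(desc)
      if (is.null(desc$center_mm) || is.null(desc$radius_mm))
        stop("involved organ needs `center_mm` and `radius_mm`")
      suv <- if (identical(desc$state, "diffuse") && !is.null(desc$ratio_to_liver))
        desc$ratio_to_liver * cfg$liver$mean_suv
      else if (!is.null(desc$suv)) desc$suv else default_suv
      idx <- sphere_indices(cfg$dim, cfg$spacing, cfg$origin,
                            desc$center_mm, desc$radius_mm)
      vals[idx] <<- pmax(vals[idx], suv)
      desc$suv <- suv
      desc
    }
    cfg$spleen <- organ(cfg$spleen, default_suv = 6)
    cfg$marrow <- organ(cfg$marrow, default_suv = 5)

    for (le in lesions) {
      idx <- sphere_indices(cfg$dim, cfg$spacing, cfg$origin,
                            le$center_mm, le$radius_mm)
      vals[idx] <- pmax(vals[idx], le$uptake)
    }

    vals <- gaussian_blur3d(vals, cfg$psf_fwhm_mm, cfg$spacing)
    if (cfg$noise_sd > 0)
      vals <- vals + stats::rnorm(length(vals), 0, cfg$noise_sd)
    if (cfg$liver$sd_suv > 0)
      vals[liver_idx] <- vals[liver_idx] +
        stats::rnorm(length(liver_idx), 0, cfg$liver$sd_suv)
    vals[vals < 0] <- 0

    ltab <- data.frame(
      lesion_id = seq_along(lesions),
      cluster_id = vapply(lesions, function(l)
        if (is.null(l$cluster)) NA_integer_ else as.integer(l$cluster), 1L),
      cx = vapply(lesions, function(l) l$center_mm[1], 0),
      cy = vapply(lesions, function(l) l$center_mm[2], 0),
      cz = vapply(lesions, function(l) l$center_mm[3], 0),
      radius_mm = vapply(lesions, function(l) l$radius_mm, 0),
      uptake = vapply(lesions, function(l) l$uptake, 0))
    ltab$true_volume_cm3 <- sphere_volume_cm3(ltab$radius_mm)

    truth <- structure(list(
      lesions = ltab,
      liver = cfg$liver,
      spleen = cfg$spleen,
      marrow = cfg$marrow,
      background = cfg$background,
      psf_fwhm_mm = cfg$psf_fwhm_mm,
      dim = cfg$dim, spacing = cfg$spacing, origin = cfg$origin,
      total_true_volume_cm3 = sum(ltab$true_volume_cm3)),
      class = "phantom_truth")

    list(volume = suv_volume(vals, cfg$spacing, cfg$origin), truth = truth)
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d lesion(s), total true volume %.2f cm3\n",
              nrow(x$lesions), x$total_true_volume_cm3))
  invisible(x)
}

#' Observer region-of-interest model
#'
#' Parameterises how a human reader places lesion boxes: independent Gaussian
#' jitter on every box face, and a split-vs-merge decision on each
#' infiltrative cluster (one merged box around the whole cluster, or one box
#' per component lesion).
#'
#' @param box_margin_jitter SD of the per-face jitter, in voxels (>= 0).
#' @param split_merge_probability probability that a cluster is delineated as
#'   a single merged box.
#' @param seed integer seed driving this observer's draws.
#' @return list of class `observer_model`.
#' @export
observer_model <- function(box_margin_jitter = 0, split_merge_probability = 0,
                           seed = 1L) {
  if (box_margin_jitter < 0) stop("jitter SD must be >= 0")
  if (split_merge_probability < 0 || split_merge_probability > 1)
    stop("split_merge_probability must be in [0, 1]")
  structure(list(box_margin_jitter = box_margin_jitter,
                 split_merge_probability = split_merge_probability,
                 seed = as.integer(seed)),
            class = "observer_model")
}

tight_lesion_boxes <- function(truth, ids, margin_vox) {
  lt <- truth$lesions[truth$lesions$lesion_id %in% ids, , drop = FALSE]
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (i in seq_len(nrow(lt))) {
    b <- sphere_tight_box(truth$dim, truth$spacing, truth$origin,
                          c(lt$cx[i], lt$cy[i], lt$cz[i]), lt$radius_mm[i])
    lo <- pmin(lo, b$low); hi <- pmax(hi, b$high)
  }
  lesion_box(pmax(lo - margin_vox, 0), pmin(hi + margin_vox, truth$dim))
}

#' Place observer lesion boxes on a phantom
#'
#' Builds each observer box from the ground-truth tight bounding box of the
#' lesion (or of a whole cluster when the merge branch is drawn), expanded by
#' a fixed margin covering the PSF spill-out, then jittered on every face.
#' Boxes are clipped to the grid and must not touch the liver region.
#'
#' @param truth a `phantom_truth`.
#' @param model an [observer_model()].
#' @return list of `lesion_box` objects; each carries attributes `lesions`
#'   (covered lesion ids) and `merged` (logical).
#' @export
place_observer_boxes <- function(truth, model) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(model, "observer_model"))
  margin_vox <- ceiling((truth$psf_fwhm_mm + 4) / truth$spacing)
  liver_box <- sphere_tight_box(truth$dim, truth$spacing, truth$origin,
                                truth$liver$center_mm, truth$liver$radius_mm)
  with_seed(model$seed, {
    groups <- list()
    lt <- truth$lesions
    for (cl in unique(lt$cluster_id[!is.na(lt$cluster_id)])) {
      ids <- lt$lesion_id[!is.na(lt$cluster_id) & lt$cluster_id == cl]
      if (stats::runif(1) < model$split_merge_probability) {
        groups[[length(groups) + 1L]] <- list(ids = ids, merged = TRUE)
      } else {
        for (id in ids) groups[[length(groups) + 1L]] <- list(ids = id, merged = FALSE)
      }
    }
    for (id in lt$lesion_id[is.na(lt$cluster_id)])
      groups[[length(groups) + 1L]] <- list(ids = id, merged = FALSE)

    lapply(groups, function(g) {
      b <- tight_lesion_boxes(truth, g$ids, margin_vox)
      if (model$box_margin_jitter > 0) {
        j_lo <- round(stats::rnorm(3, 0, model$box_margin_jitter))
        j_hi <- round(stats::rnorm(3, 0, model$box_margin_jitter))
        lo <- pmax(b$low - j_lo, 0)
        hi <- pmin(b$high + j_hi, truth$dim)
        if (any(lo >= hi)) stop("jittered box fell outside the image grid")
        b <- lesion_box(lo, hi)
      }
      if (boxes_intersect(b, liver_box))
        stop("observer box overlaps the liver region")
      attr(b, "lesions") <- g$ids
      attr(b, "merged") <- g$merged
      b
    })
  })
}
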