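# fixture builders shared across the suite; everything is generated in code

toy_volume <- function(values, spacing = c(1, 1, 1)) {
  if (is.null(dim(values))) values <- array(values, c(length(values), 1, 1))
  suv_volume(values, spacing = spacing)
}

whole_box <- function(vol) lesion_box(c(0, 0, 0), dim(vol$values))

# independent triple-loop threshold oracle (deliberately naive)
enumerate_threshold <- function(vol, box, threshold) {
  v <- vol$values
  hits <- 0L
  for (i in (box$low[1] + 1):box$high[1])
    for (j in (box$low[2] + 1):box$high[2])
      for (k in (box$low[3] + 1):box$high[3])
        if (v[i, j, k] >= threshold) hits <- hits + 1L
  hits
}

# two-sphere phantom (bright + dim) with no blur/noise, for split-vs-merge
# threshold experiments; centres chosen so the spheres are disjoint
two_lesion_volume <- function(bright = 10, dim_suv = 4.05, bg = 0,
                              spacing = c(1, 1, 1)) {
  vals <- array(bg, c(30, 12, 12))
  dimv <- dim(vals)
  idx1 <- petmtv:::sphere_indices(dimv, spacing, c(0, 0, 0), c(7, 6, 6), 3.2)
  idx2 <- petmtv:::sphere_indices(dimv, spacing, c(0, 0, 0), c(21, 6, 6), 3.2)
  vals[idx1] <- bright
  vals[idx2] <- dim_suv
  list(vol = suv_volume(vals, spacing),
       box1 = lesion_box(c(2, 1, 1), c(12, 11, 11)),
       box2 = lesion_box(c(16, 1, 1), c(26, 11, 11)),
       merged = lesion_box(c(2, 1, 1), c(26, 11, 11)),
       n1 = length(idx1), n2 = length(idx2))
}

fake_liver <- function(mean, sd, max) {
  structure(list(suv_mean = mean, suv_sd = sd, suv_max = max),
            class = "liver_stats")
}

# small deterministic single-sphere phantom config used in several tests
single_sphere_config <- function(radius_mm = 20, uptake = 10, noise_sd = 0,
                                 psf_fwhm_mm = 4.4, dim = c(64, 64, 64),
                                 liver_sd = 0) {
  phantom_config(
    dim = dim, noise_sd = noise_sd, psf_fwhm_mm = psf_fwhm_mm,
    liver = list(center_mm = NULL, radius_mm = 15, mean_suv = 2.2,
                 sd_suv = liver_sd),
    lesions = list(list(center_mm = c(220, 220, 70), radius_mm = radius_mm,
                        uptake = uptake)))
}

# cluster config: bright + dim overlapping spheres (one infiltrative cluster)
cluster_config <- function(noise_sd = 0) {
  phantom_config(
    dim = c(64, 64, 64), noise_sd = noise_sd,
    liver = list(center_mm = NULL, radius_mm = 15, mean_suv = 2.2, sd_suv = 0),
    lesions = list(
      list(center_mm = c(200, 200, 64), radius_mm = 14, uptake = 12, cluster = 1L),
      list(center_mm = c(222, 200, 64), radius_mm = 12, uptake = 4.5, cluster = 1L)))
}
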