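.config_schema <- list(
  phantom = c("dim", "spacing", "background", "psf_fwhm_mm", "noise_sd",
              "liver", "lesions", "lesion_model", "spleen", "marrow"),
  observers = c("box_margin_jitter", "split_merge_probability", "seed"),
  methods = c("suv2.5", "percent41", "liver_max", "percist",
              "daisne", "nestle", "fitting", "black"),
  method_params = c("fraction", "level", "beta", "high_fraction", "a", "b",
                    "calib", "psf_fwhm_mm", "max_iter", "shell_width"),
  stats = c("n_boot", "level", "seed", "hochberg"),
  survival = c("n_patients", "baseline_hazard", "volume_hr",
               "volume_threshold_cm3", "ipi_hr", "ct_hr", "ipi_prob",
               "ct_prob", "censor_range_years", "horizon_years"),
  output = c("dir", "write_volumes"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key(s) in %s: %s", where, paste(bad, collapse = ", ")))
}

#' Assemble and validate a pipeline run configuration
#'
#' Unknown keys anywhere in the configuration are rejected before any
#' computation, as are unknown method names.
#'
#' @param phantom named list of [phantom_config()] overrides.
#' @param observers list of two observer parameter lists
#'   (`box_margin_jitter`, `split_merge_probability`).
#' @param methods named list: method name -> parameter overrides (empty list
#'   for defaults). NULL selects all eight methods.
#' @param stats list: `n_boot`, `level`, `seed`, `hochberg`.
#' @param survival list of [survival_config()] overrides plus `n_patients`
#'   and `horizon_years`.
#' @param output list: `dir`, `write_volumes`.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(phantom = list(), observers = NULL, methods = NULL,
                       stats = list(), survival = list(), output = list()) {
  check_keys(phantom, .config_schema$phantom, "phantom")
  if (is.null(observers))
    observers <- list(list(box_margin_jitter = 1, split_merge_probability = 0.5),
                      list(box_margin_jitter = 1, split_merge_probability = 0.5))
  if (length(observers) != 2L) stop("exactly two observers are required")
  for (o in observers) check_keys(o, .config_schema$observers, "observers")
  if (is.null(methods))
    methods <- stats::setNames(rep(list(list()), 8), .config_schema$methods)
  bad <- setdiff(names(methods), .config_schema$methods)
  if (length(bad))
    stop(sprintf("unknown method name(s): %s", paste(bad, collapse = ", ")))
  for (mn in names(methods))
    check_keys(methods[[mn]], .config_schema$method_params,
               sprintf("methods.%s", mn))
  check_keys(stats, .config_schema$stats, "stats")
  check_keys(survival, .config_schema$survival, "survival")
  check_keys(output, .config_schema$output, "output")
  stats <- utils::modifyList(list(n_boot = 2000L, level = 0.95, seed = 1L,
                                  hochberg = TRUE), stats)
  survival <- utils::modifyList(list(n_patients = 50L, horizon_years = 5), survival)
  output <- utils::modifyList(list(dir = NULL, write_volumes = FALSE), output)
  structure(list(phantom = phantom, observers = observers, methods = methods,
                 stats = stats, survival = survival, output = output),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file path.
#' @return validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(raw, c("phantom", "observers", "methods", "stats", "survival",
                    "output"), "config")
  obs <- raw$observers
  if (is.data.frame(obs)) obs <- lapply(seq_len(nrow(obs)), function(i) as.list(obs[i, ]))
  do.call(run_config, c(list(observers = obs),
                        raw[setdiff(names(raw), "observers")]))
}

build_methods <- function(cfg, phantom_cfg) {
  needs_daisne <- "daisne" %in% names(cfg$methods)
  calib <- NULL
  if (needs_daisne && is.null(cfg$methods$daisne$calib)) {
    cal <- calibrate_adaptive(rep(c(24, 36, 48, 60), times = 4),
                              rep(c(3, 5, 10, 12), each = 4),
                              spacing = phantom_cfg$spacing,
                              psf_fwhm_mm = phantom_cfg$psf_fwhm_mm,
                              background = phantom_cfg$background)
    calib <- list(m = cal$m, c = cal$c)
  }
  out <- list()
  for (mn in names(cfg$methods)) {
    pars <- cfg$methods[[mn]]
    if (mn == "daisne" && is.null(pars$calib)) pars$calib <- c(calib$m, calib$c)
    if (mn == "fitting" && is.null(pars$psf_fwhm_mm))
      pars$psf_fwhm_mm <- phantom_cfg$psf_fwhm_mm
    out[[mn]] <- do.call(method_spec, c(list(name = mn), pars))
  }
  out
}

#' Run the full simulate - segment - aggregate - agreement - prognosis pipeline
#'
#' Produces the complete analysis bundle for one simulated cohort: the
#' measurement tables, descriptive statistics, agreement coefficients with
#' BCa intervals and pairwise bootstrap comparisons, Bland-Altman summaries,
#' ROC cut-offs with inter-observer disagreement accounting, Kaplan-Meier /
#' log-rank / Cox survival results, and a machine-readable JSON of all
#' statistics. Deterministic for a fixed (config, seed).
#'
#' @param config a [run_config()].
#' @param seed master seed overriding `config$stats$seed`.
#' @param out_dir output directory overriding `config$output$dir`; NULL for
#'   no file output.
#' @param n_boot bootstrap-replicate override.
#' @param methods character vector restricting the methods to run.
#' @return the results list, invisibly when written to disk.
#' @export
run_pipeline <- function(config = run_config(), seed = NULL, out_dir = NULL,
                         n_boot = NULL, methods = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(seed)) config$stats$seed <- seed
  if (!is.null(n_boot)) config$stats$n_boot <- n_boot
  if (!is.null(methods)) {
    bad <- setdiff(methods, names(config$methods))
    if (length(bad)) stop(sprintf("unknown method name(s): %s", paste(bad, collapse = ", ")))
    config$methods <- config$methods[methods]
  }
  if (!is.null(out_dir)) config$output$dir <- out_dir

  phantom_cfg <- do.call(phantom_config, config$phantom)
  obs_models <- lapply(config$observers, function(o)
    observer_model(box_margin_jitter = o$box_margin_jitter %||% 0,
                   split_merge_probability = o$split_merge_probability %||% 0))
  surv_keys <- intersect(names(config$survival),
                         c("baseline_hazard", "volume_hr", "volume_threshold_cm3",
                           "ipi_hr", "ct_hr", "ipi_prob", "ct_prob",
                           "censor_range_years"))
  surv_cfg <- do.call(survival_config, config$survival[surv_keys])
  mlist <- build_methods(config, phantom_cfg)
  seed0 <- config$stats$seed
  n_boot <- config$stats$n_boot
  horizon <- config$survival$horizon_years

  cohort <- simulate_cohort(config$survival$n_patients, phantom_cfg,
                            obs_models, surv_cfg, seed = seed0,
                            methods = mlist, keep_images = FALSE)
  pairs <- mtv_pairs(cohort$measurements)
  desc <- descriptive_stats(cohort$measurements)

  boot_seeds <- derive_seeds(seed0 + 1L, 2L * length(pairs) + 2L)
  agree <- list(); ba <- list()
  for (i in seq_along(pairs)) {
    mn <- names(pairs)[i]
    p <- pairs[[mn]]
    icc <- bca_ci(p, function(d) icc_consistency(d$obs1, d$obs2),
                  n_boot = n_boot, seed = boot_seeds[2 * i - 1])
    tau <- bca_ci(p, function(d) kendall_tau_b(d$obs1, d$obs2),
                  n_boot = n_boot, seed = boot_seeds[2 * i])
    agree[[mn]] <- data.frame(method = mn,
                              icc = icc$estimate, icc_lower = icc$lower, icc_upper = icc$upper,
                              tau = tau$estimate, tau_lower = tau$lower, tau_upper = tau$upper)
    b <- bland_altman(p$obs1, p$obs2)
    ba[[mn]] <- data.frame(method = mn, bias = b$bias, sd_diff = b$sd_diff,
                           lower_limit = b$lower_limit, upper_limit = b$upper_limit,
                           n_outside = length(b$outside))
  }
  agree <- do.call(rbind, agree)
  ba <- do.call(rbind, ba)
  cmp_icc <- compare_agreement(pairs, "icc", n_boot = n_boot,
                               seed = boot_seeds[2 * length(pairs) + 1])
  cmp_tau <- compare_agreement(pairs, "tau", n_boot = n_boot,
                               seed = boot_seeds[2 * length(pairs) + 2])

  rec <- censor_at(cohort$records, horizon)
  outcome <- binary_outcome_at(rec, horizon)
  cut_rows <- list()
  for (mn in names(pairs)) {
    p <- pairs[[mn]]
    roc_m <- roc_optimal_cutoff((p$obs1 + p$obs2) / 2, outcome)
    roc_1 <- roc_optimal_cutoff(p$obs1, outcome)
    roc_2 <- roc_optimal_cutoff(p$obs2, outcome)
    cls <- classification_disagreement(p$obs1, p$obs2, roc_1$cutoff, roc_2$cutoff)
    cut_rows[[mn]] <- data.frame(
      method = mn, auc = roc_m$auc, cutoff = roc_m$cutoff,
      sensitivity = roc_m$sensitivity, specificity = roc_m$specificity,
      cutoff_1 = roc_1$cutoff, cutoff_2 = roc_2$cutoff,
      delta_cutoff = cutoff_disagreement(roc_1$cutoff, roc_2$cutoff),
      low_mtv_1 = cls$low_1, low_mtv_2 = cls$low_2, delta_low_mtv = cls$delta_low)
  }
  cutoffs <- do.call(rbind, cut_rows)

  surv_rows <- list()
  for (mn in names(pairs)) {
    p <- pairs[[mn]]
    mean_mtv <- (p$obs1 + p$obs2) / 2
    grp <- mean_mtv >= cutoffs$cutoff[cutoffs$method == mn]
    lr <- tryCatch(log_rank(rec$time_years, rec$event, grp),
                   error = function(e) list(chisq = NA_real_, p = NA_real_))
    km_lo <- km_curve(rec$time_years[!grp], rec$event[!grp])
    km_hi <- km_curve(rec$time_years[grp], rec$event[grp])
    surv_rows[[mn]] <- data.frame(
      method = mn, pfs5_low = km_lo$survival_at(horizon),
      pfs5_high = km_hi$survival_at(horizon),
      logrank_chisq = lr$chisq, logrank_p = lr$p)
  }
  surv_tab <- do.call(rbind, surv_rows)

  cox_method <- if ("percent41" %in% names(pairs)) "percent41" else names(pairs)[1]
  pm <- pairs[[cox_method]]
  rec$mtv_group <- as.integer((pm$obs1 + pm$obs2) / 2 >=
                                cutoffs$cutoff[cutoffs$method == cox_method])
  cox <- tryCatch(cox_fit(rec, c("mtv_group", "ipi_high", "ct_chop")),
                  error = function(e) NULL)
  fup <- reverse_km_median_followup(cohort$records$time_years, cohort$records$event)

  results <- list(
    seed = seed0,
    n_patients = config$survival$n_patients,
    descriptive = desc,
    agreement = agree,
    comparison_icc = cmp_icc,
    comparison_tau = cmp_tau,
    bland_altman = ba,
    cutoffs = cutoffs,
    survival = surv_tab,
    cox = cox,
    cox_method = cox_method,
    median_followup_years = fup$median_years,
    roc_excluded_n = attr(outcome, "n_excluded"))

  dir_out <- config$output$dir
  if (!is.null(dir_out)) {
    dir.create(dir_out, recursive = TRUE, showWarnings = FALSE)
    w <- function(d, f) utils::write.csv(d, file.path(dir_out, f), row.names = FALSE)
    w(cohort$records, "cohort.csv")
    w(cohort$measurements, "measurements.csv")
    w(cohort$boxes, "boxes.csv")
    w(desc, "descriptive.csv")
    w(agree, "agreement.csv")
    w(cmp_icc, "comparison_icc.csv")
    w(cmp_tau, "comparison_tau.csv")
    w(ba, "bland_altman.csv")
    w(cutoffs, "cutoffs.csv")
    w(surv_tab, "survival.csv")
    if (!is.null(cox)) w(as.data.frame(cox), "cox.csv")
    jsonlite::write_json(results, file.path(dir_out, "results.json"),
                         auto_unbox = TRUE, digits = 10, dataframe = "rows",
                         na = "null")
    return(invisible(results))
  }
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read observer box tables and cohort tables as CSV
#'
#' Readers validate the header (a missing column is an error naming the
#' column) and the box invariant `low < high`.
#'
#' @param boxes data.frame with columns patient_id, observer, lesion_id,
#'   low_i..high_k.
#' @param path CSV path.
#' @return the path (writers, invisibly) or the validated data.frame
#'   (readers).
#' @export
write_boxes_csv <- function(boxes, path) {
  utils::write.csv(boxes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boxes_csv
#' @export
read_boxes_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("patient_id", "observer", "lesion_id",
            "low_i", "low_j", "low_k", "high_i", "high_j", "high_k")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("box table %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (any(d$low_i >= d$high_i | d$low_j >= d$high_j | d$low_k >= d$high_k))
    stop(sprintf("box table %s: low index >= high index", path))
  d
}

#' @rdname write_boxes_csv
#' @param records cohort outcome table.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boxes_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("patient_id", "time_years", "event")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("cohort table %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (any(d$time_years < 0) || !all(d$event %in% c(0, 1)))
    stop(sprintf("cohort table %s: invalid time or event values", path))
  d
}
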