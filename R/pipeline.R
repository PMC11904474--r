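#' Pipeline run configuration
#'
#' Collects every tunable setting of the per-subject and cohort pipeline.
#' The defaults reproduce the analysis constants: TBR threshold 1.6,
#' temporal band 0.008-0.09 Hz, 5 mm FWHM smoothing, 7 networks,
#' quartile-extremes survival grouping.
#'
#' @param tbr_threshold TBR segmentation threshold.
#' @param bandpass_low,bandpass_high temporal band edges in Hz.
#' @param smooth_fwhm_mm smoothing kernel FWHM in mm.
#' @param detrend include a linear trend in the nuisance design.
#' @param min_seed_voxels minimum usable cropped-seed size.
#' @param min_node_voxels minimum proximity node size.
#' @param n_networks number of atlas networks.
#' @param z_variant `"fisher-z"` or `"spatial-z"` (see [fc_map()]).
#' @param quantile_scheme survival grouping scheme (see [quantile_groups()]).
#' @param p_enter,p_remove stepwise selection thresholds.
#' @param ties Cox tie handling.
#' @param clinical_covariates covariate names for the adjusted Cox model.
#' @param between_factor optional cohort column used as the between-subject
#'   factor in the repeated-measures ANOVA.
#' @param seed integer seed recorded in the manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(tbr_threshold = 1.6,
                       bandpass_low = BAND_LOW_HZ,
                       bandpass_high = BAND_HIGH_HZ,
                       smooth_fwhm_mm = SMOOTH_FWHM_MM,
                       detrend = TRUE,
                       min_seed_voxels = 10L,
                       min_node_voxels = 5L,
                       n_networks = 7L,
                       z_variant = "fisher-z",
                       quantile_scheme = "quartile-extremes",
                       p_enter = 0.05, p_remove = 0.10,
                       ties = "efron",
                       clinical_covariates = c("age", "ecog",
                                               "mgmt_methylated",
                                               "resection_extent",
                                               "vol_pet_ml"),
                       between_factor = NULL,
                       seed = 1L) {
  structure(list(tbr_threshold = tbr_threshold,
                 bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 smooth_fwhm_mm = smooth_fwhm_mm, detrend = detrend,
                 min_seed_voxels = as.integer(min_seed_voxels),
                 min_node_voxels = as.integer(min_node_voxels),
                 n_networks = as.integer(n_networks),
                 z_variant = z_variant, quantile_scheme = quantile_scheme,
                 p_enter = p_enter, p_remove = p_remove, ties = ties,
                 clinical_covariates = clinical_covariates,
                 between_factor = between_factor,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

#' Run the full per-subject pipeline
#'
#' Preprocess the BOLD series, standardize the PET to TBR (two passes: the
#' reference region first excludes the dilated structural lesions, then the
#' dilated composite including the segmented PET mask), segment the tumor,
#' compose the lesion mask set, and compute the FC profile.
#'
#' @param subject list with `id`, `bold`, `pet`, `brain_mask`, `ce_mask`,
#'   `flair_mask`, `cavity_mask`, `atlas`, `lobe_template` and optionally
#'   `lobe_names` and `nuisance_masks` (as from [simulate_subject()] or
#'   [read_subject()]).
#' @param config `run_config`.
#' @return list with `id`, `profile` (one-row `data.frame` or `NULL`),
#'   `lesion_volumes_ml`, and `error` (`NULL` on success).
#' @export
run_subject <- function(subject, config = run_config()) {
  out <- tryCatch({
    stop_unless_same_grid(subject$brain_mask,
                          subject[c("pet", "ce_mask", "flair_mask",
                                    "cavity_mask", "lobe_template")])
    bold <- subject$bold
    if (is.null(bold$brain_mask)) bold$brain_mask <- subject$brain_mask
    stop_unless_same_grid(subject$brain_mask, list(bold = bold))
    bold <- preprocess_bold(bold,
                            nuisance_masks = subject$nuisance_masks %||% list(),
                            detrend = config$detrend,
                            low_hz = config$bandpass_low,
                            high_hz = config$bandpass_high,
                            fwhm_mm = config$smooth_fwhm_mm)
    # pass 1: reference excludes the (dilated) structural lesions only
    structural <- compose_lesion(
      volume_image(array(0, dim(subject$pet$data)), subject$pet$transform,
                   "binary-mask"),
      subject$ce_mask, subject$flair_mask, subject$cavity_mask)
    excl1 <- if (sum(structural$composite$data) > 0)
      dilate_mask(structural$composite, 1L) else structural$composite
    tbr1 <- standardize_tbr(subject$pet, subject$brain_mask, excl1)
    seg1 <- suppressWarnings(segment_pet(tbr1, config$tbr_threshold))
    # pass 2: reference excludes the dilated full composite lesion
    comp1 <- compose_lesion(seg1$mask, subject$ce_mask, subject$flair_mask,
                            subject$cavity_mask)
    tbr <- standardize_tbr(subject$pet, subject$brain_mask,
                           dilate_mask(comp1$composite, 1L))
    seg <- segment_pet(tbr, config$tbr_threshold)
    if (seg$volume_ml == 0)
      stop("no PET-avid tumor at the TBR threshold")
    lesions <- compose_lesion(seg$mask, subject$ce_mask, subject$flair_mask,
                              subject$cavity_mask)
    profile <- subject_fc_profile(bold, subject$atlas, lesions, tbr,
                                  lobe_template = subject$lobe_template,
                                  lobe_names = subject$lobe_names,
                                  min_seed_voxels = config$min_seed_voxels,
                                  min_node_voxels = config$min_node_voxels,
                                  variant = config$z_variant)
    profile <- cbind(data.frame(id = subject$id %||% NA_character_), profile)
    list(id = subject$id, profile = profile,
         lesion_volumes_ml = lesions$volumes_ml, error = NULL)
  }, error = function(e) {
    list(id = subject$id %||% NA_character_, profile = NULL,
         lesion_volumes_ml = NULL, error = conditionMessage(e))
  })
  out
}

#' Run the cohort pipeline
#'
#' Computes every subject's FC profile, merges the clinical table, and runs
#' the cohort statistics: repeated-measures ANOVA over networks, univariate
#' Cox per network, stepwise forward selection over the 7 network FC values
#' (confirmed backward), Kaplan-Meier stratification of the selected
#' network by quantile groups, and an adjusted multivariate Cox model.
#' Subject failures are recorded in the manifest and never abort the run.
#'
#' @param subjects list of subject lists (see [run_subject()]) or of
#'   zero-argument factory functions returning one; factories keep only one
#'   subject's volumes in memory at a time.
#' @param clinical `data.frame` with `id`, `os_months`, `event` and clinical
#'   covariates.
#' @param config `run_config`.
#' @return list with `profiles`, `cohort`, `rm_anova`, `cox_univariate`,
#'   `stepwise_forward`, `stepwise_backward`, `km`, `adjusted_model`,
#'   `manifest`, `failures` and `notes`.
#' @export
run_cohort <- function(subjects, clinical = NULL, config = run_config()) {
  if (length(subjects) < 2L) stop("run_cohort: need at least 2 subjects")
  t0 <- proc.time()["elapsed"]
  runs <- lapply(subjects, function(s) {
    if (is.function(s)) s <- s()       # lazily materialized subject
    run_subject(s, config)
  })
  failures <- Filter(Negate(is.null), lapply(runs, function(r)
    if (is.null(r$error)) NULL else list(id = r$id, reason = r$error)))
  profiles <- do.call(rbind, lapply(runs, `[[`, "profile"))
  if (is.null(profiles) || nrow(profiles) < 2L)
    stop("run_cohort: fewer than 2 subjects completed")
  message(sprintf("run_cohort: %d/%d subjects completed (%.1f s)",
                  nrow(profiles), length(subjects),
                  proc.time()["elapsed"] - t0))
  cohort <- if (!is.null(clinical)) merge(clinical, profiles, by = "id",
                                          sort = TRUE) else profiles
  cohort <- cohort[order(cohort$id), , drop = FALSE]
  rownames(cohort) <- NULL
  fc_cols <- paste0("fc_", names(network_names()))
  notes <- character(0)
  fc_mat <- as.matrix(cohort[, fc_cols])

  between <- if (!is.null(config$between_factor) &&
                 config$between_factor %in% names(cohort))
    cohort[[config$between_factor]] else NULL
  rma <- tryCatch(rm_anova_gg(fc_mat, between),
                  error = function(e) {
                    notes <<- c(notes, paste("rm_anova skipped:",
                                             conditionMessage(e)))
                    NULL
                  })

  has_surv <- all(c("os_months", "event") %in% names(cohort)) &&
    sum(cohort$event, na.rm = TRUE) >= 1
  uni <- step_f <- step_b <- km <- adj <- NULL
  if (has_surv) {
    cc <- cohort[complete.cases(cohort[, c("os_months", "event", fc_cols)]), ]
    note_try <- function(label, expr) tryCatch(expr, error = function(e) {
      notes <<- c(notes, paste0(label, " skipped: ", conditionMessage(e)))
      NULL
    })
    uni <- note_try("univariate Cox",
                    cox_univariate(cc, fc_cols, ties = config$ties))
    step_f <- note_try("forward selection",
                       cox_stepwise(cc, fc_cols, config$p_enter,
                                    config$p_remove, "forward",
                                    ties = config$ties))
    step_b <- note_try("backward selection",
                       cox_stepwise(cc, fc_cols, config$p_enter,
                                    config$p_remove, "backward",
                                    ties = config$ties))
    target <- if (length(step_f$selected)) step_f$selected[1]
              else if (!is.null(uni)) fc_cols[which.min(uni$p_wald)]
              else fc_cols[3]
    grp <- tryCatch(quantile_groups(cc[[target]], config$quantile_scheme),
                    error = function(e) NULL)
    if (!is.null(grp))
      km <- c(list(network = target),
              km_logrank(cc$os_months, cc$event, grp),
              list(cuts = attr(grp, "cuts"),
                   group_sizes = table(grp)))
    adj_cov <- intersect(config$clinical_covariates, names(cc))
    adj <- tryCatch(cox_fit(cc, c(target, adj_cov), ties = config$ties),
                    error = function(e) {
                      notes <<- c(notes, paste("adjusted model skipped:",
                                               conditionMessage(e)))
                      NULL
                    })
  } else {
    notes <- c(notes, "survival analysis skipped: no events or no survival columns")
  }
  manifest <- list(package = "gliomafc",
                   version = as.character(utils::packageVersion("gliomafc")),
                   config = config[setdiff(names(config), "between_factor")],
                   config_hash = config_hash(config),
                   seed = config$seed,
                   n_subjects = length(subjects),
                   n_completed = nrow(profiles),
                   failures = failures)
  list(profiles = profiles, cohort = cohort, rm_anova = rma,
       cox_univariate = uni, stepwise_forward = step_f,
       stepwise_backward = step_b, km = km, adjusted_model = adj,
       manifest = manifest, failures = failures, notes = notes)
}

#' Write cohort results to disk
#'
#' Writes the profile/cohort tables and result tables as CSV and the run
#' manifest as JSON.  Outputs contain no timestamps, so repeated runs with
#' the same seed and config are byte-identical.
#'
#' @param results output of [run_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                          row.names = FALSE)
  wcsv(results$cohort, "cohort.csv")
  if (!is.null(results$cox_univariate))
    wcsv(results$cox_univariate, "cox_univariate.csv")
  if (!is.null(results$stepwise_forward$result))
    wcsv(as.data.frame(results$stepwise_forward$result),
         "cox_stepwise_forward.csv")
  if (!is.null(results$adjusted_model))
    wcsv(as.data.frame(results$adjusted_model), "cox_adjusted.csv")
  if (!is.null(results$km)) {
    km_tab <- data.frame(group = names(results$km$medians),
                         median_os = as.numeric(results$km$medians))
    km_tab$logrank_chisq <- results$km$chisq
    km_tab$logrank_p <- results$km$p
    wcsv(km_tab, "km_groups.csv")
  }
  extras <- list(rm_anova = results$rm_anova, manifest = results$manifest,
                 notes = results$notes)
  jsonlite::write_json(extras, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Generate a complete synthetic study
#'
#' Produces `n_subjects` co-registered imaging subjects (each with its own
#' atlas realization, tumor coupled to the target network with a
#' per-subject coupling strength) and a survival cohort whose hazard is
#' driven by planted FC effects.  The per-subject couplings are drawn so
#' the measured FC spans a realistic range; the planted survival truth is
#' returned for validation.
#'
#' @param n_subjects number of subjects.
#' @param imaging `sim_imaging_params` template (per-subject seeds derive
#'   from its `seed`).
#' @param cohort_params `sim_cohort_params` (FC covariates are replaced by
#'   measured or planted profiles downstream).
#' @param target_network network the tumors couple to.
#' @param coupling_range range of per-subject coupling alpha, sampled
#'   uniformly.
#' @param log_hr_per_alpha planted log hazard ratio per coupling unit (the
#'   survival signal is carried by the coupling, which the imaging pipeline
#'   observes as the target network's FC).
#' @param out_dir if non-`NULL`, subjects are written as NIfTI files and the
#'   clinical table as CSV under this directory.
#' @param lazy if `TRUE`, `subjects` are zero-argument factory functions
#'   (accepted by [run_cohort()]) instead of materialized lists, keeping
#'   only one subject's volumes in memory at a time.
#' @return list with `subjects` (in-memory list, or factories when `lazy`),
#'   `clinical` (`data.frame`), `truth`, and `dir` (or `NULL`).
#' @export
synth_make <- function(n_subjects = 80L,
                       imaging = sim_imaging_params(),
                       cohort_params = sim_cohort_params(n_subjects = n_subjects,
                                                         seed = imaging$seed),
                       target_network = "dorsal-attention",
                       coupling_range = c(0, 2),
                       log_hr_per_alpha = -0.5,
                       out_dir = NULL, lazy = FALSE) {
  alphas <- with_seed(substream_seed(imaging$seed, "couplings"),
                      runif(n_subjects, coupling_range[1], coupling_range[2]))
  factory <- function(i) {
    force(i)
    function() {
      p <- imaging
      p$coupling <- setNames(alphas[i], target_network)
      simulate_subject(p, subject_id = i, target_network = target_network)
    }
  }
  subjects <- lapply(seq_len(n_subjects), factory)
  if (!lazy) subjects <- lapply(subjects, function(f) f())
  # survival is driven by the planted coupling, which downstream analyses
  # observe through the measured target-network FC
  codes <- names(network_names())
  target_idx <- match(target_network, network_names())
  cp <- cohort_params
  cp$n_subjects <- as.integer(n_subjects)
  cp$log_hr_per_unit_fc <- setNames(rep(0, 7), codes)
  cp$log_hr_per_unit_fc[target_idx] <- log_hr_per_alpha
  fcp <- matrix(0, n_subjects, 7,
                dimnames = list(NULL, paste0("fc_", codes)))
  fcp[, target_idx] <- alphas
  sim <- simulate_cohort(cp, fc_profiles = fcp)
  clinical <- sim$cohort[, setdiff(names(sim$cohort),
                                   paste0("fc_", names(network_names())))]
  truth <- c(sim$truth, list(coupling = setNames(alphas,
                                                 sprintf("S%03d",
                                                         seq_len(n_subjects))),
                             log_hr_per_alpha = log_hr_per_alpha,
                             target_network = target_network))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in subjects) {
      if (is.function(s)) s <- s()
      write_subject(s, file.path(out_dir, s$id))
    }
    utils::write.csv(clinical, file.path(out_dir, "clinical.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(imaging = unclass(imaging),
                              cohort = unclass(cohort_params)[
                                setdiff(names(cohort_params),
                                        "covariate_spec")],
                              coupling = as.list(truth$coupling),
                              target_network = target_network),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  list(subjects = subjects, clinical = clinical, truth = truth,
       dir = out_dir)
}
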