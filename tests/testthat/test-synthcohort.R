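test_that("parameter constructors enforce their invariants", {
  expect_error(sim_imaging_params(grid_shape = c(4, 32, 32)))
  expect_error(sim_imaging_params(n_timepoints = 10))
  expect_error(sim_imaging_params(noise_sd = 0))
  expect_error(sim_imaging_params(coupling = c(2)), "named")
  expect_error(sim_cohort_params(n_subjects = 1))
  expect_error(sim_cohort_params(censor_rate = 1))
  expect_error(sim_cohort_params(baseline_hazard = 0))
})

test_that("synthetic atlas has 7 disjoint two-component networks and lobes", {
  p <- small_params(seed = 2)
  atl <- make_atlas(p)
  lab <- atl$atlas$labels$data
  expect_equal(sort(unique(lab[lab != 0])), 1:7)
  # label image => disjoint by construction; every network has >= 2 nodes
  for (net in 1:7) {
    m <- volume_image(array(as.numeric(lab == net), dim(lab)),
                      atl$atlas$labels$transform, "binary-mask")
    expect_gte(max(label_components(m)$data), 2)
    expect_true(all(lab[m$data != 0] == net))
  }
  # parcels are inside the brain
  expect_true(all(atl$brain_mask$data[lab != 0] == 1))
  # lobe template partitions the brain into >= 4 labels
  lobes <- atl$lobe_template$data
  expect_true(all((lobes != 0) == (atl$brain_mask$data != 0)))
  expect_gte(length(unique(lobes[lobes != 0])), 4)
  # determinism
  atl2 <- make_atlas(p)
  expect_identical(atl$atlas$labels$data, atl2$atlas$labels$data)
  # sizing error on an impossibly small grid
  expect_error(make_atlas(sim_imaging_params(grid_shape = c(8, 8, 8))),
               "too small")
})

test_that("tumor overlaps its target parcel partially", {
  p <- small_params(seed = 3)
  atl <- make_atlas(p)
  tum <- simulate_tumor_mask(atl, p, "dorsal-attention")
  net <- atlas_network_mask(atl$atlas, "dorsal-attention")
  overlap <- sum(tum$data * net$data)
  expect_gt(overlap, 0)                       # overlaps the parcel
  expect_lt(overlap, sum(net$data))           # ... but not all of it
  expect_gt(sum(tum$data) - overlap, 0)       # ... and extends beyond it
  expect_true(all(atl$brain_mask$data[tum$data != 0] == 1))
})

test_that("BOLD generator plants recoverable signals", {
  p <- small_params(seed = 5, coupling = c("visual" = 2))
  atl <- make_atlas(p)
  tum <- simulate_tumor_mask(atl, p, "visual")
  sim <- simulate_bold(atl, tum, p)
  expect_equal(dim(sim$bold$data), c(p$grid_shape, p$n_timepoints))
  expect_equal(unname(sim$truth$coupling), c(2, rep(0, 6)))
  # latent courses are unit variance, near zero mean, bandlimited
  s <- sim$truth$signals
  expect_equal(apply(s, 2, sd), rep(1, 7))
  expect_lt(max(abs(colMeans(s))), 1e-10)
  # voxels outside the brain carry no signal
  expect_equal(max(abs(sim$bold$data[rep(atl$brain_mask$data == 0,
                                         p$n_timepoints)])), 0)
  # determinism
  sim2 <- simulate_bold(atl, tum, p)
  expect_identical(sim$bold$data, sim2$bold$data)
  expect_error(simulate_bold(atl, empty_mask(p$grid_shape), p), "empty")
})

test_that("noiseless coupling makes the tumor mean exactly proportional to s1", {
  p <- small_params(seed = 6, coupling = c("visual" = 2))
  p$noise_sd <- 1e-12                      # noiseless limit
  atl <- make_atlas(p)
  tum <- simulate_tumor_mask(atl, p, "visual")
  sim <- simulate_bold(atl, tum, p)
  tum_mean <- seed_timeseries(sim$bold, tum)
  expect_equal(tum_mean, 2 * sim$truth$signals[, 1], tolerance = 1e-6)
})

test_that("with zero coupling the tumor mean is uncorrelated with every network", {
  # Monte-Carlo null over many seeds: the mean sample correlation between the
  # tumor signal and each latent course vanishes
  nseed <- 40
  p0 <- small_params()
  rbar <- matrix(NA_real_, nseed, 7)
  for (s in seq_len(nseed)) {
    p <- small_params(seed = 1000 + s)
    atl <- make_atlas(p)
    tum <- simulate_tumor_mask(atl, p)
    sim <- simulate_bold(atl, tum, p)
    tm <- seed_timeseries(sim$bold, tum)
    rbar[s, ] <- cor(tm, sim$truth$signals)
  }
  # mean over seeds is within 3 SE of zero for each network (T_eff ~ 39)
  se <- 1 / sqrt(39 * nseed)
  expect_true(all(abs(colMeans(rbar)) < 3.5 * se + 0.01))
  # and individual correlations are null-scale, not signal-scale
  expect_lt(mean(abs(rbar)), 3 / sqrt(39))
})

test_that("PET generator inverts TBR standardization", {
  p <- small_params(seed = 8)
  atl <- make_atlas(p)
  tum <- simulate_tumor_mask(atl, p)
  pet <- simulate_pet(tum, atl$brain_mask, 2.0, p)
  # noiseless: TBR exactly 1 outside tumor, 2 inside (round trip tested
  # against the lesion module)
  tbr <- standardize_tbr(pet, atl$brain_mask, tum)
  expect_equal(unique(tbr$data[atl$brain_mask$data != 0 & tum$data == 0]), 1.0)
  seg <- segment_pet(tbr, 1.6)
  expect_identical(seg$mask$data, tum$data)
  # no hotspot: nothing segmented
  flat <- simulate_pet(tum, atl$brain_mask, 1.0, p)
  tbr1 <- standardize_tbr(flat, atl$brain_mask, tum)
  expect_warning(seg1 <- segment_pet(tbr1, 1.6))
  expect_equal(seg1$volume_ml, 0)
  expect_error(simulate_pet(tum, atl$brain_mask, -1, p), "> 0")
})

test_that("structural masks respect their containment relations", {
  p <- small_params(seed = 9)
  atl <- make_atlas(p)
  tum <- simulate_tumor_mask(atl, p)
  st <- simulate_structural_masks(tum, atl$brain_mask, p, cavity_prob = 1)
  dil1 <- dilate_mask(tum, 1)
  expect_true(all(dil1$data[st$ce_mask$data != 0] == 1))   # CE inside dilation
  expect_true(all(st$flair_mask$data[tum$data != 0] == 1)) # FLAIR covers tumor
  expect_gte(sum(st$flair_mask$data), sum(st$ce_mask$data))
  expect_gt(sum(st$cavity_mask$data), 0)
  st0 <- simulate_structural_masks(tum, atl$brain_mask, p, cavity_prob = 0)
  expect_equal(sum(st0$cavity_mask$data), 0)
  # composite union dominates each input
  seg <- compose_lesion(tum, st$ce_mask, st$flair_mask, st$cavity_mask)
  for (nm in c("pet_mask", "ce_mask", "flair_mask", "cavity_mask"))
    expect_gte(sum(seg$composite$data), sum(seg[[nm]]$data))
})

test_that("cohort generator plants a proportional-hazards survival model", {
  cp <- sim_cohort_params(n_subjects = 150, censor_rate = 0, seed = 3)
  sim <- simulate_cohort(cp)
  ch <- sim$cohort
  expect_equal(nrow(ch), 150)
  expect_true(all(ch$event == 1))                 # censor_rate 0
  expect_true(all(ch$os_months > 0))
  expect_equal(anyDuplicated(ch$id), 0)
  # determinism
  expect_identical(simulate_cohort(cp)$cohort, ch)
  # censoring fraction roughly matches the target
  cpc <- sim_cohort_params(n_subjects = 400, censor_rate = 0.4, seed = 4)
  frac <- 1 - mean(simulate_cohort(cpc)$cohort$event)
  expect_gt(frac, 0.25); expect_lt(frac, 0.55)
  # extreme censoring warns but still returns a table
  cpx <- sim_cohort_params(n_subjects = 5, censor_rate = 0.999, seed = 5)
  expect_warning(simx <- simulate_cohort(cpx), "censored")
  expect_equal(nrow(simx$cohort), 5)
})

test_that("null cohorts give nominal type-I error for the univariate Cox test", {
  # beta = 0 everywhere: the Wald test on one FC covariate rejects at the
  # nominal 5% rate
  nrep <- 300
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    cp <- sim_cohort_params(n_subjects = 100,
                            log_hr_per_unit_fc = setNames(rep(0, 7),
                                                          names(network_names())),
                            covariate_spec = list(), censor_rate = 0.2,
                            seed = 5000 + r)
    ch <- simulate_cohort(cp)$cohort
    fit <- cox_fit(ch, "fc_dan")
    rej[r] <- fit$p_wald < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("planted log hazard ratios are recovered on average", {
  nrep <- 60
  est <- numeric(nrep)
  beta <- log(0.90)
  for (r in seq_len(nrep)) {
    cp <- sim_cohort_params(n_subjects = 400,
                            log_hr_per_unit_fc =
                              setNames(c(0, 0, beta, 0, 0, 0, 0),
                                       names(network_names())),
                            covariate_spec = list(), censor_rate = 0,
                            seed = 7000 + r)
    ch <- simulate_cohort(cp)$cohort
    est[r] <- cox_fit(ch, "fc_dan")$coef
  }
  expect_lt(abs(median(est) - beta), 0.03)
})

test_that("subjects written to NIfTI read back identically", {
  p <- small_params(seed = 13, coupling = c("limbic" = 1))
  s <- simulate_subject(p, subject_id = 1)
  dir <- file.path(tempdir(), "subj01")
  write_subject(s, dir)
  s2 <- read_subject(dir, repetition_time = p$repetition_time)
  expect_equal(s2$bold$data, s$bold$data, tolerance = 1e-6)
  expect_equal(s2$pet$data, s$pet$data, tolerance = 1e-6)
  expect_identical(s2$ce_mask$data, s$ce_mask$data)
  expect_identical(s2$atlas$labels$data + 0L,
                   s$atlas$labels$data + 0L)
  unlink(dir, recursive = TRUE)
})
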