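# The phantom generator is checked against independent closed-form peak
# evaluation, Monte-Carlo convergence, layout counting and determinism.

test_that("zero-noise spectra equal an independently evaluated peak sum", {
  cfg <- phantom_config(noise_sd = 0)
  ppm <- ppm_values(cfg$axis)
  for (cl in c("N", "T", "R")) {
    sig <- cfg$signatures[[cl]]
    # independent direct evaluation (no shared code path beyond arithmetic)
    expected <- cfg$baseline_amplitude *
      exp(-(ppm - 2.25)^2 / (2 * 1.5^2))
    for (i in seq_len(nrow(sig$peaks))) {
      hw <- sig$peaks$linewidth[i] / 2
      expected <- expected + sig$mean_amp[i] *
        hw^2 / ((ppm - sig$peaks$center[i])^2 + hw^2)
    }
    got <- mrsinet:::signature_profile(sig, cfg)
    expect_equal(got, expected, tolerance = 1e-12)
    # and the zero-noise class mean equals it too
    expect_equal(class_mean_spectrum(cl, cfg), expected, tolerance = 1e-12)
  }
})

test_that("class signatures reproduce the expected metabolite contrasts", {
  cfg <- phantom_config(noise_sd = 0)
  # no amplitude spread: spectra are the deterministic peak sums
  for (cl in names(cfg$signatures)) cfg$signatures[[cl]]$sd_amp[] <- 0
  ppm <- ppm_values(cfg$axis)
  sN <- generate_spectrum("N", cfg, 1)
  expect_true(min(abs(ppm[which.max(sN)] - c(3.04, 2.02))) <= 0.05)
  sT <- generate_spectrum("T", cfg, 1)
  expect_gt(sT[ppm_index(cfg$axis, 1.34)], sT[ppm_index(cfg$axis, 2.02)])
  sR <- generate_spectrum("R", cfg, 1)
  expect_gt(sR[ppm_index(cfg$axis, 3.54)], sT[ppm_index(cfg$axis, 3.54)])
  expect_error(generate_spectrum("Q", cfg, 1), class = "mrsinet_class_error")
})

test_that("Monte-Carlo mean of noisy spectra converges to the zero-noise form", {
  cfg <- phantom_config(noise_sd = 0.02)
  for (cl in names(cfg$signatures)) cfg$signatures[[cl]]$sd_amp[] <- 0
  truth <- class_mean_spectrum("T", cfg)
  seeds <- mrsinet:::child_seeds(2024, 1000)
  acc <- rep(0, cfg$axis$n_points)
  for (s in seeds) acc <- acc + generate_spectrum("T", cfg, s)
  dev <- abs(acc / 1000 - truth)
  # per-point 3-sigma band: ~99.7% of the 692 points should fall inside it,
  # and the largest excursion must stay within the 5-sigma envelope
  se <- cfg$noise_sd / sqrt(1000)
  expect_gte(mean(dev < 3 * se), 0.99)
  expect_lt(max(dev), 5 * se)
})

test_that("nearest-centroid separates zero-noise classes perfectly", {
  cfg <- phantom_config(noise_sd = 0)
  x <- t(vapply(c("N", "T", "R"), function(cl)
    ul2_normalize(class_mean_spectrum(cl, cfg)), numeric(692)))
  seeds <- mrsinet:::child_seeds(7, 30)
  cls <- sample(c("N", "T", "R"), 30, replace = TRUE)
  draws <- ul2_normalize(t(mapply(function(cl, s)
    generate_spectrum(cl, cfg, s), cls, seeds)))
  pred <- rownames(x)[apply(draws, 1, function(s)
    which.min(colSums((t(x) - s)^2)))]
  expect_equal(pred, cls)
})

test_that("grid layouts produce the expected label geometry", {
  cfg <- phantom_config(tumour_layout = tumour_layout(radius = 2),
                        unknown_rim_width = 1)
  g <- generate_grid(cfg, seed = 3)
  expect_equal(sum(g$labels == "unknown"), 36)   # border of a 10x10 grid
  rr <- rep(0:9, each = 10); cc <- rep(0:9, times = 10)
  in_disc <- sqrt((rr - 4.5)^2 + (cc - 4.5)^2) <= 2
  expect_equal(g$labels == "T", in_disc)         # disc inside the rim
  expect_true(all(g$labels[!in_disc] %in% c("N", "unknown")))

  mixed <- generate_grid(cfg, seed = 3,
                         layout = tumour_layout(radius = 2.5,
                                                responding_radius = 1.25))
  expect_true(all(which(mixed$labels == "R") %in%
                  which(sqrt((rr - 4.5)^2 + (cc - 4.5)^2) <= 2.5)))
  expect_true(sum(mixed$labels == "R") >= 1)

  expect_error(generate_grid(cfg, layout = tumour_layout(c(1, 1), 4)),
               class = "mrsinet_config_error")
  # identical seeds give identical grids
  expect_identical(generate_grid(cfg, seed = 5), generate_grid(cfg, seed = 5))
  # tumour-free layout: all labelled voxels are normal
  g0 <- generate_grid(cfg, seed = 5, layout = NULL)
  expect_true(all(g0$labels %in% c("N", "unknown")))
})

test_that("cohort composition, label vocabularies and determinism hold", {
  cfg <- phantom_config()
  coh <- generate_cohort(2, 2, 1, 3, cfg, seed = 11)
  expect_equal(length(coh$subjects), 5)
  n_grids <- vapply(coh$subjects, function(s) length(s$grids), 0L)
  expect_equal(sum(n_grids == 1), 4)   # single-point subjects
  expect_equal(sum(n_grids == 3), 1)   # the longitudinal subject
  expect_false(anyDuplicated(subject_ids(coh)) > 0)
  for (s in coh$subjects) {
    labs <- unique(unlist(lapply(s$grids, `[[`, "labels")))
    if (s$condition == "control")
      expect_true(all(labs %in% c("N", "T", "unknown")))
    if (s$condition == "treated")
      expect_true(all(labs %in% c("N", "R", "unknown")))
    if (s$condition == "longitudinal") {
      # trajectory: unresponsive, then responding, then mixed relapse
      l1 <- unique(s$grids[[1]]$labels); l3 <- unique(s$grids[[3]]$labels)
      expect_true("T" %in% l1 && !"R" %in% l1)
      expect_true("R" %in% unique(s$grids[[2]]$labels))
      expect_true(all(c("T", "R") %in% l3))
      expect_equal(vapply(s$grids, `[[`, 0L, "day"), c(10L, 12L, 14L))
    }
  }
  coh2 <- generate_cohort(2, 2, 1, 3, cfg, seed = 11)
  expect_identical(lapply(coh$subjects, function(s)
    lapply(s$grids, `[[`, "labels")),
    lapply(coh2$subjects, function(s) lapply(s$grids, `[[`, "labels")))
  # single longitudinal subject: grids share the subject identifier
  solo <- generate_cohort(0, 0, 1, 3, cfg, seed = 2)
  expect_equal(length(solo$subjects), 1)
  expect_equal(unique(vapply(solo$subjects[[1]]$grids, `[[`, "", "subject_id")),
               solo$subjects[[1]]$id)
})
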