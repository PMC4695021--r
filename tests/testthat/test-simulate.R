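# Ground-truth generators: clone-model read counts, microsatellite
# read-length observations, segmented depth profiles.

test_that("identical config and seed reproduce identical output", {
  cfg <- simulation_config("stepwise", seed = 7L)
  expect_identical(simulate_lesion_pair(cfg), simulate_lesion_pair(cfg))
  mcfg <- msi_simulation_config(n_null_loci = 20, n_msi_loci = 5,
                                reads_per_locus = 10, seed = 3L)
  expect_identical(simulate_msi_observations(mcfg),
                   simulate_msi_observations(mcfg))
  expect_identical(
    simulate_depth_profile(100, 50L, c(0, 1), noise_sd = 3, seed = 5L),
    simulate_depth_profile(100, 50L, c(0, 1), noise_sd = 3, seed = 5L))
  # and a different seed changes the draw
  expect_false(identical(simulate_lesion_pair(cfg),
                         simulate_lesion_pair(simulation_config("stepwise",
                                                                seed = 8L))))
})

test_that("per-class MAF means follow the purity * ccf / 2 model", {
  # parallel: clonal mean MAF ~= rho / 2 = 0.375 in both lesions
  cfg <- simulation_config("parallel", n_clonal = 2000,
                           n_adenoma_specific = 500,
                           n_carcinoma_specific = 500,
                           outlier_fraction = 0, mean_depth = 200, seed = 11L)
  sim <- simulate_lesion_pair(cfg)
  maf_a <- with(sim$variants, alt_adenoma / (ref_adenoma + alt_adenoma))
  maf_c <- with(sim$variants, alt_carcinoma / (ref_carcinoma + alt_carcinoma))
  clonal <- sim$truth$true_class == "clonal"
  se <- sqrt(0.375 * 0.625 / (2000 * 200))
  expect_lt(abs(mean(maf_a[clonal]) - 0.375), 3 * se)
  expect_lt(abs(mean(maf_c[clonal]) - 0.375), 3 * se)
  # lesion-specific classes are absent from the other lesion
  aden <- sim$truth$true_class == "adenoma_specific"
  expect_equal(max(maf_c[aden]), 0)

  # stepwise intermediate: expected MAF (rho*f/2, rho/2) = (0.1125, 0.375)
  scfg <- simulation_config("stepwise", n_clonal = 500,
                            n_adenoma_specific = 500,
                            n_carcinoma_specific = 500,
                            stepwise_subclone_fraction = 0.3,
                            outlier_fraction = 0, mean_depth = 1000,
                            seed = 13L)
  ssim <- simulate_lesion_pair(scfg)
  st <- ssim$truth$true_class == "stepwise_intermediate"
  expect_equal(sum(st), 500L)
  smaf_a <- with(ssim$variants, alt_adenoma / (ref_adenoma + alt_adenoma))
  smaf_c <- with(ssim$variants, alt_carcinoma / (ref_carcinoma + alt_carcinoma))
  se_a <- sqrt(0.1125 * (1 - 0.1125) / (500 * 1000))
  se_c <- sqrt(0.375 * 0.625 / (500 * 1000))
  expect_lt(abs(mean(smaf_a[st]) - 0.1125), 3 * se_a)
  expect_lt(abs(mean(smaf_c[st]) - 0.375), 3 * se_c)
})

test_that("truth labels partition the variants and respect the model", {
  cfg <- simulation_config("parallel", seed = 2L, outlier_fraction = 0.02)
  sim <- simulate_lesion_pair(cfg)
  n_core <- cfg$n_clonal + cfg$n_adenoma_specific + cfg$n_carcinoma_specific
  expect_equal(nrow(sim$variants), n_core + round(0.02 * n_core))
  expect_setequal(sim$truth$variant_id, sim$variants$id)
  expect_false(anyDuplicated(sim$truth$variant_id) > 0)
  # no stepwise_intermediate class under the parallel model
  expect_false("stepwise_intermediate" %in% sim$truth$true_class)
  # stepwise model emits it
  ssim <- simulate_lesion_pair(simulation_config("stepwise", seed = 2L))
  expect_true("stepwise_intermediate" %in% ssim$truth$true_class)
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(purity_adenoma = 1.2), "purity_adenoma")
  expect_error(simulation_config("stepwise", stepwise_subclone_fraction = 1),
               "stepwise_subclone_fraction")
  expect_error(simulation_config(n_clonal = -5), "n_clonal")
  expect_error(simulation_config(outlier_fraction = 1), "outlier_fraction")
})

test_that("msi simulation without stutter is degenerate at the truth", {
  cfg <- msi_simulation_config(n_null_loci = 3, n_msi_loci = 2,
                               reads_per_locus = 1000, stutter_prob = 0,
                               msi_shift = -3L, seed = 9L)
  sim <- simulate_msi_observations(cfg)
  for (lid in sim$truth$locus_id[!sim$truth$is_msi]) {
    L <- sim$loci$tract_length[sim$loci$locus_id == lid]
    lens <- sim$lengths$length[sim$lengths$locus_id == lid]
    expect_true(all(lens == L))  # both samples degenerate at L
  }
  for (lid in sim$truth$locus_id[sim$truth$is_msi]) {
    L <- sim$loci$tract_length[sim$loci$locus_id == lid]
    tum <- sim$lengths$length[sim$lengths$locus_id == lid &
                                sim$lengths$sample == "tumor"]
    expect_setequal(unique(tum), c(L, L - 3L))
    # mixture weight ~ 0.5: binomial(1000, .5) within 4 sd
    expect_lt(abs(mean(tum == L - 3L) - 0.5), 4 * sqrt(0.25 / 1000))
  }
})

test_that("depth profile encodes the requested step structure", {
  bins <- simulate_depth_profile(500, 250L, c(0, 1), noise_sd = 0, seed = 1L)
  ratio <- bins$depth_tumor / bins$depth_normal
  expect_equal(ratio[1:250], rep(1, 250), tolerance = 1e-12)
  expect_equal(ratio[251:500], rep(2, 250), tolerance = 1e-12)

  flat <- simulate_depth_profile(200, integer(0), 0, noise_sd = 1, seed = 2L)
  lr <- log2(flat$depth_tumor / flat$depth_normal)
  expect_lt(max(abs(lr)), 0.1)

  expect_error(simulate_depth_profile(100, c(50L, 40L), c(0, 1, 0)),
               "strictly increasing")
  expect_error(simulate_depth_profile(100, 100L, c(0, 1)),
               "strictly increasing")
  expect_error(simulate_depth_profile(100, 50L, c(0, 1, 2)), "length")
})

test_that("gc_effect applies an identical recorded bias to both samples", {
  on <- simulate_depth_profile(300, 150L, c(0, 0.8), noise_sd = 0,
                               gc_effect = TRUE, seed = 4L)
  off <- simulate_depth_profile(300, 150L, c(0, 0.8), noise_sd = 0,
                                gc_effect = FALSE, seed = 4L)
  bias <- attr(on, "gc_bias")
  expect_equal(on$depth_normal, off$depth_normal * bias, tolerance = 1e-10)
  expect_equal(on$depth_tumor, off$depth_tumor * bias, tolerance = 1e-10)
  # the bias cancels in the tumor/normal ratio by construction
  expect_equal(on$depth_tumor / on$depth_normal,
               off$depth_tumor / off$depth_normal, tolerance = 1e-10)
})
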