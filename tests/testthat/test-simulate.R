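test_that("the linear reporter map assigns luciferases per arm orientation", {
  v1 <- psi_to_luminescence(50, "V1")
  expect_equal(v1$fluc, 0.5)
  expect_equal(v1$nluc, 0.5)
  # at the V1 baseline of 42 PSI, inclusion-linked Firefly reads 0.42
  v1b <- psi_to_luminescence(42, "V1")
  expect_equal(v1b$fluc, 0.42)
  expect_equal(v1b$nluc, 0.58)
  # unequal gains scale each luciferase independently
  v1g <- psi_to_luminescence(75, "V1", gains = c(incl = 2, skip = 1))
  expect_equal(v1g$fluc, 1.5)
  expect_equal(v1g$nluc, 0.25)
  # V2 swaps the luciferase assignment
  v2 <- psi_to_luminescence(42, "V2")
  expect_equal(v2$nluc, 0.42)
  expect_error(psi_to_luminescence(0, "V1"), "degenerate")
  expect_error(psi_to_luminescence(100, "V1"), "degenerate")
})

test_that("simulation is deterministic and hierarchical in the seed", {
  cfg <- small_config()
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a, b)

  # adding plates never perturbs earlier plates' draws
  cfg3 <- small_config(n_plates_per_arm = 3L)
  c3 <- simulate_screen(cfg3)
  first_two <- c3$dataset[c3$dataset$plate_id %in% c("P01", "P02"), ]
  expect_equal(tibble::as_tibble(first_two), tibble::as_tibble(a$dataset))

  # a different seed changes the data
  d <- simulate_screen(simulation_config(seed = 8, n_plates_per_arm = 2L))
  expect_false(identical(a$dataset$nluc, d$dataset$nluc))

  # and the generator leaves the caller's RNG stream untouched
  set.seed(123); before <- .Random.seed
  invisible(simulate_screen(cfg))
  expect_identical(.Random.seed, before)
})

test_that("ground truth covers every sample compound exactly once", {
  cfg <- small_config()
  sim <- simulate_screen(cfg)
  samples <- unique(sim$dataset$compound_id[sim$dataset$role == "sample"])
  expect_setequal(sim$truth$compound_id, samples)
  expect_equal(anyDuplicated(sim$truth$compound_id), 0L)
  expect_true(all(sim$truth$label %in%
                    c("activator", "inhibitor", "unidirectional_artifact",
                      "inert")))
  # every compound is plated once per arm, in the same well
  per_arm <- table(sim$dataset$compound_id[sim$dataset$role == "sample"],
                   sim$dataset$arm[sim$dataset$role == "sample"])
  expect_true(all(per_arm == 1))
})

test_that("a zero-noise, zero-effect screen is flat and yields no hits", {
  cfg <- small_config(frac_activators = 0, frac_inhibitors = 0,
                      frac_unidirectional = 0, noise_cv = 0,
                      row_effect_sd = 0, col_effect_sd = 0)
  sim <- simulate_screen(cfg)
  v1 <- sim$dataset[sim$dataset$arm == "V1" & sim$dataset$role == "sample", ]
  ratio <- v1$fluc / v1$nluc
  expect_equal(ratio, rep(0.42 / 0.58, nrow(v1)), tolerance = 1e-12)

  # flat plates are degenerate for B-scoring: recorded per plate, no hits
  norm <- normalize_screen(sim$dataset)
  expect_true(all(!norm$report$ok))
  calls <- call_hits(norm)
  expect_equal(nrow(calls), 0)
})

test_that("noise-free modulators shift both arms' ratios reciprocally", {
  # with equal baselines the two arms' ratio fold changes agree exactly
  cfg <- small_config(baseline_psi = c(V1 = 40, V2 = 40), noise_cv = 0,
                      row_effect_sd = 0, col_effect_sd = 0,
                      frac_activators = 0.3, frac_inhibitors = 0.3,
                      frac_unidirectional = 0)
  sim <- simulate_screen(cfg)
  wells <- tibble::as_tibble(sim$dataset)
  wells$ratio <- ifelse(wells$arm == "V1", wells$fluc / wells$nluc,
                        wells$nluc / wells$fluc)
  base <- 40 / 60
  mod <- sim$truth$compound_id[sim$truth$label %in%
                                 c("activator", "inhibitor")]
  v1 <- wells[wells$arm == "V1" & wells$compound_id %in% mod, ]
  v2 <- wells[wells$arm == "V2" & wells$compound_id %in% mod, ]
  v2 <- v2[match(v1$compound_id, v2$compound_id), ]
  expect_equal(v1$ratio / base, v2$ratio / base, tolerance = 1e-12)

  # under the default unequal baselines the shifts stay concordant
  cfg2 <- small_config(noise_cv = 0, row_effect_sd = 0, col_effect_sd = 0,
                       frac_activators = 0.3, frac_inhibitors = 0.3,
                       frac_unidirectional = 0)
  sim2 <- simulate_screen(cfg2)
  w2 <- tibble::as_tibble(sim2$dataset)
  w2$ratio <- ifelse(w2$arm == "V1", w2$fluc / w2$nluc, w2$nluc / w2$fluc)
  mods2 <- sim2$truth[sim2$truth$label %in% c("activator", "inhibitor"), ]
  shift <- function(arm, base_psi) {
    arm_wells <- w2[w2$arm == arm & w2$compound_id %in% mods2$compound_id, ]
    arm_wells <- arm_wells[match(mods2$compound_id, arm_wells$compound_id), ]
    log(arm_wells$ratio / (base_psi / (100 - base_psi)))
  }
  expect_true(all(sign(shift("V1", 42)) == sign(shift("V2", 33))))
})

test_that("artifacts are unidirectional and anti-concordant across arms", {
  cfg <- small_config(noise_cv = 0, row_effect_sd = 0, col_effect_sd = 0,
                      frac_activators = 0, frac_inhibitors = 0,
                      frac_unidirectional = 0.5)
  sim <- simulate_screen(cfg)
  w <- tibble::as_tibble(sim$dataset)
  art <- sim$truth[sim$truth$label == "unidirectional_artifact", ]
  v1 <- w[w$arm == "V1", ]; v2 <- w[w$arm == "V2", ]
  v1 <- v1[match(art$compound_id, v1$compound_id), ]
  v2 <- v2[match(art$compound_id, v2$compound_id), ]
  shift_v1 <- log(v1$fluc / v1$nluc) - log(0.42 / 0.58)
  shift_v2 <- log(v2$nluc / v2$fluc) - log(0.33 / 0.67)
  expect_true(all(sign(shift_v1) == -sign(shift_v2)))
  expect_equal(abs(shift_v1), abs(art$log2fc) * log(2), tolerance = 1e-9)
})

test_that("dilution series reflect ground truth through the dose curve", {
  cfg <- simulation_config(seed = 12, noise_cv = 0.02)
  truth <- tibble::tibble(
    compound_id = c("act", "inert", "art"),
    label = c("activator", "inert", "unidirectional_artifact"),
    dpsi = c(20, NA, NA), log2fc = c(NA, NA, 1.5),
    artifact_target = c(NA, NA, "fluc")
  )
  dil <- simulate_dilution(truth, cfg)
  expect_equal(nrow(dil), 30)

  res <- validate_dilutions(dil, effect_threshold = 0.5)
  expect_true(res$validated[res$compound_id == "act"])
  expect_false(res$validated[res$compound_id == "inert"])
  # activator with EC50 = 1 uM and dPSI = 20 acts by 2.5 uM at the latest
  expect_lte(res$min_effective[res$compound_id == "act"], 2.5e-6)

  # artifact: strong change in the targeted luciferase only
  art <- dil[dil$compound_id == "art", ]
  top <- art[which.max(art$concentration), ]
  expect_gt(top$rel_fluc, 2)             # 2^1.5 at saturation, ~2.7
  expect_lt(abs(log2(top$rel_nluc)), 0.3)  # untargeted luciferase ~flat
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(frac_activators = 0.6, frac_inhibitors = 0.5),
               "sum to at most 1")
  expect_error(simulation_config(baseline_psi = c(V1 = 0, V2 = 33)),
               "strictly inside")
  layout <- default_plate_layout()
  layout$role <- "neg_control"
  expect_error(simulation_config(layout = layout), "infeasible layout")
})
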