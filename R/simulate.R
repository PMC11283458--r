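## Synthetic dual-reporter screen generator with ground-truth labels.
##
## Emulates 384-well plates of the reciprocal V1/V2 reporter cell lines:
## DMSO negative controls, HDAC-inhibitor-like positive controls, true
## splicing modulators that shift PSI identically in both arms (reciprocal
## signature), unidirectional single-luciferase artifacts that multiply
## exactly one luciferase in both arms (non-reciprocal signature),
## additive row/column spatial offsets on the ratio scale, and
## multiplicative log-normal luminescence noise.

#' Default 384-well control layout
#'
#' Columns 1-2 are reserved for controls: 16 DMSO wells (column 1),
#' 8 TSA-like and 8 Scriptaid-like positive-control wells (column 2),
#' leaving 352 sample wells.
#'
#' @return Tibble with columns `row`, `col` (0-based), `role`, `control`.
#' @export
default_plate_layout <- function() {
  grid <- tidyr::expand_grid(row = 0:(PLATE_NROW - 1L),
                             col = 0:(PLATE_NCOL - 1L))
  grid$role <- "sample"
  grid$control <- NA_character_
  grid$role[grid$col == 0L] <- "neg_control"
  grid$control[grid$col == 0L] <- "dmso"
  grid$role[grid$col == 1L] <- "pos_control"
  grid$control[grid$col == 1L & grid$row <= 7L] <- "tsa"
  grid$control[grid$col == 1L & grid$row >= 8L] <- "scriptaid"
  grid
}

#' Simulation configuration
#'
#' Study conditions for the synthetic screen. Defaults reproduce the
#' screening conditions the pipeline is designed for: baseline reporter
#' PSI of 42 (V1) and 33 (V2), 10 plates per arm with 352 sample wells
#' each (3,520 compounds), 5% activators and 5% inhibitors with
#' `dPSI ~ N(+/-20, 5)`, 5% unidirectional artifacts with
#' `log2FC ~ N(+/-1.5, 0.3)` on a single luciferase, 10% CV log-normal
#' luminescence noise, and additive row/column offsets on the ratio scale
#' with SD equal to 10% of the arm's baseline ratio.
#'
#' @param seed Integer master seed; every random draw derives from it.
#' @param n_plates_per_arm Number of plate pairs (each plate exists in
#'   both arms with the same compounds in the same wells).
#' @param layout Control layout tibble, see [default_plate_layout()].
#' @param baseline_psi Named vector `c(V1 = , V2 = )` of baseline percent
#'   spliced-in (strictly inside (0, 100)).
#' @param frac_activators,frac_inhibitors,frac_unidirectional Fractions of
#'   sample compounds in each ground-truth class (must sum to <= 1; the
#'   remainder is inert).
#' @param effect_dpsi_mean,effect_dpsi_sd Mean/SD of the true-modulator
#'   |dPSI| (activators drawn positive, inhibitors negative).
#' @param artifact_log2fc_mean,artifact_log2fc_sd Mean/SD of the artifact
#'   |log2 fold change| applied to one luciferase in both arms; sign and
#'   target luciferase are drawn per compound.
#' @param row_effect_sd,col_effect_sd SDs of the additive per-plate
#'   row/column offsets, as fractions of the arm's baseline ratio.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise applied independently to each luciferase signal.
#' @param pos_control_dpsi Named vector `c(tsa = , scriptaid = )` of
#'   positive-control dPSI (both HDAC-inhibitor-like microexon
#'   activators).
#' @param gains Named vector `c(incl = , skip = )` of luciferase gains in
#'   the linear PSI-to-luminescence map.
#' @param counts_scale Overall luminescence counts scale.
#' @param sample_concentration Screening concentration recorded for sample
#'   wells (molar; default 4 uM).
#' @param ec50 Half-maximal concentration of the saturating dose curve
#'   used by [simulate_dilution()] (molar).
#' @param spatial_scale `"ratio"` (default) adds the row/column offsets on
#'   the luminescence-ratio scale — the structure an additive median
#'   polish removes; `"log_luminescence"` instead applies them
#'   multiplicatively to the numerator luciferase, a deliberate model
#'   mismatch for stress testing.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_plates_per_arm = 10L,
                              layout = default_plate_layout(),
                              baseline_psi = c(V1 = 42, V2 = 33),
                              frac_activators = 0.05,
                              frac_inhibitors = 0.05,
                              frac_unidirectional = 0.05,
                              effect_dpsi_mean = 20,
                              effect_dpsi_sd = 5,
                              artifact_log2fc_mean = 1.5,
                              artifact_log2fc_sd = 0.3,
                              row_effect_sd = 0.10,
                              col_effect_sd = 0.10,
                              noise_cv = 0.10,
                              pos_control_dpsi = c(tsa = 25, scriptaid = 20),
                              gains = c(incl = 1, skip = 1),
                              counts_scale = 1e6,
                              sample_concentration = 4e-6,
                              ec50 = 1e-6,
                              spatial_scale = c("ratio", "log_luminescence")) {
  spatial_scale <- match.arg(spatial_scale)
  fracs <- c(frac_activators, frac_inhibitors, frac_unidirectional)
  if (any(fracs < 0) || sum(fracs) > 1) {
    abort("class fractions must be non-negative and sum to at most 1")
  }
  if (any(baseline_psi <= 0) || any(baseline_psi >= 100)) {
    abort("baseline PSI must lie strictly inside (0, 100)")
  }
  if (!all(c("V1", "V2") %in% names(baseline_psi))) {
    abort("baseline_psi needs named entries V1 and V2")
  }
  if (noise_cv < 0) abort("noise_cv must be non-negative")
  n_controls <- sum(layout$role != "sample")
  if (n_controls >= PLATE_NROW * PLATE_NCOL) {
    abort("infeasible layout: controls fill the whole plate")
  }
  structure(list(
    seed = as.integer(seed), n_plates_per_arm = as.integer(n_plates_per_arm),
    layout = layout, baseline_psi = baseline_psi,
    frac_activators = frac_activators, frac_inhibitors = frac_inhibitors,
    frac_unidirectional = frac_unidirectional,
    effect_dpsi_mean = effect_dpsi_mean, effect_dpsi_sd = effect_dpsi_sd,
    artifact_log2fc_mean = artifact_log2fc_mean,
    artifact_log2fc_sd = artifact_log2fc_sd,
    row_effect_sd = row_effect_sd, col_effect_sd = col_effect_sd,
    noise_cv = noise_cv, pos_control_dpsi = pos_control_dpsi,
    gains = gains, counts_scale = counts_scale,
    sample_concentration = sample_concentration, ec50 = ec50,
    spatial_scale = spatial_scale
  ), class = "simulation_config")
}

#' Map reporter PSI to expected luciferase signals
#'
#' Linear map of the splicing reporter: the inclusion-linked luciferase
#' signal is `gain_incl * psi / 100` and the skipping-linked signal is
#' `gain_skip * (1 - psi / 100)`. For the V1 construct inclusion expresses
#' Firefly, for the reciprocal V2 construct inclusion expresses NanoLuc.
#'
#' @param psi Percent spliced-in, strictly inside (0, 100).
#' @param arm `"V1"` or `"V2"`.
#' @param gains Named vector `c(incl = , skip = )` of positive gains.
#' @return Tibble with columns `nluc`, `fluc`.
#' @export
#' @examples
#' psi_to_luminescence(42, "V1")  # fluc = 0.42, nluc = 0.58
psi_to_luminescence <- function(psi, arm = c("V1", "V2"),
                                gains = c(incl = 1, skip = 1)) {
  arm <- match.arg(arm)
  if (any(psi <= 0) || any(psi >= 100)) {
    abort("degenerate reporter pair: psi must lie strictly inside (0, 100)")
  }
  if (any(gains <= 0)) abort("gains must be positive")
  incl <- gains[["incl"]] * psi / 100
  skip <- gains[["skip"]] * (1 - psi / 100)
  if (arm == "V1") tibble(nluc = skip, fluc = incl)
  else tibble(nluc = incl, fluc = skip)
}

clamp_psi <- function(psi, lo = 1, hi = 99) pmin(pmax(psi, lo), hi)

ln_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

plate_substream_seed <- function(seed, k, stream = 0L) {
  as.integer((abs(as.numeric(seed)) + 7919 * k + 104729 * stream) %%
               2147483629)
}

## Evaluate an expression under a private RNG stream, leaving the global
## RNG state untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a complete two-arm reporter screen
#'
#' Generates `n_plates_per_arm` plate pairs: each compound occupies the
#' same well of the corresponding V1 and V2 plates. True modulators shift
#' reporter PSI identically in both arms; unidirectional artifacts
#' multiply exactly one luciferase's output in both arms; row/column
#' spatial offsets and log-normal noise are applied per plate. Random
#' draws are split hierarchically by plate pair, so adding plates never
#' perturbs earlier plates' data, and output is identical across runs
#' with the same configuration.
#'
#' @param config A [simulation_config()].
#' @return A list with `dataset` (a [screen_dataset()] covering both arms),
#'   `truth` (tibble: `compound_id`, `label`, `dpsi`, `log2fc`,
#'   `artifact_target`) and `spatial` (tibble of the injected per-plate
#'   row/column offsets: `arm`, `plate_id`, `kind`, `index`, `effect`).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  layout <- config$layout
  n_samples <- sum(layout$role == "sample")
  plates <- vector("list", config$n_plates_per_arm)
  truths <- vector("list", config$n_plates_per_arm)
  spatials <- vector("list", config$n_plates_per_arm)

  for (k in seq_len(config$n_plates_per_arm)) {
    sim <- with_seed(plate_substream_seed(config$seed, k),
                     simulate_plate_pair(config, k, layout, n_samples))
    plates[[k]] <- sim$wells
    truths[[k]] <- sim$truth
    spatials[[k]] <- sim$spatial
  }
  list(dataset = screen_dataset(dplyr::bind_rows(plates)),
       truth = dplyr::bind_rows(truths),
       spatial = dplyr::bind_rows(spatials))
}

simulate_plate_pair <- function(config, k, layout, n_samples) {
  plate_id <- sprintf("P%02d", k)
  first_id <- (k - 1L) * n_samples

  ## ground truth for this plate's sample compounds
  labels <- sample(c("activator", "inhibitor", "unidirectional_artifact",
                     "inert"),
                   size = n_samples, replace = TRUE,
                   prob = c(config$frac_activators, config$frac_inhibitors,
                            config$frac_unidirectional,
                            1 - config$frac_activators -
                              config$frac_inhibitors -
                              config$frac_unidirectional))
  dpsi <- rep(NA_real_, n_samples)
  dpsi[labels == "activator"] <-
    rnorm(sum(labels == "activator"),
          config$effect_dpsi_mean, config$effect_dpsi_sd)
  dpsi[labels == "inhibitor"] <-
    -rnorm(sum(labels == "inhibitor"),
           config$effect_dpsi_mean, config$effect_dpsi_sd)
  is_art <- labels == "unidirectional_artifact"
  log2fc <- rep(NA_real_, n_samples)
  log2fc[is_art] <- sample(c(-1, 1), sum(is_art), replace = TRUE) *
    rnorm(sum(is_art), config$artifact_log2fc_mean, config$artifact_log2fc_sd)
  artifact_target <- rep(NA_character_, n_samples)
  artifact_target[is_art] <- sample(c("nluc", "fluc"), sum(is_art),
                                    replace = TRUE)
  compound_id <- sprintf("C%05d", first_id + seq_len(n_samples))

  truth <- tibble(compound_id = compound_id, label = labels,
                  dpsi = dpsi, log2fc = log2fc,
                  artifact_target = artifact_target)

  ## per-well effect assignment shared by both arms
  well <- layout
  well$compound_id <- NA_character_
  well$compound_id[well$role == "sample"] <- compound_id
  well$compound_id[well$role == "neg_control"] <- "DMSO"
  well$compound_id[!is.na(well$control) & well$control == "tsa"] <- "TSA"
  well$compound_id[!is.na(well$control) & well$control == "scriptaid"] <-
    "Scriptaid"
  well_dpsi <- rep(0, nrow(well))
  well_dpsi[well$role == "sample"] <- ifelse(is.na(dpsi), 0, dpsi)
  well_dpsi[!is.na(well$control) & well$control == "tsa"] <-
    config$pos_control_dpsi[["tsa"]]
  well_dpsi[!is.na(well$control) & well$control == "scriptaid"] <-
    config$pos_control_dpsi[["scriptaid"]]
  well_log2fc <- rep(0, nrow(well))
  well_log2fc[well$role == "sample"] <- ifelse(is.na(log2fc), 0, log2fc)
  well_target <- rep(NA_character_, nrow(well))
  well_target[well$role == "sample"] <- artifact_target
  well_conc <- rep(NA_real_, nrow(well))
  well_conc[well$role == "sample"] <- config$sample_concentration
  well_conc[!is.na(well$control) & well$control == "tsa"] <- 200e-9
  well_conc[!is.na(well$control) & well$control == "scriptaid"] <- 4e-6

  arms <- lapply(c("V1", "V2"), function(arm) {
    simulate_plate_arm(config, arm, plate_id, well, well_dpsi,
                       well_log2fc, well_target, well_conc)
  })
  list(wells = dplyr::bind_rows(lapply(arms, `[[`, "wells")),
       truth = truth,
       spatial = dplyr::bind_rows(lapply(arms, `[[`, "spatial")))
}

simulate_plate_arm <- function(config, arm, plate_id, well, well_dpsi,
                               well_log2fc, well_target, well_conc) {
  base_psi <- config$baseline_psi[[arm]]
  base_lum <- psi_to_luminescence(base_psi, arm, config$gains)
  base_ratio <- if (arm == "V1") base_lum$fluc / base_lum$nluc
                else base_lum$nluc / base_lum$fluc
  n <- nrow(well)

  row_eff <- rnorm(PLATE_NROW, 0, config$row_effect_sd * base_ratio)
  col_eff <- rnorm(PLATE_NCOL, 0, config$col_effect_sd * base_ratio)
  spatial <- row_eff[well$row + 1L] + col_eff[well$col + 1L]

  psi_w <- clamp_psi(base_psi + well_dpsi)
  lum <- psi_to_luminescence(psi_w, arm, config$gains)
  nluc <- lum$nluc * config$counts_scale
  fluc <- lum$fluc * config$counts_scale

  art <- !is.na(well_target)
  mult <- 2^well_log2fc
  nluc[art & well_target == "nluc"] <- nluc[art & well_target == "nluc"] *
    mult[art & well_target == "nluc"]
  fluc[art & well_target == "fluc"] <- fluc[art & well_target == "fluc"] *
    mult[art & well_target == "fluc"]

  nluc <- nluc * ln_noise(n, config$noise_cv)
  fluc <- fluc * ln_noise(n, config$noise_cv)

  if (config$spatial_scale == "ratio") {
    ## distort the numerator so the recomputed ratio gains an additive offset
    if (arm == "V1") {
      ratio <- pmax(fluc / nluc + spatial, 1e-3 * base_ratio)
      fluc <- ratio * nluc
    } else {
      ratio <- pmax(nluc / fluc + spatial, 1e-3 * base_ratio)
      nluc <- ratio * fluc
    }
  } else {
    if (arm == "V1") fluc <- fluc * exp(spatial / base_ratio)
    else nluc <- nluc * exp(spatial / base_ratio)
  }

  list(
    wells = tibble(arm = arm, plate_id = plate_id,
                   row = well$row, col = well$col,
                   compound_id = well$compound_id, role = well$role,
                   nluc = nluc, fluc = fluc, concentration = well_conc),
    spatial = dplyr::bind_rows(
      tibble(arm = arm, plate_id = plate_id, kind = "row",
             index = 0:(PLATE_NROW - 1L), effect = row_eff),
      tibble(arm = arm, plate_id = plate_id, kind = "col",
             index = 0:(PLATE_NCOL - 1L), effect = col_eff)
    )
  )
}

#' Simulate secondary-screen serial dilution series
#'
#' Generates a V1-arm two-fold dilution series for each compound in a
#' ground-truth table. Effects follow a saturating dose curve with Hill
#' coefficient 1: at concentration `c` the fractional effect is
#' `c / (c + ec50)`, scaling the compound's true dPSI (modulators) or
#' log2 fold change (artifacts). Relative luminescence is reported
#' against the median of 16 simulated same-plate DMSO wells, with the
#' same log-normal noise model as the primary screen.
#'
#' @param truth Ground-truth tibble from [simulate_screen()] (or rows of
#'   it).
#' @param config A [simulation_config()].
#' @param concentrations Ascending molar concentrations; default the
#'   standard 10-point 40 nM-20 uM series.
#' @return Long tibble: `compound_id`, `arm`, `concentration`,
#'   `rel_nluc`, `rel_fluc`, `expected_direction`.
#' @export
simulate_dilution <- function(truth, config,
                              concentrations = dilution_concentrations()) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- as_tibble(truth)
  with_seed(plate_substream_seed(config$seed, 0L, stream = 7L), {
    out <- vector("list", nrow(truth))
    base_psi <- config$baseline_psi[["V1"]]
    base <- psi_to_luminescence(base_psi, "V1", config$gains)
    n_c <- length(concentrations)
    frac <- concentrations / (concentrations + config$ec50)
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      dmso_n <- median(base$nluc * ln_noise(16L, config$noise_cv))
      dmso_f <- median(base$fluc * ln_noise(16L, config$noise_cv))
      if (tr$label %in% c("activator", "inhibitor")) {
        psi_c <- clamp_psi(base_psi + tr$dpsi * frac)
        lum <- psi_to_luminescence(psi_c, "V1", config$gains)
        nluc <- lum$nluc
        fluc <- lum$fluc
        direction <- tr$label
      } else if (tr$label == "unidirectional_artifact") {
        nluc <- rep(base$nluc, n_c)
        fluc <- rep(base$fluc, n_c)
        m <- 2^(tr$log2fc * frac)
        if (tr$artifact_target == "nluc") nluc <- nluc * m else fluc <- fluc * m
        ratio_up <- (tr$artifact_target == "fluc") == (tr$log2fc > 0)
        direction <- if (ratio_up) "activator" else "inhibitor"
      } else {
        nluc <- rep(base$nluc, n_c)
        fluc <- rep(base$fluc, n_c)
        direction <- sample(c("activator", "inhibitor"), 1L)
      }
      rel_nluc <- nluc * ln_noise(n_c, config$noise_cv) / dmso_n
      rel_fluc <- fluc * ln_noise(n_c, config$noise_cv) / dmso_f
      out[[i]] <- tibble(compound_id = tr$compound_id, arm = "V1",
                         concentration = concentrations,
                         rel_nluc = rel_nluc, rel_fluc = rel_fluc,
                         expected_direction = direction)
    }
    dplyr::bind_rows(out)
  })
}

#' Simulate a PSI-to-luminescence calibration curve
#'
#' Emulates the reporter calibration experiment: a grid of reporter PSI
#' values (as driven by increasing doses of a splicing activator such as
#' SRRM4), each measured in `n_rep` replicate wells under log-normal
#' luminescence noise.
#'
#' @param config A [simulation_config()] (supplies noise, gains, seed).
#' @param psi_grid PSI values to measure (default 5 to 95 by 5).
#' @param arm Reporter arm.
#' @param n_rep Replicate wells per PSI value (default 4).
#' @return Tibble: `psi`, `replicate`, `nluc`, `fluc`,
#'   `percent_inclusion_lum` (percent Firefly for V1, percent NanoLuc for
#'   V2).
#' @export
simulate_psi_calibration <- function(config, psi_grid = seq(5, 95, by = 5),
                                     arm = "V1", n_rep = 4L) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(plate_substream_seed(config$seed, 0L, stream = 11L), {
    grid <- tidyr::expand_grid(psi = psi_grid, replicate = seq_len(n_rep))
    lum <- psi_to_luminescence(grid$psi, arm, config$gains)
    grid$nluc <- lum$nluc * ln_noise(nrow(grid), config$noise_cv)
    grid$fluc <- lum$fluc * ln_noise(nrow(grid), config$noise_cv)
    grid$percent_inclusion_lum <- percent_luminescence(
      grid$nluc, grid$fluc, which = if (arm == "V1") "fluc" else "nluc")
    grid
  })
}
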