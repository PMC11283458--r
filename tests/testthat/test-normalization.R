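test_that("median polish removes purely additive structure exactly", {
  m <- outer(10 * (0:2), 0:2, `+`)
  p <- median_polish(m)
  expect_true(all(abs(p$residuals) < 1e-12))
  expect_true(p$converged)
  expect_lte(p$iterations, 2L)

  # constant matrix: everything lands in the overall effect
  p2 <- median_polish(matrix(3.5, 4, 5))
  expect_equal(p2$overall_effect, 3.5)
  expect_true(all(p2$row_effects == 0))
  expect_true(all(p2$col_effects == 0))
  expect_true(all(p2$residuals == 0))
})

test_that("masked outlier leaves unmasked residuals untouched and scores itself", {
  set.seed(11)
  base <- make_additive_matrix(4, 4)
  mask <- matrix(FALSE, 4, 4)
  mask[2, 3] <- TRUE
  spiked <- base
  spiked[2, 3] <- spiked[2, 3] + 100

  p_clean <- median_polish(base, mask)
  p_spiked <- median_polish(spiked, mask)
  expect_equal(p_spiked$residuals[!mask], p_clean$residuals[!mask])
  expect_equal(p_spiked$residuals[2, 3], 100)

  # independent oracle: replay the sweeps as straight-line code
  res <- spiked
  overall <- 0
  row_eff <- numeric(4)
  col_eff <- numeric(4)
  for (it in seq_len(p_spiked$iterations)) {
    d <- median(res[!mask])
    overall <- overall + d
    res <- res - d
    for (i in 1:4) {
      ri <- median(res[i, !mask[i, ]])
      row_eff[i] <- row_eff[i] + ri
      res[i, ] <- res[i, ] - ri
    }
    for (j in 1:4) {
      cj <- median(res[!mask[, j], j])
      col_eff[j] <- col_eff[j] + cj
      res[, j] <- res[, j] - cj
    }
  }
  expect_equal(p_spiked$residuals, res)
  expect_equal(p_spiked$overall_effect, overall)
  expect_equal(p_spiked$row_effects, row_eff)
  expect_equal(p_spiked$col_effects, col_eff)
})

test_that("unmasked polish matches stats::medpolish where sweep order cannot matter", {
  set.seed(5)
  for (rep in 1:5) {
    m <- make_additive_matrix(6, 8)
    ours <- median_polish(m, tol = 1e-9)
    ref <- stats::medpolish(m, eps = 1e-9, maxiter = 50, trace.iter = FALSE)
    expect_true(all(abs(ours$residuals - ref$residuals) < 1e-9))
  }
})

test_that("polished rows and columns have near-zero medians and the identity holds", {
  set.seed(21)
  m <- make_additive_matrix(8, 10) + matrix(rnorm(80, 0, 0.5), 8, 10)
  mask <- matrix(runif(80) < 0.15, 8, 10)
  p <- median_polish(m, mask, tol = 1e-10, max_iter = 500)

  fit <- p$overall_effect + outer(p$row_effects, p$col_effects, `+`)
  expect_lt(max(abs(m - fit - p$residuals)), 1e-9)

  use <- !mask
  row_meds <- sapply(1:8, function(i) median(p$residuals[i, use[i, ]]))
  col_meds <- sapply(1:10, function(j) median(p$residuals[use[, j], j]))
  expect_lt(max(abs(row_meds)), 1e-6)
  expect_lt(max(abs(col_meds)), 1e-6)

  # idempotence: re-polishing residuals barely changes them
  p2 <- median_polish(p$residuals, mask, tol = 1e-10, max_iter = 500)
  expect_lt(sum(abs(p2$residuals[use] - p$residuals[use])) /
              sum(abs(p$residuals[use])), 1e-3)
})

test_that("degenerate and non-converging inputs are reported, not hidden", {
  expect_error(median_polish(matrix(NA_real_, 3, 3),
                             mask = matrix(FALSE, 3, 3)),
               "no unmasked")
  set.seed(3)
  m <- matrix(rnorm(64), 8, 8)
  expect_warning(p <- median_polish(m, tol = 1e-15, max_iter = 2L),
                 "did not converge")
  expect_false(p$converged)
  expect_equal(p$iterations, 2L)
})

test_that("B-scores are residuals over the plate's median absolute residual", {
  res <- matrix(c(2, -2, 2, -2, 2, -2), 2, 3)
  # construct the polish result directly to pin the definition
  p <- structure(list(residuals = res, overall_effect = 0,
                      row_effects = numeric(2), col_effects = numeric(3),
                      iterations = 1L, converged = TRUE, final_delta = 0,
                      mask = matrix(FALSE, 2, 3)),
                 class = "polish_result")
  b <- bscore(p)
  expect_equal(b$scale, 2)
  expect_equal(b$scores, res / 2)

  # all-zero residuals (perfectly additive plate) cannot be scaled
  p0 <- median_polish(outer(10 * (0:2), 0:2, `+`))
  expect_error(bscore(p0), "median absolute residual is zero")
})

test_that("median absolute B-score over unmasked wells is exactly 1", {
  set.seed(9)
  m <- make_additive_matrix(6, 6) + matrix(rnorm(36, 0, 0.3), 6, 6)
  mask <- matrix(FALSE, 6, 6); mask[, 1] <- TRUE
  b <- bscore(median_polish(m, mask, tol = 1e-8))
  expect_equal(median(abs(b$scores[!mask])), 1.0)
  # control wells still receive scores from their residuals
  expect_true(all(is.finite(b$scores[mask])))
})

test_that("plates are normalized independently and failures are contained", {
  p1 <- make_plate_wells("P1", seed = 1)
  p2 <- make_plate_wells("P2", seed = 2)
  ds <- screen_dataset(dplyr::bind_rows(p1, p2))
  n1 <- normalize_screen(ds)

  # perturbing plate 2 leaves plate 1's scores bit-identical
  p2b <- p2
  p2b$fluc <- p2b$fluc * 3
  dsb <- screen_dataset(dplyr::bind_rows(p1, p2b))
  n2 <- normalize_screen(dsb)
  expect_equal(n1$scores[n1$scores$plate_id == "P1", ],
               n2$scores[n2$scores$plate_id == "P1", ])

  # a degenerate plate (all equal ratios) fails alone
  p2c <- p2
  p2c$fluc <- p2c$nluc  # ratio 1 everywhere
  dsc <- screen_dataset(dplyr::bind_rows(p1, p2c))
  n3 <- normalize_screen(dsc)
  expect_false(n3$report$ok[n3$report$plate_id == "P2"])
  expect_match(n3$report$message[n3$report$plate_id == "P2"],
               "median absolute residual")
  expect_true(all(n3$report$ok[n3$report$plate_id == "P1"]))
  expect_true(all(n3$scores$plate_id == "P1"))
})

test_that("B-scores are uncorrelated with injected spatial gradients", {
  # additive row/column artifacts at up to 50% of the baseline ratio
  cfg <- small_config(row_effect_sd = 0.5, col_effect_sd = 0.5)
  sim <- simulate_screen(cfg)
  scores <- normalize_screen(sim$dataset)$scores
  samples <- scores[scores$role == "sample" & !is.na(scores$bscore), ]

  spatial <- sim$spatial
  key <- paste(samples$arm, samples$plate_id)
  row_inj <- mapply(function(k, r) {
    e <- spatial[spatial$kind == "row" & paste(spatial$arm, spatial$plate_id) == k, ]
    e$effect[match(r, e$index)]
  }, key, samples$row)
  col_inj <- mapply(function(k, cc) {
    e <- spatial[spatial$kind == "col" & paste(spatial$arm, spatial$plate_id) == k, ]
    e$effect[match(cc, e$index)]
  }, key, samples$col)
  expect_lt(abs(cor(samples$bscore, row_inj)), 0.05)
  expect_lt(abs(cor(samples$bscore, col_inj)), 0.05)
  # the gradients themselves are large relative to the baseline ratio
  expect_gt(stats::sd(row_inj), 0.2)
})
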