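## Control-masked iterative median polish and B-score scaling.
##
## Each 384-well plate is normalized independently: the ratio matrix is
## decomposed into overall + row + column effects + residuals by iterated
## median sweeps in which control and empty wells never contribute to any
## median (but still receive the subtractions), and residuals are scaled
## by the plate's median absolute residual over sample wells.

#' Control-masked iterative median polish
#'
#' Decomposes a plate matrix into `overall + row + column + residual` by
#' repeatedly sweeping medians: per iteration the overall median of the
#' unmasked residuals is absorbed into the overall effect, then row
#' medians into row effects, then column medians into column effects.
#' Masked cells (controls, empties) and missing cells never enter a
#' median, but masked cells are still updated by every subtraction so
#' their residuals remain comparable to sample wells. Iteration stops
#' when the sum of absolute unmasked residuals changes by less than
#' `tol` relative to that sum, or at `max_iter` with a warning.
#'
#' The decomposition identity `value = overall + row_effect + col_effect +
#' residual` holds exactly (to floating error) for every non-missing cell,
#' whatever the sweep order; the residuals themselves depend on the sweep
#' order, which is fixed as overall, rows, columns.
#'
#' @param x A [plate_matrix()] or a plain numeric matrix.
#' @param mask Logical matrix when `x` is a plain matrix; ignored when `x`
#'   is a `plate_matrix`.
#' @param tol Relative convergence tolerance on the sum of absolute
#'   unmasked residuals (default 0.01, the classic median-polish default).
#' @param max_iter Maximum number of sweep iterations (default 100).
#' @return An object of class `polish_result`: a list with `residuals`,
#'   `overall_effect`, `row_effects`, `col_effects`, `iterations`,
#'   `converged` and `final_delta`.
#' @export
#' @examples
#' m <- outer(10 * (0:2), 0:2, `+`)   # purely additive 3 x 3
#' p <- median_polish(m)
#' max(abs(p$residuals))              # 0: additive structure removed exactly
median_polish <- function(x, mask = NULL, tol = 0.01, max_iter = 100L) {
  if (inherits(x, "plate_matrix")) {
    mask <- x$mask
    values <- x$values
  } else {
    values <- as.matrix(x)
    storage.mode(values) <- "double"
    if (is.null(mask)) mask <- matrix(FALSE, nrow(values), ncol(values))
  }
  if (tol <= 0 || max_iter < 1L) abort("tol and max_iter must be positive")
  use <- !mask & !is.na(values)
  if (!any(use)) abort("no unmasked, non-missing values to polish")

  res <- values
  overall <- 0
  row_eff <- numeric(nrow(res))
  col_eff <- numeric(ncol(res))
  usable <- function(m) ifelse(use, m, NA_real_)

  abs_sum <- sum(abs(res[use]))
  converged <- FALSE
  delta_rel <- NA_real_
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    med_all <- median(res[use])
    overall <- overall + med_all
    res <- res - med_all

    row_med <- apply(usable(res), 1L, median, na.rm = TRUE)
    row_med[is.na(row_med)] <- 0  # rows with no unmasked values are skipped
    row_eff <- row_eff + row_med
    res <- res - row_med  # recycles down columns: subtracts row_med[i] from row i

    col_med <- apply(usable(res), 2L, median, na.rm = TRUE)
    col_med[is.na(col_med)] <- 0
    col_eff <- col_eff + col_med
    res <- sweep(res, 2L, col_med)

    new_abs_sum <- sum(abs(res[use]))
    if (new_abs_sum == 0) {
      converged <- TRUE
      delta_rel <- 0
      break
    }
    delta_rel <- abs(abs_sum - new_abs_sum) / new_abs_sum
    abs_sum <- new_abs_sum
    if (delta_rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("median polish did not converge in %d iterations", max_iter))
  }
  structure(list(residuals = res, overall_effect = overall,
                 row_effects = row_eff, col_effects = col_eff,
                 iterations = iter, converged = converged,
                 final_delta = delta_rel, mask = mask),
            class = "polish_result")
}

#' @export
print.polish_result <- function(x, ...) {
  cat(sprintf(
    "<polish_result> %d x %d, overall = %.4g, %d iteration(s), converged = %s\n",
    nrow(x$residuals), ncol(x$residuals), x$overall_effect,
    x$iterations, x$converged))
  invisible(x)
}

#' Scale polish residuals to B-scores
#'
#' The B-score of a well is its polish residual divided by the plate's
#' median absolute residual over unmasked (sample) wells, so the median
#' absolute B-score of the sample wells is exactly 1. Control wells are
#' scored too — from their own residuals — despite being masked from the
#' medians, which is what makes positive/negative control separation
#' readable on the same scale as samples.
#'
#' @param polish A [median_polish()] result.
#' @param mask Logical matrix overriding the mask stored in `polish`.
#' @param use_mad If `TRUE`, scale by `stats::mad()` of the unmasked
#'   residuals (1.4826 x median absolute deviation, the classic B-score
#'   denominator) instead of the plain median absolute residual.
#' @return An object of class `bscore_table`: list with `scores` (matrix),
#'   `scale` and `source_polish`.
#' @export
bscore <- function(polish, mask = NULL, use_mad = FALSE) {
  if (!inherits(polish, "polish_result")) abort("polish must be a polish_result")
  if (is.null(mask)) mask <- polish$mask
  res <- polish$residuals
  use <- !mask & !is.na(res)
  if (!any(use)) abort("no unmasked residuals to scale")
  scale <- if (use_mad) {
    mad(res[use])
  } else {
    median(abs(res[use]))
  }
  if (scale == 0) {
    abort("degenerate plate: median absolute residual is zero")
  }
  structure(list(scores = res / scale, scale = scale, source_polish = polish),
            class = "bscore_table")
}

#' @export
print.bscore_table <- function(x, ...) {
  cat(sprintf("<bscore_table> %d x %d, scale = %.4g\n",
              nrow(x$scores), ncol(x$scores), x$scale))
  invisible(x)
}

#' Normalize a whole screen to B-scores
#'
#' Runs `compute_ratio_plate()`, `median_polish()` and `bscore()`
#' independently for every plate of every reporter arm and returns a long
#' per-well score table together with a per-plate run report. A plate
#' that fails (e.g. a degenerate zero-scale plate) is recorded in the
#' report and contributes no scores; other plates are unaffected.
#'
#' @param dataset A [screen_dataset()].
#' @inheritParams median_polish
#' @param log2_ratio Polish log2 ratios instead of raw ratios.
#' @param use_mad Passed to [bscore()].
#' @return A list with `scores` — a tibble (arm, plate_id, row, col,
#'   compound_id, role, concentration, ratio, bscore, converged) — and
#'   `report` — a tibble (arm, plate_id, iterations, converged, scale,
#'   ok, message).
#' @export
normalize_screen <- function(dataset, tol = 0.01, max_iter = 100L,
                             log2_ratio = FALSE, use_mad = FALSE) {
  if (is.list(dataset) && !is.data.frame(dataset) &&
      "dataset" %in% names(dataset)) {
    dataset <- dataset$dataset  # accept simulate_screen() output directly
  }
  wells <- as_tibble(dataset)
  plates <- unique(wells[, c("arm", "plate_id")])
  scores <- vector("list", nrow(plates))
  report <- vector("list", nrow(plates))
  for (k in seq_len(nrow(plates))) {
    arm_k <- plates$arm[k]
    plate_k <- plates$plate_id[k]
    pw <- wells[wells$arm == arm_k & wells$plate_id == plate_k, ]
    outcome <- tryCatch({
      pm <- compute_ratio_plate(pw, arm = arm_k, log2_transform = log2_ratio)
      pol <- median_polish(pm, tol = tol, max_iter = max_iter)
      bs <- bscore(pol, use_mad = use_mad)
      idx <- cbind(pw$row + 1L, pw$col + 1L)
      scores[[k]] <- tibble(
        arm = arm_k, plate_id = plate_k,
        row = pw$row, col = pw$col,
        compound_id = pw$compound_id, role = pw$role,
        concentration = pw$concentration,
        ratio = pm$values[idx],
        bscore = bs$scores[idx],
        converged = pol$converged
      )
      list(ok = TRUE, iterations = pol$iterations,
           converged = pol$converged, scale = bs$scale, message = NA_character_)
    }, error = function(e) {
      list(ok = FALSE, iterations = NA_integer_, converged = NA,
           scale = NA_real_, message = conditionMessage(e))
    })
    report[[k]] <- tibble(arm = arm_k, plate_id = plate_k,
                          iterations = outcome$iterations,
                          converged = outcome$converged,
                          scale = outcome$scale,
                          ok = outcome$ok, message = outcome$message)
  }
  empty_scores <- tibble(
    arm = character(), plate_id = character(), row = integer(),
    col = integer(), compound_id = character(), role = character(),
    concentration = double(), ratio = double(), bscore = double(),
    converged = logical()
  )
  list(scores = dplyr::bind_rows(c(list(empty_scores), scores)),
       report = dplyr::bind_rows(report))
}
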