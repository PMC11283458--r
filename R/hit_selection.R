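## Hyperbolic gating of paired reciprocal-reporter B-scores.
##
## With x = B-score of the V1 Firefly/NanoLuc ratio and y = B-score of the
## V2 NanoLuc/Firefly ratio, a genuine splicing modulator pushes x and y in
## the same direction while a single-luciferase artifact pushes them in
## opposite directions. The gate keeps the two concordant hyperbolic
## branches and rejects the anti-concordant wedge around the asymptotes
## y = -d*x and y = -x/d.

#' Hyperbolic gate parameters
#'
#' The hit boundary in the (x, y) plane of paired reciprocal-reporter
#' B-scores is the hyperbola `(x - y/(-d)) * (-y + x/(-d)) / (-2) = t`,
#' which simplifies to `(x + y/d) * (y + x/d) / 2 = t`. `d` controls how
#' tightly the asymptote wedge hugs the axes (larger d = wider wedge =
#' more tolerance for unidirectional signal) and `t` is the margin a
#' compound must reach to be called.
#'
#' @param asymptote_divisor Constant dividing the cross terms (default 7).
#' @param threshold Right-hand-side margin a hit must reach (default 4).
#' @return A list of class `hyperbola_gate`.
#' @export
hyperbola_params <- function(asymptote_divisor = 7, threshold = 4) {
  if (!is.finite(asymptote_divisor) || asymptote_divisor == 0) {
    abort("asymptote_divisor must be finite and non-zero")
  }
  if (!is.finite(threshold) || threshold <= 0) {
    abort("threshold must be positive")
  }
  structure(list(asymptote_divisor = asymptote_divisor, threshold = threshold),
            class = "hyperbola_gate")
}

#' Gate margin of a reciprocal score pair
#'
#' Evaluates `M = (x - y/(-d)) * (-y + x/(-d)) / (-2)`. M is symmetric in
#' x and y, positive in the concordant quadrants (both scores up = putative
#' activator, both down = inhibitor) and negative for anti-concordant
#' pairs; `M >= threshold` defines a hit.
#'
#' @param x,y Numeric vectors of paired B-scores (V1 and V2 arms).
#' @param params A [hyperbola_params()] object.
#' @return Numeric vector of margins.
#' @export
#' @examples
#' gate_margin(0, 0)                      # 0 at the origin
#' gate_margin(7 / (2 * sqrt(2)), 7 / (2 * sqrt(2)))  # 4, on the boundary
gate_margin <- function(x, y, params = hyperbola_params()) {
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("gate_margin requires finite scores")
  }
  d <- params$asymptote_divisor
  (x - y / (-d)) * (-y + x / (-d)) / (-2)
}

#' Classify paired reciprocal scores
#'
#' A pair is an `activator` when its gate margin reaches the threshold and
#' the diagonal projection `x + y` is positive, an `inhibitor` when the
#' margin reaches the threshold with `x + y` negative, and `inactive`
#' otherwise. Points exactly on the boundary are hits. (`x + y = 0` with a
#' passing margin cannot occur: on that line the margin is non-positive.)
#'
#' @inheritParams gate_margin
#' @return Character vector in `{"activator", "inhibitor", "inactive"}`.
#' @export
classify_pair <- function(x, y, params = hyperbola_params()) {
  m <- gate_margin(x, y, params)
  hit <- m >= params$threshold
  dplyr::case_when(
    hit & (x + y) > 0 ~ "activator",
    hit & (x + y) < 0 ~ "inhibitor",
    .default = "inactive"
  )
}

#' Call hits from per-well B-score tables of the two reporter arms
#'
#' Aggregates replicate sample wells of each compound within each arm
#' (default: median B-score), pairs the V1 score (x) with the V2 score
#' (y), and applies the hyperbolic gate. Compounds present in only one
#' arm cannot be gated and are reported separately.
#'
#' @param scores Long per-well score table as produced by
#'   [normalize_screen()] (either the list or its `scores` element),
#'   containing both arms; only `role == "sample"` wells are used.
#' @param params A [hyperbola_params()] object.
#' @param aggregate Function collapsing replicate well B-scores within an
#'   arm to one value per compound (default `stats::median`).
#' @return A tibble of class `hit_calls` with columns `compound_id`, `x`,
#'   `y`, `n_wells_v1`, `n_wells_v2`, `margin`, `label`, plus attributes
#'   `summary` (counts and fractions) and `unpaired` (compound ids seen in
#'   a single arm).
#' @export
call_hits <- function(scores, params = hyperbola_params(),
                      aggregate = stats::median) {
  if (is.list(scores) && !is.data.frame(scores) && "scores" %in% names(scores)) {
    scores <- scores$scores
  }
  scores <- as_tibble(scores)
  samples <- dplyr::filter(scores, .data$role == "sample",
                           !is.na(.data$bscore))
  per_arm <- samples |>
    dplyr::group_by(.data$compound_id, .data$arm) |>
    dplyr::summarise(score = aggregate(.data$bscore),
                     n_wells = dplyr::n(), .groups = "drop")
  wide <- tidyr::pivot_wider(per_arm, id_cols = "compound_id",
                             names_from = "arm",
                             values_from = c("score", "n_wells"))
  for (needed in c("score_V1", "score_V2", "n_wells_V1", "n_wells_V2")) {
    if (!needed %in% names(wide)) wide[[needed]] <- NA
  }
  unpaired <- wide$compound_id[is.na(wide$score_V1) | is.na(wide$score_V2)]
  paired <- wide[!wide$compound_id %in% unpaired, ]

  calls <- tibble(
    compound_id = paired$compound_id,
    x = paired$score_V1,
    y = paired$score_V2,
    n_wells_v1 = as.integer(paired$n_wells_V1),
    n_wells_v2 = as.integer(paired$n_wells_V2)
  )
  calls$margin <- if (nrow(calls)) gate_margin(calls$x, calls$y, params) else numeric()
  calls$label <- if (nrow(calls)) classify_pair(calls$x, calls$y, params) else character()

  n_total <- nrow(calls)
  n_act <- sum(calls$label == "activator")
  n_inh <- sum(calls$label == "inhibitor")
  attr(calls, "summary") <- list(
    n_compounds = n_total,
    n_activators = n_act,
    n_inhibitors = n_inh,
    n_inactive = n_total - n_act - n_inh,
    frac_activators = if (n_total) n_act / n_total else NA_real_,
    frac_inhibitors = if (n_total) n_inh / n_total else NA_real_,
    n_unpaired = length(unpaired)
  )
  attr(calls, "unpaired") <- unpaired
  class(calls) <- c("hit_calls", class(calls))
  calls
}

#' Summarize hit calls
#'
#' @param object A [call_hits()] result.
#' @param ... Unused.
#' @return The summary list stored on the calls: compound, activator,
#'   inhibitor, inactive and unpaired counts and hit fractions.
#' @export
summary.hit_calls <- function(object, ...) {
  attr(object, "summary")
}

#' Plot paired reciprocal B-scores with the hyperbolic gate
#'
#' Scatter of (x, y) score pairs colored by call, with the gate boundary
#' drawn as the two hyperbolic branches.
#'
#' @param calls A [call_hits()] result.
#' @param params The gate used for the boundary curves.
#' @return A ggplot object.
#' @export
plot_hits <- function(calls, params = hyperbola_params()) {
  d <- params$asymptote_divisor
  t <- params$threshold
  ## boundary: (x + y/d)(y + x/d)/2 = t, solved for y given x
  branch <- function(x, sign) {
    a <- 1 / d
    b <- x * (1 + 1 / d^2)
    cc <- x^2 / d - 2 * t
    disc <- b^2 - 4 * a * cc
    out <- (-b + sign * sqrt(disc)) / (2 * a)
    out[disc < 0] <- NA_real_
    out
  }
  lim <- max(abs(c(calls$x, calls$y, 10)))
  grid <- seq(-lim, lim, length.out = 400)
  upper <- tibble(x = grid, y = branch(grid, 1))
  lower <- tibble(x = grid, y = branch(grid, -1))
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 0.8) +
    ggplot2::geom_line(data = upper, colour = "grey30", linetype = 2) +
    ggplot2::geom_line(data = lower, colour = "grey30", linetype = 2) +
    ggplot2::scale_colour_manual(values = c(
      activator = "#d95f02", inhibitor = "#7570b3", inactive = "grey70")) +
    ggplot2::labs(x = "B-score, Firefly V1 / Nano V1",
                  y = "B-score, Nano V2 / Firefly V2",
                  colour = NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
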