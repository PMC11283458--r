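## Secondary validation from two-fold serial dilution series.
##
## A putative hit is validated when its reporter-ratio effect, relative to
## same-plate DMSO controls, has the direction expected from the primary
## screen at a minimum number of consecutive concentrations; the effective
## concentration range is read directly off the dilution grid.

#' Standard two-fold dilution concentrations
#'
#' Ten-point two-fold series spanning 40 nM to 20 uM (top dose halved nine
#' times), in ascending molar concentration.
#'
#' @param top Top concentration in molar (default `20e-6`).
#' @param n Number of points (default 10).
#' @param fold Dilution factor between consecutive points (default 2).
#' @return Ascending numeric vector of length `n`.
#' @export
dilution_concentrations <- function(top = 20e-6, n = 10L, fold = 2) {
  sort(top / fold^(seq_len(n) - 1L))
}

#' Signed splicing effect from relative luminescence
#'
#' Log2 ratio-of-ratios of the two luciferases relative to DMSO. For the
#' V1 reporter (inclusion expresses Firefly) the score is
#' `log2(rel_fluc) - log2(rel_nluc)`, so positive means a shift toward
#' microexon inclusion; the sign convention is flipped for the reciprocal
#' V2 reporter (inclusion expresses NanoLuc).
#'
#' @param rel_nluc,rel_fluc Strictly positive luminescence values relative
#'   to same-plate DMSO controls.
#' @param arm `"V1"` or `"V2"`.
#' @return Numeric vector of signed effect scores (log2 units).
#' @export
#' @examples
#' effect_score(rel_nluc = 1, rel_fluc = 2, arm = "V1")   # +1
#' effect_score(rel_nluc = 4, rel_fluc = 1, arm = "V1")   # -2
effect_score <- function(rel_nluc, rel_fluc, arm = "V1") {
  if (any(!is.finite(rel_nluc)) || any(!is.finite(rel_fluc)) ||
      any(rel_nluc <= 0) || any(rel_fluc <= 0)) {
    abort("relative luminescence must be strictly positive")
  }
  arm <- match.arg(arm, c("V1", "V2"))
  s <- log2(rel_fluc) - log2(rel_nluc)
  if (arm == "V2") -s else s
}

#' Validate one dilution series against its expected direction
#'
#' Scores every concentration with [effect_score()], then looks for runs
#' of consecutive concentrations whose score has the direction expected
#' from the primary screen (positive for activators, negative for
#' inhibitors) and magnitude at least `effect_threshold`. The compound is
#' validated when the longest such run spans at least `min_consecutive`
#' points; ties between equally long runs go to the run at higher
#' concentrations. The effective range is the lowest and highest
#' concentration of that run.
#'
#' @param series Data frame for a single compound with columns
#'   `concentration` (molar), `rel_nluc`, `rel_fluc`, and either an `arm`
#'   column or all measurements from one arm; `expected_direction`
#'   (`"activator"` or `"inhibitor"`) may be a column or passed directly.
#' @param effect_threshold Minimum absolute effect score (log2 units) for
#'   a concentration to qualify (default 0.5, i.e. a ~40% ratio shift).
#' @param min_consecutive Minimum run length (default 2).
#' @param expected_direction Overrides the column of the same name.
#' @param arm Overrides the `arm` column (default `"V1"`, the arm used for
#'   secondary screening).
#' @return A list with `validated`, `min_effective`, `max_effective`
#'   (molar, `NA` when not validated) and `effect_profile`, a tibble of
#'   per-concentration scores and qualification flags in ascending
#'   concentration order.
#' @export
validate_series <- function(series, effect_threshold = 0.5,
                            min_consecutive = 2L,
                            expected_direction = NULL, arm = NULL) {
  series <- as_tibble(series)
  if (is.null(expected_direction)) {
    if (!"expected_direction" %in% names(series)) {
      abort("expected_direction must be supplied")
    }
    expected_direction <- unique(series$expected_direction)
  }
  expected_direction <- match.arg(expected_direction,
                                  c("activator", "inhibitor"))
  if (is.null(arm)) {
    arm <- if ("arm" %in% names(series)) unique(series$arm) else "V1"
  }
  if (length(arm) != 1L) abort("series must come from a single reporter arm")
  if (effect_threshold <= 0) abort("effect_threshold must be positive")

  series <- series[order(series$concentration), ]
  if (any(diff(series$concentration) == 0)) {
    abort("duplicate concentrations in dilution series")
  }
  score <- effect_score(series$rel_nluc, series$rel_fluc, arm = arm)
  want_sign <- if (expected_direction == "activator") 1 else -1
  qualifies <- (sign(score) == want_sign) & (abs(score) >= effect_threshold)

  profile <- tibble(concentration = series$concentration,
                    score = score, qualifies = qualifies)
  n <- nrow(profile)
  result <- list(validated = FALSE, min_effective = NA_real_,
                 max_effective = NA_real_, effect_profile = profile)
  if (n < min_consecutive) {
    warn(sprintf("series has %d point(s), fewer than min_consecutive = %d",
                 n, min_consecutive))
    return(result)
  }
  runs <- rle(qualifies)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= min_consecutive)
  if (length(ok) == 0) return(result)
  # longest run; ties resolved toward higher concentrations (later runs)
  best <- ok[runs$lengths[ok] == max(runs$lengths[ok])]
  best <- best[length(best)]
  result$validated <- TRUE
  result$min_effective <- profile$concentration[starts[best]]
  result$max_effective <- profile$concentration[ends[best]]
  result
}

#' Validate a panel of dilution series
#'
#' Applies [validate_series()] per compound to a long dilution table and
#' returns one row per compound.
#'
#' @param dilutions Long data frame with columns `compound_id`,
#'   `concentration`, `rel_nluc`, `rel_fluc`, `expected_direction` and
#'   optionally `arm`.
#' @inheritParams validate_series
#' @return Tibble with columns `compound_id`, `validated`,
#'   `min_effective`, `max_effective`.
#' @export
validate_dilutions <- function(dilutions, effect_threshold = 0.5,
                               min_consecutive = 2L) {
  dilutions <- as_tibble(dilutions)
  dilutions |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::group_modify(function(df, key) {
      v <- validate_series(df, effect_threshold = effect_threshold,
                           min_consecutive = min_consecutive)
      tibble(validated = v$validated,
             min_effective = v$min_effective,
             max_effective = v$max_effective)
    }) |>
    dplyr::ungroup()
}
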