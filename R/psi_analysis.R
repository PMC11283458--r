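## Percent-spliced-in analytics linking RT-PCR band intensities to the
## luminescence fractions of the dual reporters.

#' Percent spliced-in from isoform band intensities
#'
#' PSI is the percentage of transcripts including the alternative exon:
#' `100 * inc / (inc + skip)`. With `molar_correct = TRUE` each band
#' intensity is first divided by its amplicon length (nt) to convert a
#' mass-proportional stain signal into a molar one — longer amplicons bind
#' more intercalating dye per molecule.
#'
#' @param inclusion,skip Non-negative band intensities of the
#'   exon-included and exon-skipped amplicons (at least one positive).
#' @param molar_correct Divide intensities by amplicon length first.
#' @param inclusion_len,skip_len Amplicon lengths in nt, required when
#'   `molar_correct = TRUE`.
#' @return PSI in `[0, 100]`.
#' @export
#' @examples
#' psi(3, 1)                                              # 75
#' psi(300, 100, molar_correct = TRUE,
#'     inclusion_len = 300, skip_len = 150)               # 60
psi <- function(inclusion, skip, molar_correct = FALSE,
                inclusion_len = NULL, skip_len = NULL) {
  if (any(inclusion < 0) || any(skip < 0)) {
    abort("band intensities must be non-negative")
  }
  if (molar_correct) {
    if (is.null(inclusion_len) || is.null(skip_len) ||
        any(inclusion_len <= 0) || any(skip_len <= 0)) {
      abort("molar correction requires positive amplicon lengths")
    }
    inclusion <- inclusion / inclusion_len
    skip <- skip / skip_len
  }
  if (any(inclusion + skip == 0)) {
    abort("PSI undefined: both band intensities are zero")
  }
  100 * inclusion / (inclusion + skip)
}

#' Difference in percent spliced-in
#'
#' Treatment-minus-control PSI, the standard effect size for an
#' alternative splicing change.
#'
#' @param psi_treatment,psi_control PSI values in `[0, 100]`.
#' @return Delta PSI in `[-100, 100]`.
#' @export
delta_psi <- function(psi_treatment, psi_control) {
  psi_treatment - psi_control
}

#' Percent luminescence of one luciferase
#'
#' The fraction of total luminescence emitted by one of the two
#' luciferases, as a percentage. For a V1 reporter with equal gains this
#' tracks reporter PSI directly (percent Firefly ~ PSI).
#'
#' @param nluc,fluc Strictly positive luminescence signals.
#' @param which `"fluc"` or `"nluc"`.
#' @return Percentage in `(0, 100)`.
#' @export
#' @examples
#' percent_luminescence(nluc = 1, fluc = 9, which = "fluc")  # 90
percent_luminescence <- function(nluc, fluc, which = c("fluc", "nluc")) {
  which <- match.arg(which)
  if (any(nluc <= 0) || any(fluc <= 0)) {
    abort("luminescence signals must be strictly positive")
  }
  if (which == "fluc") 100 * fluc / (fluc + nluc) else 100 * nluc / (fluc + nluc)
}

#' Pearson product-moment correlation
#'
#' Thin, validating wrapper around the standard product-moment
#' correlation, used to quantify the linearity between reporter
#' luminescence fractions and RT-PCR PSI.
#'
#' @param a,b Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length")
  if (length(a) < 3) abort("need at least 3 paired observations")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    abort("correlation undefined: zero variance")
  }
  cor(a, b, method = "pearson")
}
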