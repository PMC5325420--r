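#' Relative drug efficacy
#'
#' The drug-induced fractional reduction of integrated output in a module,
#' minus the same quantity in the crosstalk-free baseline module 0:
#' RDE = (1 - IO_drug / IO_no_drug) - (1 - IO_drug^0 / IO_no_drug^0).
#' Positive values mean the drug removes a larger fraction of output in this
#' module than in the baseline; negative values mean crosstalk-mediated
#' resistance.
#'
#' @param io_module Length-2 numeric `c(no_drug, drug)` for the module under
#'   study.
#' @param io_base Length-2 numeric `c(no_drug, drug)` for the baseline
#'   module.
#' @return Scalar RDE.
#' @export
#' @examples
#' relative_drug_efficacy(c(100, 40), c(100, 60))  # 0.2
relative_drug_efficacy <- function(io_module, io_base) {
  stopifnot(length(io_module) == 2L, length(io_base) == 2L)
  if (io_module[1L] <= 0 || io_base[1L] <= 0) {
    stop("relative drug efficacy is undefined for zero untreated output")
  }
  (io_module[1L] - io_module[2L]) / io_module[1L] -
    (io_base[1L] - io_base[2L]) / io_base[1L]
}

#' Bliss combination index from integrated outputs
#'
#' The fractional reductions R1, R2 and R12 are computed as
#' R = (IO_no_drug - IO_treated) / IO_no_drug (positive under an effective
#' drug), and the combination index as CI = R12 - (R1 + R2 - R1 * R2). Under
#' Bliss independence the remaining output fraction of the combination is
#' the product of the single-drug remaining fractions and CI = 0; CI > 0
#' indicates synergy, CI < 0 antagonism.
#'
#' The `signed = TRUE` variant negates the reductions,
#' R = (IO_treated - IO_no_drug) / IO_no_drug, for comparison; with that
#' convention CI is nonzero at Bliss independence, so the positive-reduction
#' form is the default.
#'
#' @param io_no_drug Untreated integrated output (> 0).
#' @param io_d1,io_d2 Integrated output under each single drug.
#' @param io_d12 Integrated output under the combination.
#' @param signed Use the signed (negative-under-effect) reduction convention.
#' @return List with `R1`, `R2`, `R12`, `CI`.
#' @export
#' @examples
#' # Bliss-independent: remaining fractions multiply (0.5 * 0.5 = 0.25)
#' bliss_combination_index(100, 50, 50, 25)$CI  # 0
bliss_combination_index <- function(io_no_drug, io_d1, io_d2, io_d12,
                                    signed = FALSE) {
  if (!is.finite(io_no_drug) || io_no_drug <= 0) {
    stop("untreated integrated output must be positive")
  }
  red <- function(io) (io_no_drug - io) / io_no_drug
  s <- if (signed) -1 else 1
  R1 <- s * red(io_d1)
  R2 <- s * red(io_d2)
  R12 <- s * red(io_d12)
  list(R1 = R1, R2 = R2, R12 = R12, CI = R12 - (R1 + R2 - R1 * R2))
}

#' Classify a combination index into synergy / additivity / antagonism
#'
#' A tolerance band around zero absorbs small perturbations (5% by default):
#' CI > tol is synergy, CI < -tol antagonism, anything in between
#' additivity. With `tol = 0` this reduces to the pure sign rule.
#'
#' @param ci Combination index (vectorised).
#' @param tol Nonnegative half-width of the additivity band.
#' @return Character vector in `c("synergy", "additivity", "antagonism")`.
#' @export
classify_synergy <- function(ci, tol = 0.05) {
  stopifnot(tol >= 0)
  ifelse(ci > tol, "synergy", ifelse(ci < -tol, "antagonism", "additivity"))
}

#' Compare a combination's efficacy to the single anchor drug
#'
#' @param rde_combo RDE of the combination.
#' @param rde_single RDE of the single anchor drug.
#' @param tol Differences smaller than this count as a tie.
#' @return `"increase"`, `"decrease"` or `"tie"`.
#' @export
compare_combo_to_single <- function(rde_combo, rde_single, tol = 1e-9) {
  d <- rde_combo - rde_single
  if (abs(d) < tol) "tie" else if (d > 0) "increase" else "decrease"
}
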