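#' Local psoriasis severity index from total cell density
#'
#' Maps a total keratinocyte density series to the local psoriasis severity
#' index (LPSI), anchored at an initial clinical score \code{lpsi0}.
#' Induration and scaliness both correlate positively with keratinocyte
#' density, so the default \code{"corrected"} convention is the
#' proportional map \code{LPSI_i = lpsi0 * PTot_i / PTot_0} (clamped at 0),
#' under which the index falls exactly when the density falls. The
#' published formula, \code{LPSI_i = lpsi0 - lpsi0 * (PTot_i - PTot_0) /
#' PTot_0}, is retained as \code{"as_printed"} for audit: it has the
#' opposite sign (severity rises as density falls), contradicting the
#' stated positive correlation, and is not used by any experiment here.
#'
#' @param total numeric vector of total densities (cells/mm^2); the first
#'   element is the baseline PTot_0 (> 0).
#' @param lpsi0 initial severity score (mild psoriasis is roughly 0-10).
#' @param sign_convention \code{"corrected"} (default) or
#'   \code{"as_printed"}.
#' @param time optional time grid (days) stored alongside.
#' @return object of class \code{bluederm_lpsi}: data.frame with columns
#'   \code{time} and \code{lpsi}, attribute \code{lpsi0}.
#' @export
#' @examples
#' lpsi_series(c(217556, 108778), lpsi0 = 5.17)$lpsi # 5.17, 2.585
lpsi_series <- function(total, lpsi0 = 5.17,
                        sign_convention = c("corrected", "as_printed"),
                        time = NULL) {
  sign_convention <- match.arg(sign_convention)
  if (inherits(total, "bluederm_sim")) {
    if (is.null(time)) time <- total$time
    total <- total$total
  }
  if (!is.numeric(total) || !length(total) || any(!is.finite(total))) {
    stop("total must be a finite numeric vector")
  }
  if (total[1] <= 0) stop("baseline total density must be > 0")
  if (!is.numeric(lpsi0) || lpsi0 < 0) stop("lpsi0 must be >= 0")
  if (is.null(time)) time <- seq_along(total) - 1
  lpsi <- switch(sign_convention,
    corrected = pmax(0, lpsi0 * total / total[1]),
    as_printed = lpsi0 - lpsi0 * (total - total[1]) / total[1]
  )
  structure(
    data.frame(time = time, lpsi = lpsi),
    lpsi0 = lpsi0, sign_convention = sign_convention,
    class = c("bluederm_lpsi", "data.frame")
  )
}

#' Final LPSI of a simulated course of treatment
#'
#' Convenience wrapper: severity at the last day of the treatment window
#' (excluding follow-up) and at the simulation end.
#'
#' @param sim a \code{bluederm_sim}.
#' @param lpsi0 initial severity score.
#' @return named numeric vector \code{c(end_of_treatment, end_of_run)}.
#' @export
final_lpsi <- function(sim, lpsi0 = 5.17) {
  stopifnot(inherits(sim, "bluederm_sim"))
  lp <- lpsi_series(sim$total, lpsi0 = lpsi0, time = sim$time)
  t_treat <- min(treatment_days(sim$protocol), max(sim$time))
  c(end_of_treatment = lp$lpsi[match(t_treat, lp$time)],
    end_of_run = lp$lpsi[nrow(lp)])
}
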