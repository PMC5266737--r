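#' Fluence scan: final severity versus per-session fluence
#'
#' Runs one 12-week continuous-wave daily treatment per fluence and reports
#' the severity index at the end of treatment. Severity decreases with
#' fluence through the exponential proliferation factor; at fluences of 500
#' J/cm^2 and above the cytotoxic apoptosis increment switches on and
#' produces a discontinuous extra drop.
#'
#' @param params parameter list.
#' @param fluences per-session fluences to scan (J/cm^2).
#' @param state initial state.
#' @param weeks treatment length in weeks (daily sessions).
#' @param lpsi0 initial severity score.
#' @param ... passed to [simulate_treatment()].
#' @return data.frame with columns \code{fluence}, \code{final_lpsi},
#'   \code{final_total}.
#' @export
fluence_scan <- function(params = default_parameters(),
                         fluences = c(0, 10, 45, 90, 150, 200, 300, 400,
                                      500, 600, 750),
                         state = default_state(), weeks = 12,
                         lpsi0 = 5.17, ...) {
  check_fluence(fluences)
  rows <- lapply(fluences, function(f) {
    prot <- treatment_protocol(
      protocol_phase(7 * weeks, "daily", fluence = f, session_time = 1800,
                     mode = "CW")
    )
    sim <- simulate_treatment(params, state, prot, ...)
    data.frame(fluence = f,
               final_lpsi = unname(final_lpsi(sim, lpsi0)["end_of_treatment"]),
               final_total = unname(utils::tail(sim$total, 1)))
  })
  do.call(rbind, rows)
}

#' Treatment-length scan: final severity versus duration and cadence
#'
#' Simulates daily and/or every-other-day regimens of 4 to 28 weeks at a
#' fixed per-session fluence and reports the severity at the end of each
#' treatment.
#'
#' @param params parameter list.
#' @param weeks vector of total treatment durations (weeks).
#' @param cadences subset of \code{c("daily", "every_other_day")}.
#' @param fluence per-session fluence (J/cm^2).
#' @param state initial state.
#' @param lpsi0 initial severity score.
#' @param ... passed to [simulate_treatment()].
#' @return data.frame with columns \code{weeks}, \code{cadence},
#'   \code{final_lpsi}.
#' @export
length_scan <- function(params = default_parameters(),
                        weeks = seq(4, 28, by = 4),
                        cadences = c("daily", "every_other_day"),
                        fluence = 90, state = default_state(),
                        lpsi0 = 5.17, ...) {
  cadences <- match.arg(cadences, several.ok = TRUE)
  grid <- expand.grid(weeks = weeks, cadence = cadences,
                      stringsAsFactors = FALSE)
  grid$final_lpsi <- mapply(function(w, cad) {
    prot <- treatment_protocol(
      protocol_phase(7 * w, cad, fluence = fluence, session_time = 1800,
                     mode = "CW")
    )
    sim <- simulate_treatment(params, state, prot, ...)
    unname(final_lpsi(sim, lpsi0)["end_of_treatment"])
  }, grid$weeks, grid$cadence)
  grid
}

#' Bistability phase diagram over fluence
#'
#' For each fluence, runs a 12-week daily treatment followed by a
#' relaxation period with no irradiation, then classifies the endpoint as
#' healthy-dominant (healthy stem density strictly exceeds diseased stem
#' density) or diseased-dominant. Only cytotoxic fluences (>= 500 J/cm^2)
#' deplete the diseased stem pool far enough for the healthy basin to win;
#' below that the system returns to the diseased state.
#'
#' @param params parameter list.
#' @param fluences fluences to classify (J/cm^2).
#' @param state initial state.
#' @param weeks treatment length (weeks, daily sessions).
#' @param relax_weeks untreated relaxation appended after treatment.
#' @param ... passed to [simulate_treatment()].
#' @return data.frame with columns \code{fluence}, \code{Psc_h},
#'   \code{Psc_d} (endpoint densities) and \code{dominant}
#'   (\code{"healthy"} or \code{"diseased"}).
#' @export
phase_diagram <- function(params = default_parameters(),
                          fluences = c(0, 45, 90, 200, 300, 450, 500, 600,
                                       750),
                          state = default_state(), weeks = 12,
                          relax_weeks = 12, ...) {
  check_fluence(fluences)
  rows <- lapply(fluences, function(f) {
    prot <- treatment_protocol(
      protocol_phase(7 * weeks, "daily", fluence = f, session_time = 1800,
                     mode = "CW"),
      follow_up_days = 7 * relax_weeks
    )
    sim <- simulate_treatment(params, state, prot, ...)
    end <- sim$state[nrow(sim$state), ]
    data.frame(
      fluence = f,
      Psc_h = unname(end["Psc_h"]),
      Psc_d = unname(end["Psc_d"]),
      dominant = if (end["Psc_h"] > end["Psc_d"]) "healthy" else "diseased"
    )
  })
  do.call(rbind, rows)
}

#' Hypothesis screen across the thirteen mechanism cases
#'
#' Runs the same protocol under each case and summarizes, per day, the
#' three capacities plotted in the screen: proliferative capacity (total
#' self-proliferation flux, gamma terms), differentiation capacity (total
#' division/differentiation flux, k terms) and immune capacity (the
#' diseased-stem killing flux). These operational definitions are an
#' interpretation of the screen's unlabeled axes (summed instantaneous
#' fluxes); tests only assert directions of change.
#'
#' @param params parameter list.
#' @param protocol treatment protocol.
#' @param cases integer vector of case ids.
#' @param state initial state.
#' @param ... passed to [simulate_treatment()].
#' @return named list (one element per case) of data.frames with columns
#'   \code{time}, \code{proliferative}, \code{differentiation},
#'   \code{immune}, \code{total}.
#' @export
screen_cases <- function(params = default_parameters(),
                         protocol = pfaff_protocol(), cases = 1:13,
                         state = default_state(), ...) {
  out <- lapply(cases, function(id) {
    case <- hypothesis_case(id)
    sim <- simulate_treatment(params, state, protocol, case = case, ...)
    cap <- capacity_series(sim, params, case)
    cap
  })
  names(out) <- paste0("case_", cases)
  out
}

# Daily capacity fluxes for one simulated trajectory.
capacity_series <- function(sim, params, case) {
  cal <- c(0, sim$theta$fluence)  # day 0 precedes the first session
  n <- length(sim$time)
  prolif <- numeric(n); diff_ <- numeric(n); imm <- numeric(n)
  for (i in seq_len(n)) {
    s <- sim$state[i, ]
    f <- cal[min(i, length(cal))]
    m <- case_multipliers(case, f, params)
    Lg <- 1 - (s["Psc_h"] + s["Psc_d"]) / (params$lambda_cap * params$Psc_max)
    th_reg <- stem_regulation_factor(s["Pta_h"], s["Pta_d"], params)
    prolif[i] <-
      params$gamma1_hom * th_reg * m[["gamma1"]] * Lg * s["Psc_h"] +
      params$gamma2_h * m[["gamma2"]] * s["Pta_h"] +
      params$gamma1_d * m[["gamma1"]] * Lg * s["Psc_d"] +
      params$gamma2_d * m[["gamma2"]] * s["Pta_d"]
    diff_[i] <-
      (params$k1a_hom * m[["k1a"]] + 2 * params$k1s_hom * m[["k1s"]]) *
        th_reg * s["Psc_h"] +
      (params$k2a_h * m[["k2a"]] + 2 * params$k2s_h * m[["k2s"]]) * s["Pta_h"] +
      params$k3_h * m[["k3"]] * s["Pga_h"] +
      params$k4_h * m[["k4"]] * s["Psp_h"] +
      params$k5_h * m[["k5"]] * s["Pgc_h"] +
      (params$k1a_d * m[["k1a"]] + 2 * params$k1s_d * m[["k1s"]]) * s["Psc_d"] +
      (params$k2a_d * m[["k2a"]] + 2 * params$k2s_d * m[["k2s"]]) * s["Pta_d"] +
      params$k3_d * m[["k3"]] * s["Pga_d"] +
      params$k4_d * m[["k4"]] * s["Psp_d"] +
      params$k5_d * m[["k5"]] * s["Pgc_d"]
    imm[i] <- immune_killing(s[["Psc_d"]], params)
  }
  data.frame(time = sim$time, proliferative = prolif,
             differentiation = diff_, immune = imm, total = sim$total)
}
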