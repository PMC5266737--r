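#' A treatment phase
#'
#' One contiguous block of a phototherapy protocol: its length in days, the
#' session cadence, the per-session fluence, session length, irradiation
#' mode (continuous or pulsed wave) and the duty cycle for pulsed mode.
#' Intensities follow from these: the average intensity is
#' fluence/session_time and the peak intensity is average/duty_cycle (equal
#' to the average for continuous wave).
#'
#' @param days phase duration in days (> 0 integer).
#' @param cadence \code{"daily"}, \code{"every_other_day"} or
#'   \code{"three_per_week"}.
#' @param fluence per-session fluence (J/cm^2), >= 0.
#' @param session_time session length (s), > 0.
#' @param mode \code{"CW"} (continuous) or \code{"PW"} (pulsed).
#' @param duty_cycle fraction of the session during which light is on, in
#'   (0, 1]; forced to 1 for CW.
#' @return list of class \code{bluederm_phase}.
#' @export
protocol_phase <- function(days, cadence = c("daily", "every_other_day",
                                             "three_per_week"),
                           fluence = 90, session_time = 1800,
                           mode = c("CW", "PW"), duty_cycle = 1) {
  cadence <- match.arg(cadence)
  mode <- match.arg(mode)
  if (!is.numeric(days) || length(days) != 1 || days < 0 ||
      days != round(days)) {
    stop("days must be a non-negative integer")
  }
  if (!is.numeric(fluence) || fluence < 0) stop("fluence must be >= 0")
  if (!is.numeric(session_time) || session_time <= 0) {
    stop("session_time must be > 0")
  }
  if (mode == "CW") duty_cycle <- 1
  if (!is.numeric(duty_cycle) || duty_cycle <= 0 || duty_cycle > 1) {
    stop("duty_cycle must lie in (0, 1]")
  }
  structure(
    list(days = as.integer(days), cadence = cadence, fluence = fluence,
         session_time = session_time, mode = mode, duty_cycle = duty_cycle),
    class = "bluederm_phase"
  )
}

#' A treatment protocol
#'
#' Ordered list of phases followed by an untreated follow-up period.
#'
#' @param phases list of [protocol_phase()] objects (a single phase may be
#'   passed bare).
#' @param follow_up_days untreated days appended after the last phase.
#' @param three_per_week_days which days of each 7-day block carry a session
#'   under the \code{three_per_week} cadence (default 1, 3, 5 --
#'   Mon/Wed/Fri of a week starting Monday; the clinical pattern is not
#'   pinned down, any 3-of-7 choice is accepted).
#' @return list of class \code{bluederm_protocol}.
#' @export
#' @examples
#' p <- pfaff_protocol()
#' sum(build_calendar(p) > 0) # 52 session days
treatment_protocol <- function(phases, follow_up_days = 0,
                               three_per_week_days = c(1, 3, 5)) {
  if (inherits(phases, "bluederm_phase")) phases <- list(phases)
  if (!length(phases) ||
      !all(vapply(phases, inherits, TRUE, "bluederm_phase"))) {
    if (length(phases)) stop("phases must be protocol_phase objects")
  }
  if (!is.numeric(follow_up_days) || follow_up_days < 0) {
    stop("follow_up_days must be >= 0")
  }
  if (length(three_per_week_days) != 3 ||
      !all(three_per_week_days %in% 1:7) ||
      anyDuplicated(three_per_week_days)) {
    stop("three_per_week_days must be 3 distinct days in 1..7")
  }
  structure(
    list(phases = phases, follow_up_days = as.integer(follow_up_days),
         three_per_week_days = sort(as.integer(three_per_week_days))),
    class = "bluederm_protocol"
  )
}

#' The reference clinical protocol
#'
#' Twelve-week pulsed-wave regimen used in the clinical study the model is
#' benchmarked against: 4 weeks of daily sessions followed by 8 weeks of
#' three sessions per week, each session delivering 90 J/cm^2 over 30
#' minutes (average intensity 50 mW/cm^2).
#'
#' @param fluence per-session fluence (J/cm^2).
#' @param session_time session length (s).
#' @param mode irradiation mode.
#' @param duty_cycle duty cycle for pulsed mode.
#' @param follow_up_days untreated follow-up appended after week 12.
#' @return a \code{bluederm_protocol}.
#' @export
pfaff_protocol <- function(fluence = 90, session_time = 1800, mode = "PW",
                           duty_cycle = 0.5, follow_up_days = 0) {
  treatment_protocol(
    list(
      protocol_phase(28, "daily", fluence, session_time, mode, duty_cycle),
      protocol_phase(56, "three_per_week", fluence, session_time, mode,
                     duty_cycle)
    ),
    follow_up_days = follow_up_days
  )
}

#' Per-day fluence calendar of a protocol
#'
#' Expands a protocol into a day-indexed vector of applied fluences:
#' session days carry the phase's fluence, rest days and follow-up carry 0.
#' \code{every_other_day} places sessions on days 1, 3, 5, ... of the
#' phase; \code{three_per_week} uses the protocol's 3-of-7 weekday pattern
#' within each 7-day block of the phase.
#'
#' @param protocol a \code{bluederm_protocol}.
#' @return numeric vector; element i is the fluence applied on day i.
#' @export
build_calendar <- function(protocol) {
  stopifnot(inherits(protocol, "bluederm_protocol"))
  out <- numeric(0)
  for (ph in protocol$phases) {
    day_in_phase <- seq_len(ph$days)
    on <- switch(ph$cadence,
      daily = rep(TRUE, ph$days),
      every_other_day = day_in_phase %% 2 == 1,
      three_per_week = ((day_in_phase - 1) %% 7 + 1) %in%
        protocol$three_per_week_days
    )
    out <- c(out, ifelse(on, ph$fluence, 0))
  }
  c(out, numeric(protocol$follow_up_days))
}

#' Average and peak intensity of a phase
#'
#' The average intensity is the session fluence divided by the session
#' time; the peak intensity is the average divided by the duty cycle (for
#' continuous wave the two coincide). Both are reported in mW/cm^2.
#'
#' @param phase a [protocol_phase()].
#' @return named numeric vector \code{c(I_av, I_p)} in mW/cm^2.
#' @export
#' @examples
#' phase_intensities(protocol_phase(28, "daily", 90, 1800)) # I_av = 50
phase_intensities <- function(phase) {
  stopifnot(inherits(phase, "bluederm_phase"))
  if (phase$session_time <= 0) stop("session_time must be > 0")
  i_av <- phase$fluence / phase$session_time * 1000  # J/(cm^2 s) -> mW/cm^2
  c(I_av = i_av, I_p = i_av / phase$duty_cycle)
}

#' Total days covered by a protocol (treatment + follow-up)
#' @param protocol a \code{bluederm_protocol}.
#' @return integer number of days.
#' @export
protocol_days <- function(protocol) {
  sum(vapply(protocol$phases, `[[`, integer(1), "days")) +
    protocol$follow_up_days
}

#' Treatment days covered by a protocol (excluding follow-up)
#' @param protocol a \code{bluederm_protocol}.
#' @return integer number of days.
#' @export
treatment_days <- function(protocol) {
  sum(vapply(protocol$phases, `[[`, integer(1), "days"))
}

#' @export
print.bluederm_protocol <- function(x, ...) {
  cat("<bluederm_protocol>", length(x$phases), "phase(s),",
      treatment_days(x), "treatment days +", x$follow_up_days,
      "follow-up days\n")
  for (ph in x$phases) {
    ints <- phase_intensities(ph)
    cat(sprintf("  %3d d %-15s F=%g J/cm2, %s, I_av=%.3g I_p=%.3g mW/cm2\n",
                ph$days, ph$cadence, ph$fluence, ph$mode,
                ints["I_av"], ints["I_p"]))
  }
  invisible(x)
}
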