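#' Load a model configuration file
#'
#' Reads a YAML (or JSON) document with up to three top-level sections --
#' \code{parameters}, \code{state}, \code{protocol} -- and returns
#' validated model objects. Every section is optional; omitted sections
#' (and omitted keys inside \code{parameters} and \code{state}) fall back
#' to the package defaults, so a config may override a single value.
#' Unknown keys and invariant violations are reported with their key
#' paths.
#'
#' The protocol section has the form:
#' \preformatted{
#' protocol:
#'   follow_up_days: 28
#'   phases:
#'     - {days: 28, cadence: daily, fluence: 90, session_time: 1800,
#'        mode: PW, duty_cycle: 0.5}
#' }
#'
#' @param path file path.
#' @return list with \code{params}, \code{state}, \code{protocol}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (!is.list(doc)) stop("config must be a mapping")
  unknown <- setdiff(names(doc), c("parameters", "state", "protocol"))
  if (length(unknown)) {
    stop("unknown top-level section(s): ", paste(unknown, collapse = ", "))
  }
  params <- tryCatch(
    default_parameters(overrides = as.list(doc$parameters)),
    error = function(e) stop("in section 'parameters': ",
                             conditionMessage(e), call. = FALSE)
  )
  state <- if (is.null(doc$state)) {
    default_state()
  } else {
    s <- as.list(unlist(default_state()))
    over <- as.list(doc$state)
    bad <- setdiff(names(over), state_names())
    if (length(bad)) {
      stop("in section 'state': unknown component(s): ",
           paste(bad, collapse = ", "))
    }
    s[names(over)] <- over
    tryCatch(epidermis_state(s),
             error = function(e) stop("in section 'state': ",
                                      conditionMessage(e), call. = FALSE))
  }
  protocol <- if (is.null(doc$protocol)) {
    pfaff_protocol()
  } else {
    parse_protocol(doc$protocol)
  }
  list(params = params, state = state, protocol = protocol)
}

parse_protocol <- function(x) {
  phases <- lapply(x$phases, function(ph) {
    known <- c("days", "cadence", "fluence", "session_time", "mode",
               "duty_cycle")
    bad <- setdiff(names(ph), known)
    if (length(bad)) {
      stop("in section 'protocol': unknown phase key(s): ",
           paste(bad, collapse = ", "))
    }
    do.call(protocol_phase, ph)
  })
  args <- list(phases = phases)
  if (!is.null(x$follow_up_days)) args$follow_up_days <- x$follow_up_days
  if (!is.null(x$three_per_week_days)) {
    args$three_per_week_days <- x$three_per_week_days
  }
  do.call(treatment_protocol, args)
}

#' Write a configuration file
#'
#' Serializes parameters, state and protocol to a YAML document that
#' [load_config()] reads back.
#'
#' @param path output file path.
#' @param params parameter list.
#' @param state state vector.
#' @param protocol treatment protocol.
#' @return the path, invisibly.
#' @export
write_config <- function(path, params = default_parameters(),
                         state = default_state(),
                         protocol = pfaff_protocol()) {
  doc <- list(
    parameters = unclass(params),
    state = as.list(unclass(state)),
    protocol = list(
      follow_up_days = protocol$follow_up_days,
      three_per_week_days = protocol$three_per_week_days,
      phases = lapply(protocol$phases, unclass)
    )
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Run manifest
#'
#' Captures everything needed to reproduce a simulation: the full
#' parameter snapshot, protocol, hypothesis case, equation convention,
#' solver settings, seed, package version and a timestamp.
#'
#' @param sim a \code{bluederm_sim}.
#' @param seed seed used for any stochastic companion analyses (NA if
#'   none).
#' @return list of class \code{bluederm_manifest}.
#' @export
run_manifest <- function(sim, seed = NA_integer_) {
  stopifnot(inherits(sim, "bluederm_sim"))
  structure(
    list(
      package = "bluederm",
      version = as.character(utils::packageVersion("bluederm")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      parameters = unclass(sim$params),
      initial_state = as.list(sim$state[1, ]),
      protocol = list(
        follow_up_days = sim$protocol$follow_up_days,
        three_per_week_days = sim$protocol$three_per_week_days,
        phases = lapply(sim$protocol$phases, unclass)
      ),
      case = unclass(sim$case),
      convention = sim$convention,
      fluence_absorbed = sim$fluence_absorbed,
      solver = list(method = "lsoda", rtol = sim$rtol, atol = sim$atol),
      horizon_days = max(sim$time),
      seed = seed
    ),
    class = "bluederm_manifest"
  )
}

#' Write a run manifest as JSON
#' @param manifest a \code{bluederm_manifest} (or a \code{bluederm_sim},
#'   which is converted first).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  if (inherits(manifest, "bluederm_sim")) manifest <- run_manifest(manifest)
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Re-run a simulation from a manifest
#'
#' @param path JSON manifest path (or a parsed manifest list).
#' @return a \code{bluederm_sim}, reproduced to solver tolerance.
#' @export
rerun_manifest <- function(path) {
  m <- if (is.character(path)) jsonlite::read_json(path,
                                                   simplifyVector = TRUE)
       else path
  params <- default_parameters(overrides = m$parameters[
    names(m$parameters) %in% names(default_parameter_skeleton())])
  state <- epidermis_state(unlist(m$initial_state))
  phases <- lapply(seq_len(nrow_phases(m$protocol$phases)), function(i) {
    ph <- phase_record(m$protocol$phases, i)
    protocol_phase(ph$days, ph$cadence, ph$fluence, ph$session_time,
                   ph$mode, ph$duty_cycle)
  })
  protocol <- treatment_protocol(
    phases, follow_up_days = m$protocol$follow_up_days,
    three_per_week_days = unlist(m$protocol$three_per_week_days)
  )
  case <- hypothesis_case(m$case$case_id,
                          theta_k_direction = m$case$theta_k_direction,
                          theta_k_max = m$case$theta_k_max)
  simulate_treatment(params, state, protocol, case = case,
                     convention = m$convention,
                     horizon_days = m$horizon_days,
                     fluence_absorbed = isTRUE(m$fluence_absorbed),
                     rtol = m$solver$rtol, atol = m$solver$atol)
}

# jsonlite may simplify the phase list to a data.frame; support both.
nrow_phases <- function(ph) if (is.data.frame(ph)) nrow(ph) else length(ph)
phase_record <- function(ph, i) {
  if (is.data.frame(ph)) as.list(ph[i, ]) else ph[[i]]
}

#' Export a simulation as tidy CSV
#'
#' Long-format table (time, compartment, density) as produced by
#' [as.data.frame.bluederm_sim()].
#'
#' @param sim a \code{bluederm_sim}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sim_csv <- function(sim, path) {
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}
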