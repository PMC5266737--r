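#' Compartment names of the 12-dimensional epidermis state
#'
#' Order: healthy stem, transit amplifying, growth arrested, spinous,
#' granular, corneocyte, then the same six diseased compartments.
#'
#' @return character vector of length 12.
#' @export
state_names <- function() {
  c("Psc_h", "Pta_h", "Pga_h", "Psp_h", "Pgc_h", "Pcc_h",
    "Psc_d", "Pta_d", "Pga_d", "Psp_d", "Pgc_d", "Pcc_d")
}

#' Build an epidermis state vector
#'
#' @param values named numeric vector or list with the 12 compartment
#'   densities (cells/mm^2); names must match [state_names()].
#' @return named numeric vector of class \code{bluederm_state}.
#' @export
epidermis_state <- function(values) {
  values <- unlist(values)
  if (!all(state_names() %in% names(values))) {
    stop("state must name all compartments: ",
         paste(setdiff(state_names(), names(values)), collapse = ", "))
  }
  extra <- setdiff(names(values), state_names())
  if (length(extra)) {
    stop("unknown state component(s): ", paste(extra, collapse = ", "))
  }
  s <- as.numeric(values[state_names()])
  names(s) <- state_names()
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("all cell densities must be finite and non-negative")
  }
  class(s) <- c("bluederm_state", "numeric")
  s
}

#' Default initial state: a mild psoriatic epidermis
#'
#' Initial cell-density distribution of a lesional 1 mm^2 epidermis with a
#' small residual healthy population (1,042 cells/mm^2) coexisting with a
#' dominant diseased population (216,514 cells/mm^2); the total of 217,556
#' cells/mm^2 is roughly twice the density of healthy skin. The diseased
#' granular compartment is empty (parakeratosis).
#'
#' @return state vector of class \code{bluederm_state}.
#' @export
#' @examples
#' sum(default_state()) # 217556
default_state <- function() {
  epidermis_state(c(
    Psc_h = 362,  Pta_h = 77,    Pga_h = 61,    Psp_h = 238,
    Pgc_h = 119,  Pcc_h = 185,
    Psc_d = 6459, Pta_d = 32098, Pga_d = 20536, Psp_d = 79788,
    Pgc_d = 0,    Pcc_d = 77633
  ))
}

#' @export
print.bluederm_state <- function(x, ...) {
  cat("<bluederm_state> total", format(sum(x), big.mark = ","),
      "cells/mm^2\n")
  print(unclass(x))
  invisible(x)
}
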