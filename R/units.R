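#' Characteristic scales of the chromatin model
#'
#' The non-dimensional model maps to physical units through a length scale
#' \code{L} (default 5 micrometres: nuclear x-diameter of the P0 rod cell)
#' and a time scale \code{T} (default 5 hours, from matching simulated and
#' observed reorganization dynamics). The phase-field mobility is
#' \eqn{\mu = 1/T}; the products \eqn{\mu \epsilon_\phi^2} and
#' \eqn{\mu \epsilon_\psi^2} are the effective diffusion coefficients of
#' the chromatin interfaces.
#'
#' @param L length scale in micrometres.
#' @param T time scale in hours.
#' @return list with \code{L}, \code{T} and \code{mu} (= 1/T, per hour).
#' @export
chromatin_scales <- function(L = 5, T = 5) {
  stopifnot(L > 0, T > 0)
  list(L = L, T = T, mu = 1 / T)
}

#' Dimensional squared gradient coefficient
#'
#' Converts a non-dimensional squared gradient coefficient to square
#' micrometres: \eqn{\epsilon^2 = \varepsilon^2 L^2}.
#'
#' @param epsSqNondim non-dimensional squared gradient coefficient.
#' @param scales a \code{\link{chromatin_scales}}.
#' @return value in square micrometres.
#' @export
eps_sq_dimensional <- function(epsSqNondim, scales = chromatin_scales()) {
  epsSqNondim * scales$L^2
}

#' Interface diffusion coefficient
#'
#' \eqn{\mu \epsilon^2} in square micrometres per hour, the effective
#' diffusivity of a chromatin interface.
#'
#' @param epsSqNondim non-dimensional squared gradient coefficient.
#' @param scales a \code{\link{chromatin_scales}}.
#' @return diffusion coefficient in um^2/h.
#' @export
diffusion_coefficient <- function(epsSqNondim, scales = chromatin_scales()) {
  scales$mu * eps_sq_dimensional(epsSqNondim, scales)
}
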