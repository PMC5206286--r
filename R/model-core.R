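#' Smooth interpolation function h
#'
#' Maps a phase-field value to an effective occupancy. \code{h} is the
#' standard quintic interpolant \eqn{h(u) = u^3 (10 - 15 u + 6 u^2)}: it fixes
#' 0 and 1, is monotone on \[0, 1\], and has vanishing derivative at both
#' wells, so bulk regions contribute 0 or 1 to volume integrals regardless of
#' small excursions.
#'
#' @param u numeric scalar, vector, matrix or array.
#' @return object of the same shape as \code{u}.
#' @examples
#' interp_h(c(0, 0.5, 1))
#' @export
interp_h <- function(u) {
  u * u * u * (10 - 15 * u + 6 * u * u)
}

#' Derivative of the interpolation function
#'
#' \eqn{h'(u) = 30 u^2 (1-u)^2}. Used by the energy bookkeeping; the solver
#' absorbs it into the assembled reaction terms.
#'
#' @param u numeric object.
#' @return same shape as \code{u}.
#' @export
interp_h_prime <- function(u) {
  30 * (u * (1 - u))^2
}

#' Double-well bulk potential g
#'
#' \eqn{g(u) = u^2 (1-u)^2 / 4}, the bistable bulk energy with minima of
#' value 0 at \eqn{u = 0} and \eqn{u = 1}. Its negative derivative is the
#' reaction kernel \eqn{u (1-u) (u - 1/2)} that appears in the evolution
#' equations, which fixes the normalization.
#'
#' @param u numeric object.
#' @return same shape as \code{u}.
#' @examples
#' doublewell_g(c(0, 0.5, 1))
#' @export
doublewell_g <- function(u) {
  (u * (1 - u))^2 / 4
}

#' Model parameters for the chromatin phase-field energy
#'
#' Bundles the (dimensionless) coefficients of the energy: volume-constraint
#' intensities (\code{alpha0} full nuclear occupancy, \code{alphaV}
#' chromosome volume, \code{alphav} heterochromatin volume), domain-restriction
#' intensities (\code{beta0} confinement to the nucleus, \code{betaPhi}
#' territory exclusion between chromosomes, \code{betaPsi} confinement of
#' heterochromatin to chromosomes), the envelope-heterochromatin affinity
#' \code{gamma} (positive when LBR/lamin A tethering is present, 0 when
#' absent), and the squared gradient coefficients \code{epsPhiSq},
#' \code{epsPsiSq} that set the diffuse-interface (intermingling) widths.
#'
#' Defaults are the representative set: \code{alpha0 = 25/6},
#' \code{alphaV = 10/6}, \code{alphav = 20/3}, \code{beta0 = 5/3},
#' \code{betaPhi = 1}, \code{betaPsi = 2/3}.
#'
#' @param alpha0,alphaV,alphav volume-energy coefficients (>= 0).
#' @param beta0,betaPhi,betaPsi domain-restriction coefficients (>= 0).
#' @param gamma envelope-heterochromatin affinity (>= 0).
#' @param epsPhiSq,epsPsiSq squared gradient coefficients (> 0),
#'   non-dimensional (length^2 in units of the domain scale).
#' @param mobility length-3 positive multipliers for the nucleus, chromosome
#'   and heterochromatin fields (the nucleus one is carried for completeness;
#'   the nucleus field is prescribed, not evolved).
#' @param N number of chromosome fields (>= 1).
#' @return an object of class \code{"chromatin_params"} (a named list).
#' @export
model_params <- function(alpha0 = 25 / 6, alphaV = 10 / 6, alphav = 20 / 3,
                         beta0 = 5 / 3, betaPhi = 1, betaPsi = 2 / 3,
                         gamma = 0, epsPhiSq = 2e-4, epsPsiSq = 6e-4,
                         mobility = c(1, 1, 1), N = 8L) {
  p <- list(alpha0 = alpha0, alphaV = alphaV, alphav = alphav,
            beta0 = beta0, betaPhi = betaPhi, betaPsi = betaPsi,
            gamma = gamma, epsPhiSq = epsPhiSq, epsPsiSq = epsPsiSq,
            mobility = rep_len(as.numeric(mobility), 3L), N = as.integer(N))
  validate_model_params(p)
  class(p) <- "chromatin_params"
  p
}

validate_model_params <- function(p) {
  nn <- c("alpha0", "alphaV", "alphav", "beta0", "betaPhi", "betaPsi", "gamma")
  for (f in nn) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) ||
        p[[f]] < 0) {
      stop(sprintf("'%s' must be a single finite non-negative number", f))
    }
  }
  if (p$epsPhiSq <= 0 || p$epsPsiSq <= 0) {
    stop("'epsPhiSq' and 'epsPsiSq' must be positive")
  }
  if (any(p$mobility <= 0)) stop("mobility multipliers must be positive")
  if (p$N < 1L) stop("'N' must be >= 1")
  invisible(p)
}

#' Heterochromatin conversion schedule and volume targets
#'
#' Describes the target-volume rules of the two architecture regimes.
#' In the \emph{conventional} regime the targets are constants:
#' per-chromosome \code{VbarM} and \code{vbarM}. In the \emph{inverted}
#' regime the chromosome target contracts to \code{r * VbarM} and the
#' heterochromatin target tracks \code{rho_m(t) * V_m(t)}, where the
#' conversion fraction \eqn{\rho_m(t)} rises monotonically from
#' \code{rhoM0} towards \code{rhoM0 + rhoBarM} along either the sigmoid
#' \deqn{\rho_m(t) = \rho_m(0) + \bar\rho_m t / (t + \alpha_1 e^{-\alpha_2 (t - t^*)})}
#' (\code{variant = "sigmoid"}) or the saturating form
#' \eqn{\rho_m(0) + \bar\rho_m t / (10 + t)} (\code{variant = "saturating"}).
#'
#' @param regime \code{"conventional"} or \code{"inverted"}.
#' @param VbarM per-chromosome target volumes (area on the non-dimensional
#'   grid), length N.
#' @param vbarM per-chromosome heterochromatin target volumes (conventional
#'   regime only).
#' @param r chromosome-volume contraction ratio in (0, 1\] (inverted regime).
#' @param rhoM0 per-chromosome initial conversion fractions
#'   \eqn{v_m(0)/V_m(0)}.
#' @param rhoBarM per-chromosome asymptotic increases of the conversion
#'   fraction.
#' @param alpha1,alpha2,tStar sigmoid shape parameters (recycled to length N).
#' @param variant \code{"sigmoid"} or \code{"saturating"}.
#' @return object of class \code{"conversion_schedule"}.
#' @export
conversion_schedule <- function(regime = c("conventional", "inverted"),
                                VbarM, vbarM = NULL, r = 1,
                                rhoM0 = NULL, rhoBarM = NULL,
                                alpha1 = 120, alpha2 = 0.03, tStar = 120,
                                variant = c("sigmoid", "saturating")) {
  regime <- match.arg(regime)
  variant <- match.arg(variant)
  N <- length(VbarM)
  if (any(!is.finite(VbarM)) || any(VbarM <= 0)) stop("'VbarM' must be positive")
  if (regime == "conventional") {
    if (is.null(vbarM)) stop("conventional regime requires 'vbarM'")
    vbarM <- rep_len(vbarM, N)
    if (any(vbarM < 0) || any(vbarM > VbarM)) {
      stop("'vbarM' must satisfy 0 <= vbarM <= VbarM")
    }
  } else {
    if (r <= 0 || r > 1) stop("'r' must lie in (0, 1]")
    if (is.null(rhoM0) || is.null(rhoBarM)) {
      stop("inverted regime requires 'rhoM0' and 'rhoBarM'")
    }
    rhoM0 <- rep_len(rhoM0, N)
    rhoBarM <- rep_len(rhoBarM, N)
    if (any(rhoM0 < 0) || any(rhoM0 + rhoBarM > 1) || any(rhoBarM < 0)) {
      stop("need 0 <= rhoM0 and rhoM0 + rhoBarM <= 1 for every chromosome")
    }
  }
  s <- list(regime = regime, VbarM = as.numeric(VbarM),
            vbarM = if (is.null(vbarM)) NULL else as.numeric(vbarM),
            r = r,
            rhoM0 = if (is.null(rhoM0)) NULL else as.numeric(rhoM0),
            rhoBarM = if (is.null(rhoBarM)) NULL else as.numeric(rhoBarM),
            alpha1 = rep_len(as.numeric(alpha1), N),
            alpha2 = rep_len(as.numeric(alpha2), N),
            tStar = rep_len(as.numeric(tStar), N),
            variant = variant, N = N)
  class(s) <- "conversion_schedule"
  s
}

#' Conversion fraction rho_m(t)
#'
#' Evaluates the heterochromatin conversion fraction of chromosome \code{m}
#' at time \code{t} under an inverted-regime schedule. Monotone
#' non-decreasing in \code{t}; equals \code{rhoM0[m]} at \code{t = 0} and
#' tends to \code{rhoM0[m] + rhoBarM[m]} as \code{t} grows.
#'
#' @param t non-dimensional time (scalar or vector, >= 0).
#' @param m chromosome index.
#' @param sched a \code{\link{conversion_schedule}} with
#'   \code{regime = "inverted"}.
#' @return numeric of the same length as \code{t}.
#' @export
rho_m <- function(t, m, sched) {
  stopifnot(inherits(sched, "conversion_schedule"))
  if (sched$regime != "inverted") {
    stop("rho_m is defined for the inverted regime only")
  }
  if (any(t < 0)) stop("'t' must be non-negative")
  if (sched$variant == "sigmoid") {
    den <- t + sched$alpha1[m] * exp(-sched$alpha2[m] * (t - sched$tStar[m]))
    sched$rhoM0[m] + sched$rhoBarM[m] * t / den
  } else {
    sched$rhoM0[m] + sched$rhoBarM[m] * t / (10 + t)
  }
}

#' Chromosome and heterochromatin volumes
#'
#' Midpoint Riemann sums \eqn{V_m = \int h(\phi_m)} and
#' \eqn{v_m = \int h(\phi_m) h(\psi)} over the domain.
#'
#' @param state a \code{\link{simulation_state}}.
#' @return list with numeric vectors \code{V} and \code{v} of length N.
#' @export
volumes <- function(state) {
  stopifnot(inherits(state, "simulation_state"))
  if (!all(is.finite(state$phi)) || !all(is.finite(state$psi))) {
    stop("non-finite field values in state at t = ", format(state$t))
  }
  dA <- state$grid$dx * state$grid$dy
  hpsi <- interp_h(state$psi)
  N <- dim(state$phi)[3]
  V <- numeric(N)
  v <- numeric(N)
  for (m in seq_len(N)) {
    hp <- interp_h(state$phi[, , m])
    V[m] <- sum(hp) * dA
    v[m] <- sum(hp * hpsi) * dA
  }
  list(V = V, v = v)
}

#' Total territory occupancy field
#'
#' \eqn{\chi = \sum_m h(\phi_m)}, shared by all reaction terms of one step.
#'
#' @param state a \code{\link{simulation_state}}.
#' @return matrix of the grid shape.
#' @export
chi_field <- function(state) {
  N <- dim(state$phi)[3]
  chi <- matrix(0, nrow = state$grid$nx, ncol = state$grid$ny)
  for (m in seq_len(N)) chi <- chi + interp_h(state$phi[, , m])
  chi
}

# Effective targets at time t: list(Vbar, vbar) per chromosome.
# Inverted regime: Vbar = r * VbarM, vbar = rho_m(t) * V_m(t) (needs vols).
schedule_targets <- function(sched, t, vols) {
  if (sched$regime == "conventional") {
    list(Vbar = sched$VbarM, vbar = sched$vbarM, rho = NULL)
  } else {
    rho <- vapply(seq_len(sched$N), function(m) rho_m(t, m, sched), numeric(1))
    list(Vbar = sched$r * sched$VbarM, vbar = rho * vols$V, rho = rho)
  }
}

#' Reaction coefficient field A_m
#'
#' Assembles the spatial coefficient field \eqn{A_m} driving chromosome
#' field \code{m}. Conventional regime:
#' \deqn{A_m = 60\alpha_V (V_m - \bar V_m) + 60\alpha_v (v_m - \bar v_m) h(\psi)
#'  - 60\alpha_0 [\int(1 - h(\phi_0)) - \sum_n V_n]
#'  + 30\beta_0 h(\phi_0) + 30\beta_\phi [\chi - h(\phi_m)] - 30\beta_\psi h(\psi).}
#' Inverted regime: the volume terms become
#' \eqn{60\alpha_V (V_m - r \bar V_m)} and
#' \eqn{60\alpha_v (v_m - \rho_m V_m)(h(\psi) - \rho_m)} with
#' \eqn{\rho_m = \rho_m(t)} evaluated at the state's time.
#'
#' @param m chromosome index.
#' @param state a \code{\link{simulation_state}}.
#' @param params a \code{\link{model_params}}.
#' @param sched a \code{\link{conversion_schedule}}; its regime selects the
#'   variant.
#' @param chi precomputed \code{\link{chi_field}} for this state.
#' @param nucVol current nuclear volume \eqn{\int (1 - h(\phi_0))}.
#' @return matrix of the grid shape.
#' @export
reaction_A <- function(m, state, params, sched, chi = chi_field(state),
                       nucVol = nuclear_volume(state$phi0, state$grid)) {
  vols <- volumes(state)
  tg <- schedule_targets(sched, state$t, vols)
  hpsi <- interp_h(state$psi)
  hp <- interp_h(state$phi[, , m])
  occ <- -60 * params$alpha0 * (nucVol - sum(vols$V))
  out <- occ +
    30 * params$beta0 * interp_h(state$phi0) +
    30 * params$betaPhi * (chi - hp) -
    30 * params$betaPsi * hpsi
  if (sched$regime == "conventional") {
    out <- out + 60 * params$alphaV * (vols$V[m] - tg$Vbar[m]) +
      60 * params$alphav * (vols$v[m] - tg$vbar[m]) * hpsi
  } else {
    out <- out + 60 * params$alphaV * (vols$V[m] - tg$Vbar[m]) +
      60 * params$alphav * (vols$v[m] - tg$rho[m] * vols$V[m]) *
        (hpsi - tg$rho[m])
  }
  out
}

#' Reaction coefficient field B
#'
#' Assembles the coefficient field driving the heterochromatin field:
#' \deqn{B = 60\alpha_v \sum_m (v_m - \bar v_m) h(\phi_m)
#'  + 30\beta_\psi (1 - \chi) - 30\gamma \nabla^2 h(\phi_0),}
#' with \eqn{\bar v_m} replaced by \eqn{\rho_m(t) V_m} in the inverted
#' regime.
#'
#' @inheritParams reaction_A
#' @param lapH0 discrete Laplacian of \eqn{h(\phi_0)} (supply the solver's
#'   operator; defaults to \code{\link{laplacian}} of \code{interp_h(phi0)}).
#' @return matrix of the grid shape.
#' @export
reaction_B <- function(state, params, sched, chi = chi_field(state),
                       lapH0 = laplacian(interp_h(state$phi0),
                                         state$grid$dx, state$grid$dy)) {
  vols <- volumes(state)
  tg <- schedule_targets(sched, state$t, vols)
  out <- 30 * params$betaPsi * (1 - chi) - 30 * params$gamma * lapH0
  for (m in seq_len(sched$N)) {
    out <- out + 60 * params$alphav * (vols$v[m] - tg$vbar[m]) *
      interp_h(state$phi[, , m])
  }
  out
}

#' Diagnostic energy decomposition
#'
#' Evaluates the four energy terms by midpoint Riemann sums with
#' central-difference gradients: the basal gradient + double-well energy
#' (\code{E0}), the domain-restriction energy (\code{E1}; the
#' territory-exclusion sum counts each unordered chromosome pair once, which
#' is the convention consistent with the reaction terms), the volume-target
#' energy (\code{E2}) and the envelope-affinity energy (\code{E3}).
#' Diagnostic only: the dynamics integrates the reaction fields, not this
#' evaluation.
#'
#' @inheritParams reaction_A
#' @return named numeric vector \code{c(E0, E1, E2, E3, E)}.
#' @export
total_energy <- function(state, params, sched) {
  g <- state$grid
  dA <- g$dx * g$dy
  N <- dim(state$phi)[3]
  hphi <- lapply(seq_len(N), function(m) interp_h(state$phi[, , m]))
  hpsi <- interp_h(state$psi)
  h0 <- interp_h(state$phi0)
  vols <- volumes(state)
  tg <- schedule_targets(sched, state$t, vols)
  nucVol <- sum(1 - h0) * dA

  grad_sq <- function(f) {
    gx <- grad_x(f, g$dx)
    gy <- grad_y(f, g$dy)
    gx * gx + gy * gy
  }
  E0 <- 0
  for (m in seq_len(N)) {
    E0 <- E0 + sum(params$epsPhiSq / 2 * grad_sq(state$phi[, , m]) +
                     doublewell_g(state$phi[, , m])) * dA
  }
  E0 <- E0 + sum(params$epsPsiSq / 2 * grad_sq(state$psi) +
                   doublewell_g(state$psi)) * dA

  chi <- Reduce(`+`, hphi)
  E1 <- 0
  for (m in seq_len(N)) E1 <- E1 + params$beta0 * sum(h0 * hphi[[m]]) * dA
  E1 <- E1 + params$betaPsi * sum((1 - chi) * hpsi) * dA
  if (N > 1) {
    for (m in seq_len(N - 1)) {
      for (n in seq.int(m + 1, N)) {
        E1 <- E1 + params$betaPhi * sum(hphi[[m]] * hphi[[n]]) * dA
      }
    }
  }

  E2 <- params$alpha0 * (nucVol - sum(vols$V))^2 +
    params$alphaV * sum((vols$V - tg$Vbar)^2) +
    params$alphav * sum((vols$v - tg$vbar)^2)

  E3 <- params$gamma *
    sum(grad_x(h0, g$dx) * grad_x(hpsi, g$dx) +
          grad_y(h0, g$dy) * grad_y(hpsi, g$dy)) * dA

  c(E0 = E0, E1 = E1, E2 = E2, E3 = E3, E = E0 + E1 + E2 + E3)
}

# central-difference gradients with mirror boundaries (zero-flux)
grad_x <- function(f, dx) {
  nx <- nrow(f)
  up <- f[c(2:nx, nx), , drop = FALSE]
  dn <- f[c(1, 1:(nx - 1)), , drop = FALSE]
  (up - dn) / (2 * dx)
}
grad_y <- function(f, dy) {
  ny <- ncol(f)
  up <- f[, c(2:ny, ny), drop = FALSE]
  dn <- f[, c(1, 1:(ny - 1)), drop = FALSE]
  (up - dn) / (2 * dy)
}
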