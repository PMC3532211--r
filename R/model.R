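## Dynamical core: rate functions, the 9-dimensional right-hand side, and
## per-equilibrium fishery metrics.

#' State vector layout
#'
#' Names of the nine biomass densities (g/L), in the fixed order used by
#' every function in the package: the plaice-exclusive, sole-exclusive and
#' shared resources, then the plaice stages (J, LJ, A), then the sole stages.
#'
#' @return character vector of length 9.
#' @export
state_names <- function() {
  c("R_p", "R_s", "R_sh", "J_p", "LJ_p", "A_p", "J_s", "LJ_s", "A_s")
}

#' Construct a state vector
#'
#' @param R_p,R_s,R_sh resource biomass densities (g/L).
#' @param J_p,LJ_p,A_p plaice stage biomass densities (g/L).
#' @param J_s,LJ_s,A_s sole stage biomass densities (g/L).
#' @return named numeric vector in the canonical order of [state_names()].
#' @export
make_state <- function(R_p = 0, R_s = 0, R_sh = 0, J_p = 0, LJ_p = 0,
                       A_p = 0, J_s = 0, LJ_s = 0, A_s = 0) {
  x <- c(R_p, R_s, R_sh, J_p, LJ_p, A_p, J_s, LJ_s, A_s)
  if (anyNA(x) || any(x < 0))
    stop("state components must be non-negative and finite", call. = FALSE)
  setNames(x, state_names())
}

#' Split the resource maximum by the overlap fraction
#'
#' The non-plaice-exclusive resource base `K_m` is divided between the
#' sole-exclusive resource and the shared resource: `K_sole =
#' (1 - omega) * K_m`, `K_shared = omega * K_m`. The split conserves `K_m`
#' exactly; `omega = 0` gives sole a private resource and no competition,
#' `omega = 1` leaves sole only the shared resource.
#'
#' @param K_m resource maximum to split (g/L), positive.
#' @param omega overlap fraction in `[0, 1]`.
#' @return named numeric `c(K_sole=, K_shared=)`.
#' @export
split_resource_maxima <- function(K_m, omega) {
  stopifnot(K_m > 0)
  if (is.na(omega) || omega < 0 || omega > 1)
    stop("omega must lie in [0, 1]", call. = FALSE)
  K_sole <- (1 - omega) * K_m
  c(K_sole = K_sole, K_shared = K_m - K_sole)  # conserves K_m exactly
}

#' Holling type-II ingestion over an exclusive and a shared resource
#'
#' Total mass-specific ingestion of a consumer stage feeding on its exclusive
#' resource and the shared resource: `I_max * (R_own + R_sh) / (R_h + R_own +
#' R_sh)`. The two resources enter additively with equal weight; intake is
#' split between them in proportion to their densities (no preference).
#'
#' @param R_own density of the species' exclusive resource (g/L).
#' @param R_sh density of the shared resource (g/L).
#' @param I_max maximum mass-specific ingestion rate (g g^-1 d^-1).
#' @param R_h half-saturation density (g/L), positive.
#' @return named numeric `c(total=, frac_own=, frac_shared=)`; the fractions
#'   sum to 1 when any food is present and are 0 at zero food.
#' @export
ingestion <- function(R_own, R_sh, I_max, R_h) {
  stopifnot(R_h > 0, I_max >= 0)
  if (is.na(R_own) || is.na(R_sh) || R_own < 0 || R_sh < 0)
    stop("resource densities must be non-negative", call. = FALSE)
  avail <- R_own + R_sh
  total <- I_max * avail / (R_h + avail)
  if (avail > 0)
    c(total = total, frac_own = R_own / avail, frac_shared = R_sh / avail)
  else
    c(total = 0, frac_own = 0, frac_shared = 0)
}

#' Net biomass production rate
#'
#' Assimilated intake minus maintenance, per unit body mass:
#' `nu = delta * IR - T`. Negative values are meaningful and indicate
#' starvation (biomass loss).
#'
#' @param IR mass-specific ingestion rate (g g^-1 d^-1), non-negative.
#' @param delta food conversion efficiency.
#' @param T_maint mass-specific maintenance rate (g g^-1 d^-1).
#' @return net production rate (g g^-1 d^-1), possibly negative.
#' @export
net_production <- function(IR, delta, T_maint) {
  if (any(IR < 0)) stop("ingestion rate must be non-negative", call. = FALSE)
  delta * IR - T_maint
}

#' Stage maturation rate
#'
#' Rate at which biomass flows out of a stage into the next, given the
#' stage's net production `nu`, its total mortality `mu_total` (background
#' plus any fishing) and the entry-to-exit mass ratio `z`:
#' `gamma = (nu - mu_total) / (1 - z^(1 - mu_total/nu))` for `nu > 0`.
#' When net production is non-positive no individual reaches the stage exit
#' size, so `gamma = 0`. The removable singularity at `nu = mu_total` is
#' evaluated by its limit `-nu / ln(z)`; the function is continuous in `nu`
#' across that point.
#'
#' @param nu stage net biomass production (g g^-1 d^-1); any sign.
#' @param mu_total total per-capita mortality in the stage (d^-1),
#'   non-negative.
#' @param z stage entry-to-exit mass ratio, in (0, 1).
#' @return maturation rate (d^-1), non-negative.
#' @export
maturation_rate <- function(nu, mu_total, z) {
  if (is.na(z) || z <= 0 || z >= 1)
    stop("z must lie strictly between 0 and 1", call. = FALSE)
  stopifnot(mu_total >= 0)
  if (nu <= 0) return(0)
  expo <- 1 - mu_total / nu
  if (abs(expo) < 1e-9) -nu / log(z) else (nu - mu_total) / (1 - z^expo)
}

#' Fishing mortality of a stage
#'
#' Linear harvesting: a single fleet-wide effort modulated by the stage's
#' relative catchability, `F = f * E`. Only large juveniles and adults carry
#' non-zero catchability.
#'
#' @param f relative catchability (d^-1 per unit effort), non-negative.
#' @param E harvesting effort (arbitrary unit), non-negative.
#' @return fishing mortality rate (d^-1).
#' @export
fishing_mortality <- function(f, E) {
  if (any(f < 0) || any(E < 0))
    stop("catchability and effort must be non-negative", call. = FALSE)
  f * E
}

# Per-species stage rates at a given resource environment. Returns the
# pieces the RHS and the bookkeeping tests need: nu per stage, maturation
# rates, mortality rates, and the grazing pressure the stages exert on each
# resource (g/L/d).
species_rates <- function(sp, B, R_own, R_sh, R_h, E) {
  avail <- R_own + R_sh
  denom <- R_h + avail
  IR <- sp$I_max * avail / denom           # per-stage mass-specific intake
  nu <- sp$delta * IR - sp$T_maint
  mu_st <- c(J = sp$mu,
             LJ = sp$mu + sp$f[["LJ"]] * E,
             A = sp$mu + sp$f[["A"]] * E)
  gamma <- c(J = maturation_rate(nu[["J"]], mu_st[["J"]], sp$z[["J"]]),
             LJ = maturation_rate(nu[["LJ"]], mu_st[["LJ"]], sp$z[["LJ"]]))
  graze_total <- sum(sp$I_max * B) / denom # per unit resource density
  list(IR = IR, nu = nu, mu = mu_st, gamma = gamma,
       graze_own = graze_total * R_own, graze_sh = graze_total * R_sh)
}

#' Time derivative of the full system state
#'
#' Right-hand side of the nine coupled ODEs. Resources follow semi-chemostat
#' dynamics `dR/dt = r (K - R)` minus grazing; consumer stages gain biomass
#' by somatic growth (`nu` applied to the standing stock), maturation inflow
#' and -- for small juveniles -- reproduction `max(nu_A, 0) * A`, and lose it
#' to maturation, background mortality and fishing. Negative net production
#' acts as starvation loss within the stage; starving stages neither mature
#' nor reproduce.
#'
#' @param state named or unnamed numeric vector in [state_names()] order,
#'   non-negative.
#' @param params a [flatmix_params()] object.
#' @param E harvesting effort, non-negative.
#' @param omega optional overlap override; defaults to
#'   `params$resources$omega`.
#' @return named derivative vector (g L^-1 d^-1) in the same order.
#' @export
rhs <- function(state, params, E, omega = NULL) {
  if (anyNA(state) || any(state < 0))
    stop("state must be non-negative and finite", call. = FALSE)
  if (is.na(E) || E < 0) stop("effort must be non-negative", call. = FALSE)
  res <- params$resources
  if (is.null(omega)) omega <- res$omega
  K <- split_resource_maxima(res$K_m, omega)

  R_p <- state[[1]]; R_s <- state[[2]]; R_sh <- state[[3]]
  Bp <- c(J = state[[4]], LJ = state[[5]], A = state[[6]])
  Bs <- c(J = state[[7]], LJ = state[[8]], A = state[[9]])

  rp <- species_rates(params$species$plaice, Bp, R_p, R_sh, res$R_h, E)
  rs <- species_rates(params$species$sole, Bs, R_s, R_sh, res$R_h, E)

  dR_p <- res$r * (res$K_p - R_p) - rp$graze_own
  dR_s <- res$r * (K[["K_sole"]] - R_s) - rs$graze_own
  dR_sh <- res$r * (K[["K_shared"]] - R_sh) - rp$graze_sh - rs$graze_sh

  stage_deriv <- function(B, rt) {
    nuA_pos <- max(rt$nu[["A"]], 0)
    dJ <- nuA_pos * B[["A"]] + rt$nu[["J"]] * B[["J"]] -
      rt$gamma[["J"]] * B[["J"]] - rt$mu[["J"]] * B[["J"]]
    dLJ <- rt$gamma[["J"]] * B[["J"]] + rt$nu[["LJ"]] * B[["LJ"]] -
      rt$gamma[["LJ"]] * B[["LJ"]] - rt$mu[["LJ"]] * B[["LJ"]]
    dA <- rt$gamma[["LJ"]] * B[["LJ"]] + min(rt$nu[["A"]], 0) * B[["A"]] -
      rt$mu[["A"]] * B[["A"]]
    c(dJ, dLJ, dA)
  }

  setNames(c(dR_p, dR_s, dR_sh, stage_deriv(Bp, rp), stage_deriv(Bs, rs)),
           state_names())
}

# deSolve-compatible wrapper.
rhs_desolve <- function(t, y, parms) {
  y[y < 0 & y > -1e-12] <- 0  # absorb round-off undershoot from the stepper
  y[y < 0] <- 0
  list(rhs(y, parms$params, parms$E, parms$omega))
}

#' Landings, discards and revenue at a state
#'
#' Instantaneous fishery flows at a system state: adults are landed
#' (`f_A * E * A`), large juveniles are caught and discarded
#' (`f_LJ * E * LJ`). Revenue is price times landed biomass with the g-to-kg
#' conversion made explicit, so its unit is EUR per litre of habitat per day.
#' The discard ratio (discards over landings) is `NA` when a species has no
#' landings.
#'
#' @inheritParams rhs
#' @return a list of class `flatmix_metrics` with per-species named vectors
#'   `landings`, `discards`, `discard_ratio`, `revenue` (plaice, sole) and
#'   scalar `revenue_total`.
#' @export
fishery_metrics <- function(state, params, E, omega = NULL) {
  if (anyNA(state) || any(state < 0))
    stop("state must be non-negative and finite", call. = FALSE)
  if (is.na(E) || E < 0) stop("effort must be non-negative", call. = FALSE)
  sp_names <- c("plaice", "sole")
  LJ <- c(plaice = state[[5]], sole = state[[8]])
  A <- c(plaice = state[[6]], sole = state[[9]])
  landings <- discards <- revenue <- ratio <- setNames(numeric(2), sp_names)
  for (nm in sp_names) {
    sp <- params$species[[nm]]
    landings[nm] <- fishing_mortality(sp$f[["A"]], E) * A[nm]
    discards[nm] <- fishing_mortality(sp$f[["LJ"]], E) * LJ[nm]
    revenue[nm] <- sp$price * (A[nm] / 1000) * sp$f[["A"]] * E
    ratio[nm] <- if (landings[nm] > 0) discards[nm] / landings[nm] else NA_real_
  }
  structure(list(landings = landings, discards = discards,
                 discard_ratio = ratio, revenue = revenue,
                 revenue_total = sum(revenue)),
            class = "flatmix_metrics")
}
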