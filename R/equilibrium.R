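## Equilibrium computation: stiff integration to the attractor, damped Newton
## polishing, natural-parameter continuation over effort/overlap grids, and
## detection of extinction thresholds and revenue maxima.

# Internal un-validated RHS: identical arithmetic to rhs() but tolerant of the
# small negative excursions a Newton iterate can take (R_h > 0 keeps the
# functional-response denominator away from zero there).
rhs_unsafe <- function(state, params, E, omega) {
  res <- params$resources
  K <- (1 - omega) * res$K_m
  K <- c(K, res$K_m - K)
  R_p <- state[[1]]; R_s <- state[[2]]; R_sh <- state[[3]]
  Bp <- c(J = state[[4]], LJ = state[[5]], A = state[[6]])
  Bs <- c(J = state[[7]], LJ = state[[8]], A = state[[9]])
  rp <- species_rates(params$species$plaice, Bp, R_p, R_sh, res$R_h, E)
  rs <- species_rates(params$species$sole, Bs, R_s, R_sh, res$R_h, E)
  dR_p <- res$r * (res$K_p - R_p) - rp$graze_own
  dR_s <- res$r * (K[[1]] - R_s) - rs$graze_own
  dR_sh <- res$r * (K[[2]] - R_sh) - rp$graze_sh - rs$graze_sh
  sd <- function(B, rt) {
    nuA_pos <- max(rt$nu[["A"]], 0)
    c(nuA_pos * B[["A"]] + (rt$nu[["J"]] - rt$gamma[["J"]] - rt$mu[["J"]]) * B[["J"]],
      rt$gamma[["J"]] * B[["J"]] +
        (rt$nu[["LJ"]] - rt$gamma[["LJ"]] - rt$mu[["LJ"]]) * B[["LJ"]],
      rt$gamma[["LJ"]] * B[["LJ"]] +
        (min(rt$nu[["A"]], 0) - rt$mu[["A"]]) * B[["A"]])
  }
  c(dR_p, dR_s, dR_sh, sd(Bp, rp), sd(Bs, rs))
}

#' Solver control settings
#'
#' @param int_tol relative state change over a probe window below which the
#'   integration phase is considered settled.
#' @param res_tol max-norm residual of the time derivative required of a
#'   polished equilibrium (g L^-1 d^-1).
#' @param extinct_tol total biomass (g/L) below which a species is recorded
#'   extinct, clamped to zero and the equilibrium re-polished.
#' @param t_chunk initial integration probe window (days); grows geometrically.
#' @param t_max total integration time cap (days).
#' @param max_newton maximum damped-Newton iterations per polish.
#' @param seed_density default consumer stage density (g/L) used to seed a
#'   cold start.
#' @return a named list of class `flatmix_control`.
#' @export
flatmix_control <- function(int_tol = 1e-8, res_tol = 1e-9,
                            extinct_tol = 1e-9, t_chunk = 2500,
                            t_max = 2e6, max_newton = 60,
                            seed_density = 1e-3) {
  structure(list(int_tol = int_tol, res_tol = res_tol,
                 extinct_tol = extinct_tol, t_chunk = t_chunk, t_max = t_max,
                 max_newton = max_newton, seed_density = seed_density),
            class = "flatmix_control")
}

#' Standard cold-start state
#'
#' Resources at their consumer-free maxima (for the given overlap), every
#' consumer stage at a small uniform seed density.
#'
#' @inheritParams solve_equilibrium
#' @param seed_density consumer stage seed density (g/L).
#' @return a named state vector.
#' @export
default_init_state <- function(params, omega = NULL, seed_density = 1e-3) {
  res <- params$resources
  if (is.null(omega)) omega <- res$omega
  K <- split_resource_maxima(res$K_m, omega)
  make_state(R_p = res$K_p, R_s = K[["K_sole"]], R_sh = K[["K_shared"]],
             J_p = seed_density, LJ_p = seed_density, A_p = seed_density,
             J_s = seed_density, LJ_s = seed_density, A_s = seed_density)
}

species_idx <- list(plaice = 4:6, sole = 7:9)

# Integrate until the relative state change over a growing probe window drops
# below int_tol (or t_max is hit). Returns the endpoint and time used.
integrate_to_steady <- function(state, params, E, omega, control) {
  parms <- list(params = params, E = E, omega = omega)
  t_used <- 0; chunk <- control$t_chunk
  repeat {
    sol <- suppressWarnings(
      deSolve::ode(y = state, times = c(0, chunk), func = rhs_desolve,
                   parms = parms, method = "lsoda",
                   rtol = 1e-8, atol = 1e-12, maxsteps = 100000))
    new <- pmax(sol[nrow(sol), -1], 0)
    t_used <- t_used + chunk
    delta <- max(abs(new - state) / (abs(new) + 1e-8))
    state <- new
    if (delta < control$int_tol || t_used >= control$t_max) break
    chunk <- min(chunk * 2, 64 * control$t_chunk, control$t_max - t_used)
  }
  list(state = setNames(state, state_names()), t = t_used,
       settled = delta < control$int_tol)
}

#' Invasion growth rate of a species at a given resource environment
#'
#' Dominant eigenvalue of the linearized stage dynamics (J, LJ, A) of one
#' species at fixed resource densities -- the per-day growth rate of a
#' vanishingly rare population. Its sign decides whether an extinct species
#' can re-invade the resident equilibrium; the transcritical extinction
#' threshold is exactly where it crosses zero.
#'
#' @param params a [flatmix_params()] object.
#' @param species `"plaice"` or `"sole"`.
#' @param state system state supplying the resource densities (consumer
#'   components are ignored; the species is treated as rare).
#' @param E harvesting effort.
#' @param omega unused placeholder for signature symmetry; the rates depend
#'   only on `state` and `E`.
#' @return the dominant eigenvalue (d^-1); positive means invadable.
#' @export
invasion_rate <- function(params, species, state, E, omega = NULL) {
  sp <- params$species[[species]]
  R_own <- if (species == "plaice") state[[1]] else state[[2]]
  rt <- species_rates(sp, c(J = 0, LJ = 0, A = 0), R_own, state[[3]],
                      params$resources$R_h, E)
  M <- matrix(0, 3, 3)
  M[1, 1] <- rt$nu[["J"]] - rt$gamma[["J"]] - rt$mu[["J"]]
  M[1, 3] <- max(rt$nu[["A"]], 0)
  M[2, 1] <- rt$gamma[["J"]]
  M[2, 2] <- rt$nu[["LJ"]] - rt$gamma[["LJ"]] - rt$mu[["LJ"]]
  M[3, 2] <- rt$gamma[["LJ"]]
  M[3, 3] <- min(rt$nu[["A"]], 0) - rt$mu[["A"]]
  max(Re(eigen(M, only.values = TRUE)$values))
}

# Damped Newton on the free components of rhs = 0; fixed components stay at
# their current value (used to pin extinct species at zero).
newton_polish <- function(state, params, E, omega, control,
                          free = rep(TRUE, 9)) {
  f_full <- function(x) rhs_unsafe(x, params, E, omega)
  x <- state
  fval <- f_full(x)[free]
  nrm <- max(abs(fval))
  iters <- 0
  for (it in seq_len(control$max_newton)) {
    if (nrm < control$res_tol / 10) break
    n_free <- sum(free)
    J <- matrix(0, n_free, n_free)
    h <- pmax(1e-7, 1e-6 * abs(x[free]))
    idx_free <- which(free)
    for (k in seq_len(n_free)) {
      xp <- x; xm <- x
      xp[idx_free[k]] <- xp[idx_free[k]] + h[k]
      xm[idx_free[k]] <- xm[idx_free[k]] - h[k]
      J[, k] <- (f_full(xp)[free] - f_full(xm)[free]) / (2 * h[k])
    }
    step <- tryCatch(solve(J, -fval), error = function(e) NULL)
    if (is.null(step))
      step <- tryCatch(qr.solve(J, -fval, tol = 1e-14),
                       error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      x_try <- x
      x_try[free] <- x[free] + lambda * step
      f_try <- f_full(x_try)[free]
      if (all(is.finite(f_try)) && max(abs(f_try)) < nrm) {
        x <- x_try; fval <- f_try; nrm <- max(abs(f_try)); break
      }
      lambda <- lambda / 2
      if (lambda < 1 / 128) { lambda <- 0; break }
    }
    iters <- it
    if (lambda == 0) break
  }
  list(state = x, residual = max(abs(f_full(x))), iterations = iters,
       converged = nrm < control$res_tol)
}

#' Solve for an equilibrium of the harvested two-stock system
#'
#' Integrates the stiff system from `init` until the relative state change
#' over a probe window is negligible, then polishes the endpoint with a
#' damped Newton iteration on `rhs = 0`. A species whose total biomass falls
#' below the extinction tolerance is clamped to zero and the remaining
#' components re-polished with the species pinned (the extinct set is
#' forward-invariant, so this is the transcritical branch the integration was
#' approaching). A Newton iterate converging to an infeasible interior root
#' (negative stage biomass) is likewise resolved by declaring that species
#' extinct.
#'
#' @param params a [flatmix_params()] object.
#' @param omega resource overlap in `[0, 1]`; `NULL` uses
#'   `params$resources$omega`.
#' @param E harvesting effort, non-negative.
#' @param init initial state; defaults to [default_init_state()].
#' @param control a [flatmix_control()] list.
#' @return an object of class `flatmix_eq`: a list with `omega`, `E`,
#'   `state`, `metrics` ([fishery_metrics()]), `extinct` (named logical),
#'   `residual`, `iterations`, `t_integrated`, `method` and `converged`.
#'   Non-convergence is flagged, never silent.
#' @export
solve_equilibrium <- function(params, omega = NULL, E = 0, init = NULL,
                              control = flatmix_control()) {
  if (is.null(omega)) omega <- params$resources$omega
  if (is.na(omega) || omega < 0 || omega > 1)
    stop("omega must lie in [0, 1]", call. = FALSE)
  if (is.na(E) || E < 0) stop("effort must be non-negative", call. = FALSE)
  if (is.null(init)) init <- default_init_state(params, omega,
                                                control$seed_density)
  init <- setNames(pmax(as.numeric(init), 0), state_names())

  ig <- integrate_to_steady(init, params, E, omega, control)
  x <- ig$state
  free <- rep(TRUE, 9)
  pin_dead <- function() {
    for (nm in names(species_idx))
      if (any(free[species_idx[[nm]]]) &&
          sum(x[species_idx[[nm]]]) < control$extinct_tol) {
        x[species_idx[[nm]]] <<- 0
        free[species_idx[[nm]]] <<- FALSE
      }
  }
  pin_dead()

  pol <- NULL
  polish_rounds <- function() {
    for (round in 1:2) {
      for (attempt in 1:3) {
        pol <<- newton_polish(x, params, E, omega, control, free)
        x <<- pol$state
        changed <- FALSE
        for (nm in names(species_idx)) {
          idx <- species_idx[[nm]]
          if (any(free[idx]) &&
              (min(x[idx]) < -1e-8 ||
               sum(pmax(x[idx], 0)) < control$extinct_tol)) {
            x[idx] <<- 0; free[idx] <<- FALSE; changed <- TRUE
          }
        }
        x[x < 0 & x > -1e-8] <<- 0
        if (!changed) break
      }
      if (pol$converged || round == 2) break
      ig2 <- integrate_to_steady(pmax(x, 0), params, E, omega, control)
      x <<- ig2$state
      ig$t <<- ig$t + ig2$t
      pin_dead()
    }
  }
  polish_rounds()

  # Remnant-vs-equilibrium disambiguation via the transcritical criterion.
  # A slowly decaying remnant can slip under the absolute residual floor
  # (residual ~ mortality x biomass); a species that is rare AND cannot
  # invade the ambient resource environment is extinct, not equilibrial.
  clamped <- FALSE
  for (nm in names(species_idx)) {
    idx <- species_idx[[nm]]
    if (any(free[idx]) && sum(x[idx]) < 1e-3 &&
        invasion_rate(params, nm, x, E) < -1e-10) {
      x[idx] <- 0
      free[idx] <- FALSE
      clamped <- TRUE
    }
  }
  if (clamped) polish_rounds()

  # Conversely, a species classified extinct must not be able to re-invade
  # the resident equilibrium. A wrongly-killed species -- the near-threshold
  # dynamics are slow and a Newton overshoot can clamp it -- is re-seeded
  # and the system re-polished, once.
  revived <- FALSE
  for (nm in names(species_idx)) {
    idx <- species_idx[[nm]]
    if (!any(free[idx]) &&
        invasion_rate(params, nm, x, E) > 1e-9) {
      x[idx] <- 1e-6
      free[idx] <- TRUE
      revived <- TRUE
    }
  }
  if (revived) polish_rounds()

  if (any(x < 0)) {  # infeasible root not attributable to an extinction
    pol$converged <- FALSE
    x <- pmax(x, 0)
  }
  x <- setNames(x, state_names())
  residual <- max(abs(rhs(x, params, E, omega)))
  extinct <- vapply(species_idx, function(idx) sum(x[idx]) <= 0, logical(1))
  structure(list(
    omega = omega, E = E, state = x,
    metrics = fishery_metrics(x, params, E, omega),
    extinct = extinct, residual = residual,
    iterations = pol$iterations, t_integrated = ig$t,
    method = "integrate+newton",
    converged = pol$converged && residual < control$res_tol
  ), class = "flatmix_eq")
}

#' @export
print.flatmix_eq <- function(x, ...) {
  cat(sprintf("flatmix equilibrium  (omega = %g, E = %g)\n", x$omega, x$E))
  print(signif(x$state, 6))
  cat(sprintf("  extinct: %s | residual %.2e | %s\n",
              paste(names(x$extinct)[x$extinct], collapse = ", "),
              x$residual,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

curve_skeleton <- function(kind, params, control) {
  structure(list(kind = kind, params = params, control = control,
                 records = list()),
            class = "flatmix_curve")
}

grid_brackets <- function(grid, records) {
  out <- list()
  for (nm in names(species_idx)) {
    ext <- vapply(records, function(r) r$extinct[[nm]], logical(1))
    out[[nm]] <-
      if (!ext[1] && any(ext)) {
        i <- which(ext)[1]
        c(lo = grid[i - 1], hi = grid[i])
      } else c(lo = NA_real_, hi = NA_real_)
  }
  out
}

#' Sweep equilibria over a harvesting-effort grid
#'
#' Solves the equilibrium at each effort of an increasing grid. With
#' `continuation = TRUE` (natural-parameter continuation) each solve is
#' warm-started from the previous equilibrium, following the branch upward
#' from the first grid point; otherwise every solve starts from the standard
#' seed. Grid brackets of the per-species extinction crossings are recorded.
#'
#' @inheritParams solve_equilibrium
#' @param E_grid strictly increasing vector of efforts.
#' @param continuation warm-start each solve from the previous equilibrium?
#' @param init state for the first solve; defaults to the standard seed.
#' @return an object of class `flatmix_curve` (kind `"effort"`) holding the
#'   per-grid-point `flatmix_eq` records, the extinction brackets, `omega`
#'   and the parameter set; convert with [as.data.frame()].
#' @export
sweep_effort <- function(params, omega = NULL, E_grid,
                         continuation = TRUE, init = NULL,
                         control = flatmix_control()) {
  if (is.null(omega)) omega <- params$resources$omega
  stopifnot(length(E_grid) >= 1, !is.unsorted(E_grid, strictly = TRUE),
            all(E_grid >= 0))
  cv <- curve_skeleton("effort", params, control)
  cv$omega <- omega; cv$grid <- E_grid
  prev <- init
  for (i in seq_along(E_grid)) {
    rec <- solve_equilibrium(params, omega, E_grid[i], init = prev,
                             control = control)
    cv$records[[i]] <- rec
    if (continuation) prev <- rec$state
  }
  cv$extinction_brackets <- grid_brackets(E_grid, cv$records)
  cv
}

#' Sweep equilibria over a resource-overlap grid
#'
#' Solves equilibria along an increasing grid of the overlap fraction at
#' fixed effort (default: unfished), warm-starting along the grid, and
#' refines any species-exclusion crossing by bisection on omega.
#'
#' @inheritParams solve_equilibrium
#' @param omega_grid increasing vector of overlap fractions in `[0, 1]`.
#' @param E fixed harvesting effort.
#' @param bisect_rtol relative tolerance of the exclusion-threshold bisection
#'   (on the omega scale; absolute, since omega is order 1).
#' @return a `flatmix_curve` of kind `"omega"`; `exclusion_omega` holds the
#'   refined per-species exclusion thresholds (`NA` when a species never
#'   drops out on the grid).
#' @export
sweep_omega <- function(params, omega_grid, E = 0, init = NULL,
                        control = flatmix_control(), bisect_rtol = 1e-4) {
  stopifnot(length(omega_grid) >= 1,
            !is.unsorted(omega_grid, strictly = TRUE),
            all(omega_grid >= 0), all(omega_grid <= 1))
  cv <- curve_skeleton("omega", params, control)
  cv$E <- E; cv$grid <- omega_grid
  prev <- init
  for (i in seq_along(omega_grid)) {
    rec <- solve_equilibrium(params, omega_grid[i], E, init = prev,
                             control = control)
    cv$records[[i]] <- rec
    prev <- rec$state
  }
  cv$extinction_brackets <- grid_brackets(omega_grid, cv$records)
  cv$exclusion_omega <- vapply(names(species_idx), function(nm) {
    br <- cv$extinction_brackets[[nm]]
    if (anyNA(br)) return(NA_real_)
    i_lo <- match(br[["lo"]], omega_grid)
    lo <- br[["lo"]]; hi <- br[["hi"]]
    warm <- cv$records[[i_lo]]$state
    while (hi - lo > bisect_rtol) {
      mid <- (lo + hi) / 2
      rec <- solve_equilibrium(params, mid, E, init = warm, control = control)
      if (rec$extinct[[nm]]) hi <- mid else { lo <- mid; warm <- rec$state }
    }
    (lo + hi) / 2
  }, numeric(1))
  cv
}

#' Effort at which a species is driven extinct
#'
#' Locates the transcritical harvesting threshold `E*` of one species along
#' the continuation branch from `E = 0` upward: a doubling search finds an
#' effort at which the species is extinct, then bisection (warm-started from
#' the highest effort at which the species was seen alive) narrows the
#' persistence boundary.
#'
#' @inheritParams solve_equilibrium
#' @param species `"plaice"` or `"sole"`.
#' @param rtol relative tolerance on `E*`.
#' @param E_init first non-zero effort probed by the doubling search.
#' @param E_cap doubling-search ceiling; a species still alive there is
#'   deemed unfishable.
#' @return the threshold effort, with attribute `bracket`; `Inf` when the
#'   species cannot be fished to extinction (e.g. both catchabilities zero),
#'   `NA` when the species is already extinct at `E = 0`.
#' @export
find_extinction_effort <- function(params, omega = NULL, species,
                                   rtol = 1e-4, E_init = 1, E_cap = 2^20,
                                   control = flatmix_control()) {
  stopifnot(species %in% names(species_idx))
  if (is.null(omega)) omega <- params$resources$omega
  sp <- params$species[[species]]
  if (sp$f[["LJ"]] == 0 && sp$f[["A"]] == 0) return(Inf)
  base <- solve_equilibrium(params, omega, 0, control = control)
  if (base$extinct[[species]]) return(NA_real_)
  lo <- 0; warm <- base$state; E <- E_init
  repeat {
    rec <- solve_equilibrium(params, omega, E, init = warm, control = control)
    if (rec$extinct[[species]]) break
    lo <- E; warm <- rec$state; E <- E * 2
    if (E > E_cap) return(Inf)
  }
  hi <- E
  while ((hi - lo) > rtol * hi) {
    mid <- (lo + hi) / 2
    rec <- solve_equilibrium(params, omega, mid, init = warm,
                             control = control)
    if (rec$extinct[[species]]) hi <- mid else { lo <- mid; warm <- rec$state }
  }
  structure((lo + hi) / 2, bracket = c(lo = lo, hi = hi))
}

#' Effort ceiling at which both species are extinct
#'
#' Doubling search for an effort beyond both extinction thresholds, used to
#' size the default sweep grid.
#'
#' @inheritParams find_extinction_effort
#' @param margin multiplicative head-room applied to the found effort.
#' @return an effort at which neither species persists, times `margin`.
#' @export
find_effort_ceiling <- function(params, omega = NULL, E_init = 1,
                                E_cap = 2^20, margin = 1.1,
                                control = flatmix_control()) {
  if (is.null(omega)) omega <- params$resources$omega
  E <- E_init
  warm <- solve_equilibrium(params, omega, 0, control = control)$state
  repeat {
    rec <- solve_equilibrium(params, omega, E, init = warm, control = control)
    if (all(rec$extinct)) return(E * margin)
    warm <- rec$state
    E <- E * 2
    if (E > E_cap)
      stop("no effort below the cap drives both species extinct",
           call. = FALSE)
  }
}

#' Locate and classify the maxima of a revenue-effort curve
#'
#' Finds the interior local maxima of the combined revenue along an effort
#' sweep (strict neighbour comparison after collapsing plateaus), refines
#' each by golden-section search on re-solved equilibria, classifies the
#' curve as unimodal/bimodal/multimodal, and reports whether the global
#' maximum lies beyond the plaice extinction threshold.
#'
#' @param curve a `flatmix_curve` of kind `"effort"` with at least 3 points.
#' @param refine refine grid maxima by golden-section search?
#' @param refine_tol absolute tolerance of the golden-section search on the
#'   effort axis; default scales with the grid spacing.
#' @return a list of class `flatmix_revenue_analysis`: data.frame `maxima`
#'   (columns `E`, `revenue`, `revenue_plaice`, `revenue_sole`), `modality`
#'   (`"none"`, `"unimodal"`, `"bimodal"`, `"multimodal"`), `global_max`
#'   (one-row data.frame or `NULL`), and
#'   `global_beyond_plaice_extinction` (`NA` when plaice never goes extinct
#'   on the grid).
#' @export
analyze_revenue_curve <- function(curve, refine = TRUE, refine_tol = NULL) {
  stopifnot(inherits(curve, "flatmix_curve"), curve$kind == "effort",
            length(curve$records) >= 3)
  E <- curve$grid
  rev <- vapply(curve$records, function(r) r$metrics$revenue_total, numeric(1))
  if (is.null(refine_tol)) refine_tol <- max(1e-6, 1e-3 * min(diff(E)))

  # collapse plateaus (relative equality) then strict neighbour comparison
  scale <- max(abs(rev), 1e-300)
  grp <- cumsum(c(TRUE, abs(diff(rev)) > 1e-12 * scale))
  run_val <- tapply(rev, grp, function(v) v[1])
  run_first <- tapply(seq_along(rev), grp, function(i) i[1])
  run_last <- tapply(seq_along(rev), grp, function(i) i[length(i)])
  peaks <- integer(0)
  nr <- length(run_val)
  if (nr >= 3 && max(rev) > 0)
    for (k in 2:(nr - 1))
      if (run_val[k] > run_val[k - 1] && run_val[k] > run_val[k + 1])
        peaks <- c(peaks, floor((run_first[k] + run_last[k]) / 2))

  maxima <- lapply(peaks, function(i) {
    lo <- E[max(i - 1, 1)]; hi <- E[min(i + 1, length(E))]
    if (refine) {
      warm <- curve$records[[i]]$state
      f <- function(e) solve_equilibrium(curve$params, curve$omega, e,
                                         init = warm,
                                         control = curve$control)$metrics$revenue_total
      op <- optimize(f, lower = lo, upper = hi, maximum = TRUE,
                     tol = refine_tol)
      rec <- solve_equilibrium(curve$params, curve$omega, op$maximum,
                               init = warm, control = curve$control)
    } else {
      rec <- curve$records[[i]]
    }
    data.frame(E = rec$E, revenue = rec$metrics$revenue_total,
               revenue_plaice = rec$metrics$revenue[["plaice"]],
               revenue_sole = rec$metrics$revenue[["sole"]])
  })
  maxima <- if (length(maxima)) do.call(rbind, maxima) else
    data.frame(E = numeric(0), revenue = numeric(0),
               revenue_plaice = numeric(0), revenue_sole = numeric(0))

  modality <- switch(as.character(min(nrow(maxima), 3)),
                     "0" = "none", "1" = "unimodal", "2" = "bimodal",
                     "3" = "multimodal")
  global_max <- if (nrow(maxima)) maxima[which.max(maxima$revenue), ] else NULL
  br <- curve$extinction_brackets$plaice
  beyond <- if (is.null(global_max) || anyNA(br)) NA else
    global_max$E > mean(br)
  structure(list(maxima = maxima, modality = modality,
                 global_max = global_max,
                 global_beyond_plaice_extinction = beyond),
            class = "flatmix_revenue_analysis")
}

#' @export
print.flatmix_revenue_analysis <- function(x, ...) {
  cat(sprintf("revenue curve: %s (%d interior maxima)\n", x$modality,
              nrow(x$maxima)))
  if (nrow(x$maxima)) print(x$maxima)
  if (!is.na(x$global_beyond_plaice_extinction))
    cat(sprintf("global maximum %s the plaice extinction threshold\n",
                if (x$global_beyond_plaice_extinction) "beyond" else "below"))
  invisible(x)
}

#' Flatten a sweep to a data.frame
#'
#' One row per grid point: grid variable(s), the nine state components,
#' per-species landings/discards/discard-ratio/revenue flows, combined
#' revenue, extinction flags and convergence diagnostics.
#'
#' @param x a `flatmix_curve`.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return a data.frame with one row per grid point.
#' @export
as.data.frame.flatmix_curve <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  if (length(x$records) == 0) {
    cols <- c("omega", "E", state_names(), "landings_plaice", "landings_sole",
              "discards_plaice", "discards_sole", "discard_ratio_plaice",
              "discard_ratio_sole", "revenue_plaice", "revenue_sole",
              "revenue_total", "extinct_plaice", "extinct_sole", "residual",
              "converged")
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)),
                                    cols))
    empty$extinct_plaice <- logical(0); empty$extinct_sole <- logical(0)
    empty$converged <- logical(0)
    return(empty)
  }
  rows <- lapply(x$records, function(r) {
    m <- r$metrics
    cbind(data.frame(omega = r$omega, E = r$E),
          as.data.frame(as.list(r$state)),
          data.frame(
            landings_plaice = m$landings[["plaice"]],
            landings_sole = m$landings[["sole"]],
            discards_plaice = m$discards[["plaice"]],
            discards_sole = m$discards[["sole"]],
            discard_ratio_plaice = m$discard_ratio[["plaice"]],
            discard_ratio_sole = m$discard_ratio[["sole"]],
            revenue_plaice = m$revenue[["plaice"]],
            revenue_sole = m$revenue[["sole"]],
            revenue_total = m$revenue_total,
            extinct_plaice = r$extinct[["plaice"]],
            extinct_sole = r$extinct[["sole"]],
            residual = r$residual, converged = r$converged))
  })
  do.call(rbind, rows)
}

#' @export
print.flatmix_curve <- function(x, ...) {
  cat(sprintf("flatmix %s sweep: %d grid points\n", x$kind,
              length(x$records)))
  print(utils::head(as.data.frame(x)[, 1:11]))
  invisible(x)
}
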