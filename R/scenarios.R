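## Scenario runners: the standard experiments (competition sweep, effort
## sweeps, revenue analysis, equal-size-range sensitivity) with pass/fail
## property reports, and a synthetic pseudo-observation generator.

species_total <- function(curve, species) {
  idx <- species_idx[[species]]
  vapply(curve$records, function(r) sum(r$state[idx]), numeric(1))
}

stage_series <- function(curve, component) {
  vapply(curve$records, function(r) r$state[[component]], numeric(1))
}

# Monotone within a small tolerance relative to the series scale.
is_monotone <- function(v, direction = c("increasing", "decreasing"),
                        rel_tol = 1e-6) {
  direction <- match.arg(direction)
  if (length(v) < 2) return(TRUE)
  tol <- rel_tol * max(abs(v), 1e-300)
  d <- diff(v)
  if (direction == "increasing") all(d >= -tol) else all(d <= tol)
}

# Rises to an interior peak, then falls.
is_hump_shaped <- function(v, rel_tol = 1e-6) {
  if (length(v) < 3) return(FALSE)
  k <- which.max(v)
  k > 1 && k < length(v) &&
    is_monotone(v[1:k], "increasing", rel_tol) &&
    is_monotone(v[k:length(v)], "decreasing", rel_tol)
}

report_row <- function(claim, value, pass) {
  data.frame(claim = claim, value = as.character(value), pass = pass,
             stringsAsFactors = FALSE)
}

make_report <- function(rows, curve = NULL, extra = list()) {
  structure(c(list(checks = do.call(rbind, rows), curve = curve), extra),
            class = "flatmix_report")
}

#' @export
print.flatmix_report <- function(x, ...) {
  print(x$checks, row.names = FALSE)
  invisible(x)
}

#' Competition scenario: overlap sweep without fishing
#'
#' Sweeps the unfished equilibrium over the resource-overlap fraction and
#' checks the qualitative structure: plaice biomass rises with overlap, sole
#' biomass falls, and sole is competitively excluded as overlap approaches 1.
#'
#' @inheritParams solve_equilibrium
#' @param n_grid number of overlap grid points between 0 and 1.
#' @return a `flatmix_report` with the checks, the underlying `flatmix_curve`
#'   and the refined sole-exclusion overlap (`exclusion_omega`).
#' @export
scenario_competition <- function(params, n_grid = 101,
                                 control = flatmix_control()) {
  cv <- sweep_omega(params, seq(0, 1, length.out = n_grid), E = 0,
                    control = control)
  plaice <- species_total(cv, "plaice")
  sole <- species_total(cv, "sole")
  excl <- cv$exclusion_omega[["sole"]]
  rows <- list(
    report_row("plaice biomass non-decreasing in overlap",
               sprintf("range %.4g..%.4g g/L", min(plaice), max(plaice)),
               is_monotone(plaice, "increasing")),
    report_row("sole biomass non-increasing in overlap",
               sprintf("range %.4g..%.4g g/L", max(sole), min(sole)),
               is_monotone(sole, "decreasing")),
    report_row("sole excluded near complete overlap",
               sprintf("exclusion at omega = %.4g", excl),
               !is.na(excl) || cv$records[[n_grid]]$extinct[["sole"]])
  )
  make_report(rows, cv, list(exclusion_omega = excl))
}

#' Effort scenario: equilibrium sweep over harvesting effort
#'
#' Sweeps equilibria over an effort grid at fixed overlap (continuation from
#' the unfished state) and evaluates the qualitative claims appropriate to
#' that overlap. Without competition (`omega = 0`): adult biomass of both
#' species falls monotonically, small- and large-juvenile biomass is
#' hump-shaped, the discard ratio rises with effort, and plaice goes extinct
#' before sole. Under strong competition (`omega > 0`): sole biomass rises
#' with effort while plaice declines towards extinction, and falls once
#' plaice is gone.
#'
#' @inheritParams solve_equilibrium
#' @param n_grid number of effort grid points.
#' @param E_max top of the grid; `NULL` sizes it adaptively with
#'   [find_effort_ceiling()].
#' @return a `flatmix_report`; the sweep is in `$curve`.
#' @export
scenario_effort <- function(params, omega = 0, n_grid = 201, E_max = NULL,
                            control = flatmix_control()) {
  if (is.null(E_max)) E_max <- find_effort_ceiling(params, omega,
                                                   control = control)
  cv <- sweep_effort(params, omega, seq(0, E_max, length.out = n_grid),
                     control = control)
  E <- cv$grid
  alive <- function(nm) !vapply(cv$records, function(r) r$extinct[[nm]],
                                logical(1))
  rows <- list()
  if (omega == 0) {
    for (nm in c("plaice", "sole")) {
      a <- alive(nm)
      adult <- stage_series(cv, paste0("A_", substr(nm, 1, 1)))[a]
      rows <- c(rows, list(
        report_row(paste("adult", nm, "biomass decreasing in effort"),
                   sprintf("%.4g -> %.4g g/L", adult[1], adult[length(adult)]),
                   is_monotone(adult, "decreasing")),
        report_row(paste(nm, "juvenile biomass hump-shaped"), "",
                   is_hump_shaped(stage_series(cv, paste0("J_", substr(nm, 1, 1))))),
        report_row(paste(nm, "large-juvenile biomass hump-shaped"), "",
                   is_hump_shaped(stage_series(cv, paste0("LJ_", substr(nm, 1, 1)))))))
      ratio <- vapply(cv$records,
                      function(r) r$metrics$discard_ratio[[nm]], numeric(1))
      keep <- a & E > 0 & !is.na(ratio)
      rows <- c(rows, list(
        report_row(paste(nm, "discard ratio increasing in effort"),
                   sprintf("%.4g -> %.4g", ratio[keep][1],
                           ratio[keep][sum(keep)]),
                   is_monotone(ratio[keep], "increasing"))))
    }
    bp <- cv$extinction_brackets$plaice
    bs <- cv$extinction_brackets$sole
    rows <- c(rows, list(
      report_row("plaice extinct at lower effort than sole",
                 sprintf("E* plaice in [%.4g, %.4g], sole in [%.4g, %.4g]",
                         bp[1], bp[2], bs[1], bs[2]),
                 !anyNA(bp) && (anyNA(bs) || bp[["hi"]] <= bs[["lo"]]))))
  } else {
    sole_tot <- species_total(cv, "sole")
    plaice_alive <- alive("plaice")
    i_ext <- if (all(plaice_alive)) NA_integer_ else which(!plaice_alive)[1]
    before <- if (is.na(i_ext)) sole_tot else sole_tot[seq_len(i_ext - 1)]
    after <- if (is.na(i_ext)) numeric(0) else sole_tot[i_ext:length(sole_tot)]
    rises <- length(before) >= 2 &&
      max(before) > before[1] * (1 + 1e-6)
    rows <- c(rows, list(
      report_row("sole biomass rises with effort while plaice persists",
                 sprintf("%.4g -> max %.4g g/L", before[1], max(before)),
                 rises),
      report_row("plaice driven extinct on the grid",
                 sprintf("first extinct at E = %.4g",
                         if (is.na(i_ext)) NA else E[i_ext]), !is.na(i_ext)),
      report_row("sole biomass decreasing after plaice extinction", "",
                 length(after) >= 2 &&
                   is_monotone(after, "decreasing", rel_tol = 1e-4))))
  }
  make_report(rows, cv)
}

#' Revenue scenario: shape of the revenue-effort relation
#'
#' Runs (or reuses) an effort sweep, analyses the combined revenue curve with
#' [analyze_revenue_curve()], and evaluates the claims appropriate to the
#' overlap level: without competition a single interior maximum at which both
#' species persist and sole supplies the majority of the revenue; at
#' intermediate overlap a global maximum beyond the plaice extinction
#' threshold; at strong overlap a bimodal combined curve.
#'
#' @inheritParams scenario_effort
#' @param curve optional pre-computed effort sweep at this overlap.
#' @return a `flatmix_report`; the revenue analysis is in `$analysis`.
#' @export
scenario_revenue <- function(params, omega = 0, n_grid = 201, E_max = NULL,
                             curve = NULL, control = flatmix_control()) {
  if (is.null(curve)) {
    if (is.null(E_max)) E_max <- find_effort_ceiling(params, omega,
                                                     control = control)
    curve <- sweep_effort(params, omega, seq(0, E_max, length.out = n_grid),
                          control = control)
  }
  an <- analyze_revenue_curve(curve)
  gm <- an$global_max
  rows <- list(report_row("revenue curve modality", an$modality, TRUE))
  if (omega == 0) {
    br <- curve$extinction_brackets$plaice
    both_extant <- !is.null(gm) && !anyNA(br) && gm$E < br[["lo"]]
    rows <- c(rows, list(
      report_row("single interior revenue maximum",
                 sprintf("%d maxima", nrow(an$maxima)),
                 an$modality == "unimodal"),
      report_row("both species extant at the revenue peak",
                 sprintf("peak E = %.4g", if (is.null(gm)) NA else gm$E),
                 both_extant),
      report_row("sole supplies the majority of peak revenue",
                 if (is.null(gm)) "" else
                   sprintf("sole %.3g vs plaice %.3g EUR/L/d",
                           gm$revenue_sole, gm$revenue_plaice),
                 !is.null(gm) && gm$revenue_sole > gm$revenue_plaice)))
  }
  if (omega >= 0.5) {
    rows <- c(rows, list(
      report_row("global revenue peak beyond plaice extinction",
                 sprintf("peak E = %.4g", if (is.null(gm)) NA else gm$E),
                 isTRUE(an$global_beyond_plaice_extinction))))
  }
  if (omega >= 0.8) {
    rows <- c(rows, list(
      report_row("combined revenue curve bimodal",
                 sprintf("%d maxima", nrow(an$maxima)),
                 an$modality == "bimodal")))
  }
  make_report(rows, curve, list(analysis = an))
}

#' Equal-size-range sensitivity scenario
#'
#' Rebuilds both species with a common set of stage-boundary lengths (their
#' own length-weight rules, ingestion, maintenance and catchabilities are
#' kept; stage weights and mass ratios are re-derived) and checks that the
#' qualitative structure survives: plaice remains the superior competitor,
#' the combined revenue curve at strong overlap remains bimodal, and both
#' extinction thresholds move to higher effort than under the default
#' size ranges.
#'
#' @inheritParams scenario_effort
#' @param L shared stage-boundary lengths `c(J=, LJ=, A=)` (cm); default is
#'   the plaice boundaries.
#' @param omega_revenue overlap at which the bimodality check is run.
#' @param n_grid effort grid size of the revenue sweeps.
#' @return a `flatmix_report`; `$params_equalized` holds the rebuilt set and
#'   `$extinction` the default-vs-equalized threshold table.
#' @export
scenario_equal_sizes <- function(params, L = NULL, omega_revenue = 0.8,
                                 n_grid = 151, control = flatmix_control()) {
  if (is.null(L)) L <- params$species$plaice$L
  eq_params <- set_stage_boundaries(
    set_stage_boundaries(params, "plaice", L), "sole", L)

  # superiority: unfished biomasses under strong overlap
  eq0 <- solve_equilibrium(eq_params, omega_revenue, 0, control = control)
  plaice_tot <- sum(eq0$state[species_idx$plaice])
  sole_tot <- sum(eq0$state[species_idx$sole])

  rev_rep <- scenario_revenue(eq_params, omega_revenue, n_grid = n_grid,
                              control = control)

  ext <- expand.grid(species = c("plaice", "sole"),
                     set = c("default", "equalized"),
                     stringsAsFactors = FALSE)
  ext$E_star <- mapply(function(sp, set) {
    p <- if (set == "default") params else eq_params
    as.numeric(find_extinction_effort(p, omega = 0, species = sp,
                                      control = control))
  }, ext$species, ext$set)
  e_def <- ext$E_star[ext$set == "default"]
  e_eq <- ext$E_star[ext$set == "equalized"]

  rows <- list(
    report_row("plaice superior competitor with equalized stages",
               sprintf("plaice %.4g vs sole %.4g g/L", plaice_tot, sole_tot),
               plaice_tot > sole_tot),
    report_row("revenue bimodality persists with equalized stages",
               rev_rep$analysis$modality,
               rev_rep$analysis$modality == "bimodal"),
    report_row("extinctions shift to higher effort with equalized stages",
               sprintf("default %.4g/%.4g vs equalized %.4g/%.4g",
                       e_def[1], e_def[2], e_eq[1], e_eq[2]),
               all(e_eq > e_def))
  )
  make_report(rows, rev_rep$curve,
              list(params_equalized = eq_params, extinction = ext,
                   revenue_report = rev_rep))
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate synthetic noisy observations of the equilibrium fishery
#'
#' Computes equilibrium stage biomasses and discard fractions over an effort
#' grid and multiplies each observable by independent lognormal noise with
#' unit median and a given coefficient of variation
#' (`sdlog = sqrt(log(1 + cv^2))`). With `noise_cv = 0` the table is the
#' exact model output. Deterministic for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' These pseudo-observations emulate equilibrium survey/market data and
#' exist so the calibration machinery can be exercised end-to-end without
#' external data.
#'
#' @inheritParams sweep_effort
#' @param noise_cv coefficient of variation of the multiplicative
#'   observation noise, non-negative.
#' @param seed integer RNG seed.
#' @return a data.frame with one row per (effort, species): `omega`, `E`,
#'   `species`, `discard_fraction`, `J`, `LJ`, `A` (biomasses in g/L).
#' @export
generate_pseudo_observations <- function(params, omega = 0, E_grid = 1,
                                         noise_cv = 0, seed = 1,
                                         control = flatmix_control()) {
  stopifnot(noise_cv >= 0)
  if (length(E_grid) == 1) {
    cv <- curve_skeleton("effort", params, control)
    cv$omega <- omega; cv$grid <- E_grid
    cv$records <- list(solve_equilibrium(params, omega, E_grid,
                                         control = control))
  } else {
    cv <- sweep_effort(params, omega, E_grid, control = control)
  }
  rows <- list()
  for (i in seq_along(cv$records)) {
    r <- cv$records[[i]]
    for (nm in c("plaice", "sole")) {
      idx <- species_idx[[nm]]
      rows[[length(rows) + 1]] <- data.frame(
        omega = omega, E = r$E, species = nm,
        discard_fraction = r$metrics$discard_ratio[[nm]],
        J = r$state[[idx[1]]], LJ = r$state[[idx[2]]], A = r$state[[idx[3]]],
        stringsAsFactors = FALSE)
    }
  }
  obs <- do.call(rbind, rows)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    obs[, c("discard_fraction", "J", "LJ", "A")] <- with_fixed_seed(seed, {
      vals <- as.matrix(obs[, c("discard_fraction", "J", "LJ", "A")])
      vals * matrix(rlnorm(length(vals), meanlog = 0, sdlog = sdlog),
                    nrow = nrow(vals))
    })
  }
  obs
}
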