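#' Length-weight conversion
#'
#' Allometric length-weight relationship `W = a * L^b` with `W` in g and `L`
#' in cm, and its inverse. Defaults are the sole coefficients; plaice uses
#' `a = 0.0089`, `b = 3.0353`.
#'
#' @param L body length (cm), non-negative.
#' @param W body weight (g), non-negative.
#' @param a coefficient (g cm^-b), positive.
#' @param b allometric exponent, positive.
#' @return weight in g (`weight_at_length`) or length in cm
#'   (`length_at_weight`).
#' @examples
#' weight_at_length(24, a = 0.0091, b = 3.077) # adult sole, ~160.7 g
#' @export
weight_at_length <- function(L, a, b) {
  stopifnot(a > 0, b > 0)
  if (any(L < 0)) stop("length must be non-negative", call. = FALSE)
  a * L^b
}

#' @rdname weight_at_length
#' @export
length_at_weight <- function(W, a, b) {
  stopifnot(a > 0, b > 0)
  if (any(W < 0)) stop("weight must be non-negative", call. = FALSE)
  (W / a)^(1 / b)
}

#' Average individual weight of a stage
#'
#' Logarithmic mean of the weights at which individuals enter and leave a
#' stage, `(W_max - W_min) / (ln W_max - ln W_min)`. This is the
#' biomass-weighted average weight of a stage whose individuals are
#' distributed as 1/W between the boundary weights, and reproduces the
#' stage-average weights of the default parameter table. Continuous limit
#' `W_avg -> W_min` as `W_max -> W_min` is guarded.
#'
#' @param W_min,W_max stage entry and exit weights (g), `0 < W_min <= W_max`.
#' @return average weight in g, strictly between `W_min` and `W_max` (equal
#'   when the stage is degenerate).
#' @export
stage_average_weight <- function(W_min, W_max) {
  if (any(W_min <= 0)) stop("W_min must be positive", call. = FALSE)
  if (any(W_max < W_min)) stop("W_max must be >= W_min", call. = FALSE)
  out <- numeric(length(W_min))
  dl <- log(W_max) - log(W_min)
  tiny <- dl < 1e-12
  out[tiny] <- W_min[tiny]
  out[!tiny] <- (W_max[!tiny] - W_min[!tiny]) / dl[!tiny]
  out
}

#' Stage entry-to-exit mass ratio
#'
#' Ratio `z` between the mass at which an individual enters a stage and the
#' mass at which it matures out of it, computed from the boundary lengths via
#' the length-weight exponent: `z = (L_entry / L_exit)^b`. The `a`
#' coefficient cancels.
#'
#' @param L_entry,L_exit boundary lengths (cm), `0 < L_entry <= L_exit`.
#' @param b allometric exponent of the length-weight relationship.
#' @return mass ratio in (0, 1], 1 only for a degenerate stage.
#' @export
z_ratio <- function(L_entry, L_exit, b) {
  stopifnot(b > 0)
  if (any(L_entry <= 0) || any(L_exit < L_entry))
    stop("need 0 < L_entry <= L_exit", call. = FALSE)
  (L_entry / L_exit)^b
}

#' Annual survival from a daily background mortality rate
#'
#' @param mu background mortality rate (per day), non-negative.
#' @return fraction surviving one year, `exp(-365 * mu)`.
#' @examples
#' annual_survival(0.001) # ~0.69, i.e. ~70 % annual survival
#' @export
annual_survival <- function(mu) {
  if (any(mu < 0)) stop("mu must be non-negative", call. = FALSE)
  exp(-365 * mu)
}

#' Convert an areal benthos density to a volumetric one
#'
#' Benthic macro-invertebrate standing stock is surveyed per square metre of
#' sea floor; the model needs g per litre of occupied habitat. The benthic
#' habitat is taken as a thin water layer above the bottom, with the prey
#' concentrated in a fraction of the bottom surface.
#'
#' @param areal areal density (g m^-2), positive.
#' @param layer_depth depth of the benthic layer (m), positive; 0.1 m in the
#'   default derivation.
#' @param concentration_fraction fraction of the bottom surface holding the
#'   prey, in (0, 1]; 1/3 in the default derivation.
#' @return volumetric density in g L^-1 (1 m^2 x 1 m depth = 1000 L).
#' @examples
#' benthos_to_volumetric(10.1, 0.1, 1 / 3) # ~0.3 g/L
#' @export
benthos_to_volumetric <- function(areal, layer_depth, concentration_fraction) {
  if (any(areal <= 0)) stop("areal density must be positive", call. = FALSE)
  if (any(layer_depth <= 0) || any(concentration_fraction <= 0))
    stop("layer depth and concentration fraction must be positive", call. = FALSE)
  areal / (layer_depth * 1000 * concentration_fraction)
}

## ---- parameter containers ------------------------------------------------

stage_names <- c("J", "LJ", "A")

#' Per-species parameter set
#'
#' Assembles the biological and fishery parameters of one stock. Stage
#' average weights `W_avg` and mass ratios `z` are derived from the
#' stage-boundary lengths and the length-weight rule; everything else is
#' taken as given.
#'
#' @param name species label.
#' @param L named lengths `c(J=, LJ=, A=)` (cm): size at settlement, size at
#'   first catch, size at landing/maturation; strictly increasing.
#' @param lw_a,lw_b length-weight coefficients (`W = a L^b`, g and cm).
#' @param I_max named maximum mass-specific ingestion rates
#'   `c(J=, LJ=, A=)` (g g^-1 d^-1).
#' @param T_maint mass-specific maintenance rate (g g^-1 d^-1).
#' @param delta food conversion efficiency, in (0, 1).
#' @param mu background mortality (d^-1).
#' @param price landing price (EUR kg^-1).
#' @param f_LJ,f_A relative catchabilities of large juveniles and adults
#'   (d^-1 per unit effort); small juveniles are never caught.
#' @return an object of class `flatmix_species`.
#' @export
species_params <- function(name, L, lw_a, lw_b, I_max, T_maint, delta, mu,
                           price, f_LJ, f_A) {
  L <- L[stage_names]; I_max <- I_max[stage_names]
  stopifnot(
    !anyNA(L), !anyNA(I_max), all(I_max > 0),
    L[["J"]] < L[["LJ"]], L[["LJ"]] < L[["A"]],
    lw_a > 0, lw_b > 0, T_maint > 0, delta > 0, delta < 1,
    mu > 0, price >= 0, f_LJ >= 0, f_A >= 0
  )
  W_bound <- weight_at_length(L, lw_a, lw_b)
  W_avg <- c(
    stage_average_weight(W_bound[["J"]], W_bound[["LJ"]]),
    stage_average_weight(W_bound[["LJ"]], W_bound[["A"]]),
    W_bound[["A"]]  # adults do not grow: weight at maturation
  )
  names(W_avg) <- stage_names
  z <- c(
    J  = z_ratio(L[["J"]], L[["LJ"]], lw_b),
    LJ = z_ratio(L[["LJ"]], L[["A"]], lw_b)
  )
  structure(
    list(name = name, L = L, lw_a = lw_a, lw_b = lw_b, W_avg = W_avg, z = z,
         I_max = I_max, T_maint = T_maint, delta = delta, mu = mu,
         price = price, f = c(LJ = unname(f_LJ), A = unname(f_A))),
    class = "flatmix_species"
  )
}

#' Resource parameter set
#'
#' @param r resource regrowth rate (d^-1) of the semi-chemostat dynamics.
#' @param K_m maximum density of the non-plaice-exclusive resource base
#'   (g L^-1); split by `omega` into sole-exclusive and shared parts.
#' @param K_p maximum density of the plaice-exclusive resource (g L^-1).
#' @param R_h half-saturation density of the functional response (g L^-1).
#' @param omega resource overlap fraction in `[0, 1]`; 0 = no competition,
#'   1 = sole feeds only on the shared resource.
#' @return an object of class `flatmix_resources`.
#' @export
resource_params <- function(r, K_m, K_p, R_h, omega = 0) {
  stopifnot(r > 0, K_m > 0, K_p > 0, R_h > 0)
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1]", call. = FALSE)
  structure(list(r = r, K_m = K_m, K_p = K_p, R_h = R_h, omega = omega),
            class = "flatmix_resources")
}

#' Full model parameter set
#'
#' @param plaice,sole [species_params()] objects.
#' @param resources a [resource_params()] object.
#' @return an object of class `flatmix_params`.
#' @export
flatmix_params <- function(plaice, sole, resources) {
  stopifnot(inherits(plaice, "flatmix_species"),
            inherits(sole, "flatmix_species"),
            inherits(resources, "flatmix_resources"))
  structure(list(species = list(plaice = plaice, sole = sole),
                 resources = resources),
            class = "flatmix_params")
}

#' @export
print.flatmix_params <- function(x, ...) {
  cat("flatmix parameter set\n")
  r <- x$resources
  cat(sprintf("  resources: r = %g /d, K_m = %g, K_p = %g, R_h = %g g/L, omega = %g\n",
              r$r, r$K_m, r$K_p, r$R_h, r$omega))
  for (sp in x$species) {
    cat(sprintf("  %s: L = %s cm, I_max = %s /d, T = %g, mu = %g, price = %g EUR/kg, f = (LJ %g, A %g)\n",
                sp$name, paste(sp$L, collapse = "/"),
                paste(sp$I_max, collapse = "/"), sp$T_maint, sp$mu, sp$price,
                sp$f[["LJ"]], sp$f[["A"]]))
  }
  invisible(x)
}

## ---- default parameter set ----------------------------------------------

# Printed reference values for the derivable entries of the default table:
# stage-average weights (g) and stage mass ratios, with the decimal increment
# they were printed at. Used only by the validator, never by the dynamics.
.default_reference <- list(
  plaice = list(
    W = c(J = 1.7, LJ = 65.5, A = 208.6), W_ulp = c(0.1, 0.1, 0.1),
    z = c(J = 0.003, LJ = 0.048), z_ulp = c(0.001, 0.001),
    rtol = 0.07
  ),
  sole = list(
    W = c(J = 2.3, LJ = 66.4, A = 160.7), W_ulp = c(0.1, 0.1, 0.1),
    z = c(J = 0.0003, LJ = 0.118), z_ulp = c(0.0001, 0.001),
    rtol = 0.02
  )
)

.default_species_args <- list(
  plaice = list(
    name = "plaice", L = c(J = 1.5, LJ = 10, A = 27),
    lw_a = 0.0089, lw_b = 3.0353,
    I_max = c(J = 0.069, LJ = 0.020, A = 0.013),
    T_maint = 0.0037, delta = 0.36, mu = 0.001, price = 1.38,
    f_LJ = 5e-5, f_A = 0.001272
  ),
  sole = list(
    name = "sole", L = c(J = 0.85, LJ = 12, A = 24),
    lw_a = 0.0091, lw_b = 3.077,
    I_max = c(J = 0.050, LJ = 0.016, A = 0.011),
    T_maint = 0.0032, delta = 0.36, mu = 0.001, price = 10.06,
    f_LJ = 2e-6, f_A = 0.001455
  )
)

.default_resource_args <- list(r = 0.1, K_m = 0.3, K_p = 1, R_h = 0.01,
                               omega = 0)

#' Default parameter set
#'
#' Builds the default sole/plaice parameterisation. Derivable entries (stage
#' average weights, stage mass ratios) are recomputed from the stage-boundary
#' lengths and length-weight rules and checked against their printed
#' reference values; non-derivable entries (ingestion rates, maintenance,
#' conversion efficiency, catchabilities, prices, resource maxima, regrowth
#' rate, half-saturation constant) are taken verbatim.
#'
#' The check accepts a derived value when it is within half a unit of the
#' reference's printed precision, or within a relative tolerance of 2 % for
#' sole and 7 % for plaice. The plaice rows need the wider band: the printed
#' plaice weights are not fully consistent with the printed plaice
#' length-weight coefficients (`a = 0.0089` yields an adult weight near
#' 197 g, not 208.6 g); the derived values are used, the discrepancy is
#' diagnostic only.
#'
#' @param omega resource overlap fraction in `[0, 1]`.
#' @param validate if `TRUE` (default) error when a derived entry misses its
#'   reference beyond tolerance, listing the offending entries.
#' @return a [flatmix_params()] object.
#' @seealso [derivation_report()] for the full printed-vs-derived table.
#' @export
default_params <- function(omega = 0, validate = TRUE) {
  pars <- flatmix_params(
    plaice = do.call(species_params, .default_species_args$plaice),
    sole = do.call(species_params, .default_species_args$sole),
    resources = do.call(resource_params,
                        modifyList(.default_resource_args,
                                   list(omega = omega)))
  )
  if (validate) {
    rep <- derivation_report(pars)
    bad <- rep[!rep$ok, , drop = FALSE]
    if (nrow(bad) > 0)
      stop("derived parameter(s) miss their reference value: ",
           paste(bad$parameter, collapse = ", "), call. = FALSE)
  }
  pars
}

#' Printed-vs-derived parameter validation report
#'
#' Recomputes every derivable default-table entry (stage average weights,
#' stage mass ratios, both species) from the stage lengths and length-weight
#' rules in `params` and compares it with the printed reference value.
#'
#' @param params a [flatmix_params()] object; entries for species other than
#'   the default plaice/sole pair are skipped.
#' @return a data.frame with columns `parameter`, `printed`, `derived`,
#'   `rel_diff`, `tolerance`, `ok`.
#' @export
derivation_report <- function(params = default_params(validate = FALSE)) {
  rows <- list()
  for (nm in intersect(names(params$species), names(.default_reference))) {
    sp <- params$species[[nm]]
    ref <- .default_reference[[nm]]
    add <- function(label, printed, derived, ulp) {
      tol <- max(ulp / 2, ref$rtol * abs(printed))
      rows[[length(rows) + 1]] <<- data.frame(
        parameter = paste(nm, label), printed = printed, derived = derived,
        rel_diff = abs(derived - printed) / abs(printed), tolerance = tol,
        ok = abs(derived - printed) <= tol + 1e-12)
    }
    for (i in seq_along(stage_names))
      add(paste0("W_avg_", stage_names[i]), ref$W[[i]], sp$W_avg[[i]],
          ref$W_ulp[[i]])
    for (i in 1:2)
      add(paste0("z_", c("J-LJ", "LJ-A")[i]), ref$z[[i]], sp$z[[i]],
          ref$z_ulp[[i]])
  }
  do.call(rbind, rows)
}

#' Replace a species' stage-boundary lengths
#'
#' Rebuilds one species with new boundary lengths; stage average weights and
#' mass ratios are re-derived from the species' own length-weight rule, while
#' ingestion, maintenance, catchability and price are kept. Used by the
#' equal-size-range sensitivity analysis.
#'
#' @param params a [flatmix_params()] object.
#' @param species `"plaice"` or `"sole"`.
#' @param L named lengths `c(J=, LJ=, A=)` (cm), strictly increasing.
#' @return the modified [flatmix_params()] object.
#' @export
set_stage_boundaries <- function(params, species, L) {
  stopifnot(inherits(params, "flatmix_params"),
            species %in% names(params$species))
  sp <- params$species[[species]]
  params$species[[species]] <- species_params(
    name = sp$name, L = L, lw_a = sp$lw_a, lw_b = sp$lw_b, I_max = sp$I_max,
    T_maint = sp$T_maint, delta = sp$delta, mu = sp$mu, price = sp$price,
    f_LJ = sp$f[["LJ"]], f_A = sp$f[["A"]])
  params
}
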