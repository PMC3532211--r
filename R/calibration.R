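## Calibration of large-juvenile catchabilities against target
## discard-over-landings fractions.

#' Equilibrium discard fraction
#'
#' Solves the equilibrium at the given overlap and effort and returns the
#' discarded-over-landed biomass fraction per species,
#' `(f_LJ * LJ) / (f_A * A)`.
#'
#' @inheritParams solve_equilibrium
#' @param eq optional pre-computed `flatmix_eq` at (`omega`, `E`); skips the
#'   solve.
#' @return named numeric `c(plaice=, sole=)`; `NA` for an extinct species or
#'   one without landings.
#' @export
discard_fraction_at <- function(params, omega = 0, E = 1, init = NULL,
                                control = flatmix_control(), eq = NULL) {
  if (is.null(eq))
    eq <- solve_equilibrium(params, omega, E, init = init, control = control)
  out <- eq$metrics$discard_ratio
  out[eq$extinct] <- NA_real_
  attr(out, "equilibrium") <- eq
  out
}

set_f_LJ <- function(params, species, value) {
  params$species[[species]]$f[["LJ"]] <- value
  params
}

#' Tune large-juvenile catchabilities to target discard fractions
#'
#' Finds, independently per species, the large-juvenile catchability `f_LJ`
#' at which the equilibrium discard-over-landings fraction equals a target.
#' Tuning is done at zero resource overlap -- there the two stocks are
#' uncoupled, so the two scalar root-finding problems are independent -- and
#' at a reference effort of 1, the effort at which the adult catchabilities
#' reproduce the assessment fishing mortalities; both are explicit arguments.
#' Every evaluation re-solves the equilibrium (the stock structure itself
#' depends on `f_LJ`); solves are warm-started from the previous equilibrium.
#'
#' The realized fraction is 0 at `f_LJ = 0` and increasing in `f_LJ`, so a
#' bracketing root-find applies: the initial upper bound is scaled from the
#' `f_LJ = 0` equilibrium (`target * f_A * A / LJ`) and expanded by doubling
#' until the target is straddled.
#'
#' @inheritParams solve_equilibrium
#' @param targets named target fractions `c(plaice=, sole=)`, each in (0, 1).
#' @param E_ref reference effort at which the targets must be realized.
#' @param rtol relative tolerance on the tuned catchability.
#' @param max_expand maximum number of bracket doublings.
#' @return a list of class `flatmix_calibration` with named vectors `f_LJ`
#'   (tuned catchabilities), `achieved` (fractions realized when re-solving
#'   with the tuned values), `target`, plus `omega` and `E_ref`.
#' @export
tune_catchability <- function(params, omega = 0,
                              targets = c(plaice = 0.3, sole = 0.1),
                              E_ref = 1, rtol = 1e-6, max_expand = 30,
                              control = flatmix_control()) {
  stopifnot(all(c("plaice", "sole") %in% names(targets)),
            all(targets > 0), all(targets < 1), E_ref > 0)
  tuned <- setNames(numeric(2), c("plaice", "sole"))
  for (nm in c("plaice", "sole")) {
    target <- targets[[nm]]
    warm <- new.env()
    frac_at <- function(f) {
      p <- set_f_LJ(params, nm, f)
      eq <- solve_equilibrium(p, omega, E_ref,
                              init = warm$state, control = control)
      warm$state <- eq$state
      if (eq$extinct[[nm]])
        stop(nm, " goes extinct during tuning at f_LJ = ", f, call. = FALSE)
      eq$metrics$discard_ratio[[nm]]
    }
    base <- solve_equilibrium(set_f_LJ(params, nm, 0), omega, E_ref,
                              control = control)
    if (base$extinct[[nm]])
      stop(nm, " does not persist at the reference effort", call. = FALSE)
    warm$state <- base$state
    sp <- params$species[[nm]]
    guess <- target * sp$f[["A"]] * base$state[[species_idx[[nm]][3]]] /
      base$state[[species_idx[[nm]][2]]]
    hi <- guess
    expand <- 0
    while (frac_at(hi) < target) {
      hi <- hi * 2
      expand <- expand + 1
      if (expand > max_expand)
        stop("bracket expansion failed for ", nm,
             " (target ", target, " not reachable below f_LJ = ", hi, ")",
             call. = FALSE)
    }
    root <- uniroot(function(f) frac_at(f) - target, lower = 0, upper = hi,
                    tol = rtol * hi / 2)
    tuned[nm] <- root$root
  }
  p2 <- set_f_LJ(set_f_LJ(params, "plaice", tuned[["plaice"]]),
                 "sole", tuned[["sole"]])
  achieved <- discard_fraction_at(p2, omega, E_ref, control = control)
  attr(achieved, "equilibrium") <- NULL
  structure(list(f_LJ = tuned, achieved = achieved,
                 target = setNames(as.numeric(targets[c("plaice", "sole")]),
                                   c("plaice", "sole")),
                 omega = omega, E_ref = E_ref),
            class = "flatmix_calibration")
}

#' @export
print.flatmix_calibration <- function(x, ...) {
  cat(sprintf("discard calibration at omega = %g, E_ref = %g\n",
              x$omega, x$E_ref))
  print(data.frame(species = names(x$f_LJ), f_LJ = x$f_LJ,
                   target = x$target, achieved = x$achieved,
                   row.names = NULL))
  invisible(x)
}
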