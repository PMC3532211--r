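## Configuration and tabular IO: YAML parameter files mirroring the default
## parameter table, CSV curve output with a metadata header, JSON reports.

# Small stable fingerprint of an R object (djb2 over its serialized bytes);
# stamped into output headers so a curve file can be matched to the exact
# configuration that produced it.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.species_keys <- c("L_J", "L_LJ", "L_A", "lw_a", "lw_b", "I_max_J",
                   "I_max_LJ", "I_max_A", "T", "delta", "mu")
.fishery_keys <- c("f_LJ", "f_A", "price")
.resource_keys <- c("r", "K_m", "K_p", "R_h", "omega")

species_to_config <- function(sp) {
  list(L_J = unname(sp$L[["J"]]), L_LJ = unname(sp$L[["LJ"]]),
       L_A = unname(sp$L[["A"]]), lw_a = sp$lw_a, lw_b = sp$lw_b,
       I_max_J = unname(sp$I_max[["J"]]), I_max_LJ = unname(sp$I_max[["LJ"]]),
       I_max_A = unname(sp$I_max[["A"]]), T = sp$T_maint, delta = sp$delta,
       mu = sp$mu)
}

#' Write a parameter set to a YAML configuration file
#'
#' One block per species (stage lengths, length-weight rule, ingestion,
#' maintenance, conversion, mortality), one resource block, one fishery
#' block (catchabilities and prices). The file round-trips through
#' [load_params_config()].
#'
#' @param params a [flatmix_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "flatmix_params"))
  cfg <- list(
    resources = params$resources[.resource_keys],
    plaice = species_to_config(params$species$plaice),
    sole = species_to_config(params$species$sole),
    fishery = lapply(params$species, function(sp)
      list(f_LJ = unname(sp$f[["LJ"]]), f_A = unname(sp$f[["A"]]),
           price = sp$price))
  )
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

check_keys <- function(block, expected, where) {
  unknown <- setdiff(names(block), expected)
  if (length(unknown))
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(expected, names(block))
  if (length(missing))
    stop("missing key(s) in ", where, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
}

#' Load a parameter set from a YAML configuration file
#'
#' Reads and validates a configuration written by [write_params_config()]
#' (or the shipped default, `system.file("extdata", "default_params.yaml",
#' package = "flatmix")`). Unknown or missing keys are rejected by name;
#' parameter invariants (e.g. `omega` in `[0, 1]`, increasing stage lengths)
#' are enforced by the constructors; the derivable stage weights and mass
#' ratios of the default species are re-derived and checked against their
#' printed references, with a warning carrying the diff report on failure.
#'
#' @param path YAML file path.
#' @return a [flatmix_params()] object.
#' @export
load_params_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("resources", "plaice", "sole", "fishery"), "config")
  check_keys(cfg$resources, .resource_keys, "resources")
  check_keys(cfg$fishery, c("plaice", "sole"), "fishery")
  build_species <- function(nm) {
    blk <- cfg[[nm]]
    check_keys(blk, .species_keys, nm)
    fsh <- cfg$fishery[[nm]]
    check_keys(fsh, .fishery_keys, paste0("fishery$", nm))
    species_params(
      name = nm,
      L = c(J = blk$L_J, LJ = blk$L_LJ, A = blk$L_A),
      lw_a = blk$lw_a, lw_b = blk$lw_b,
      I_max = c(J = blk$I_max_J, LJ = blk$I_max_LJ, A = blk$I_max_A),
      T_maint = blk$T, delta = blk$delta, mu = blk$mu,
      price = fsh$price, f_LJ = fsh$f_LJ, f_A = fsh$f_A)
  }
  pars <- flatmix_params(
    plaice = build_species("plaice"), sole = build_species("sole"),
    resources = do.call(resource_params, cfg$resources))
  rep <- derivation_report(pars)
  if (!is.null(rep) && any(!rep$ok)) {
    bad <- rep[!rep$ok, , drop = FALSE]
    warning("derived parameter(s) miss their printed reference:\n",
            paste(utils::capture.output(print(bad, row.names = FALSE)),
                  collapse = "\n"), call. = FALSE)
  }
  pars
}

#' Path to the shipped default configuration
#'
#' @return path of the installed `default_params.yaml`.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_params.yaml", package = "flatmix",
              mustWork = TRUE)
}

#' Write a sweep to CSV
#'
#' One row per grid point in the stable column order of
#' [as.data.frame.flatmix_curve()], floats at 12 significant digits,
#' preceded by `#`-prefixed metadata lines (package version, sweep kind,
#' configuration hash and, when given, the RNG seed).
#'
#' @param curve a `flatmix_curve`.
#' @param path output CSV path.
#' @param seed optional seed to record in the metadata header.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path, seed = NULL) {
  stopifnot(inherits(curve, "flatmix_curve"))
  df <- as.data.frame(curve)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 12,
                                                 format = "g"))
  meta <- c(
    sprintf("# flatmix %s", as.character(utils::packageVersion("flatmix"))),
    sprintf("# kind: %s", curve$kind),
    sprintf("# config_hash: %s", config_hash(curve$params)),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a curve CSV
#'
#' @param path CSV written by [write_curve_csv()].
#' @return a data.frame (metadata lines skipped).
#' @export
read_curve_csv <- function(path) {
  read.table(path, header = TRUE, sep = ",", comment.char = "#")
}

#' Write a report (or any list) as JSON
#'
#' `flatmix_report` objects are flattened to their check table plus any
#' scalar extras; heavy components (curves, parameter sets) are dropped.
#'
#' @param report a `flatmix_report` or plain list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (inherits(report, "flatmix_report")) {
    keep <- setdiff(names(report),
                    c("curve", "params_equalized", "revenue_report",
                      "analysis"))
    out <- report[keep]
    if (!is.null(report$analysis))
      out$analysis <- list(modality = report$analysis$modality,
                           maxima = report$analysis$maxima)
  } else out <- report
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
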