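# Run configuration: one structured text (YAML) file aggregating the
# physical parameters, with defaults at the published study conditions.

#' Run configuration
#'
#' Aggregates all tunable parameters with defaults at the standard study
#' conditions: dielectrics 4/78.4, ionic strength 0.15 M, packing tolerance
#' optimum 1.3 A (perturbed to 0.8/1.6 A in scans), physiological window pH
#' 6-8, repack scan at pH 6.5, pH grid 0-14 step 0.1.
#'
#' @param env a [dielectric_environment()]
#' @param packing a [packing_config()]
#' @param grid a [grid_spec()] or NULL for the default focusing protocol
#' @param window a [sensor_window()]
#' @param mc list(steps, seed) Monte Carlo protocol
#' @param tolerances list(optimum, low, high) clash tolerances, Angstrom
#' @param scan_ph repacking-scan pH
#' @param ph_grid titration pH grid
#' @param include_termini,include_tyr_cys site enumeration switches
#' @return a `fddh_config`
#' @export
run_config <- function(env = dielectric_environment(),
                       packing = packing_config(),
                       grid = NULL,
                       window = sensor_window(),
                       mc = list(steps = NULL, seed = 1),
                       tolerances = list(optimum = 1.3, low = 0.8, high = 1.6),
                       scan_ph = 6.5,
                       ph_grid = seq(0, 14, 0.1),
                       include_termini = FALSE,
                       include_tyr_cys = FALSE) {
  structure(list(env = env, packing = packing, grid = grid, window = window,
                 mc = mc, tolerances = tolerances, scan_ph = scan_ph,
                 ph_grid = ph_grid, include_termini = include_termini,
                 include_tyr_cys = include_tyr_cys), class = "fddh_config")
}

#' Write a run configuration to YAML
#' @param config a [run_config()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_config <- function(config, path) {
  flat <- list(
    eps_protein = config$env$eps_protein,
    eps_solvent = config$env$eps_solvent,
    ionic_strength = config$env$ionic_strength,
    temperature = config$env$temperature,
    probe_radius = config$env$probe_radius,
    ion_exclusion_radius = config$env$ion_exclusion_radius,
    clash_tolerance = config$packing$clash_tolerance,
    dh_threshold = config$packing$dh_threshold,
    tol_optimum = config$tolerances$optimum,
    tol_low = config$tolerances$low,
    tol_high = config$tolerances$high,
    window_low = config$window$ph_low,
    window_high = config$window$ph_high,
    diagonal_tol = config$window$diagonal_tol,
    scan_ph = config$scan_ph,
    ph_min = min(config$ph_grid), ph_max = max(config$ph_grid),
    ph_step = config$ph_grid[2] - config$ph_grid[1],
    mc_seed = config$mc$seed,
    include_termini = config$include_termini,
    include_tyr_cys = config$include_tyr_cys)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path file written by [write_config()] (missing keys keep defaults)
#' @return a `fddh_config`
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
  env <- dielectric_environment(
    eps_protein = g("eps_protein", 4), eps_solvent = g("eps_solvent", 78.4),
    ionic_strength = g("ionic_strength", 0.15),
    temperature = g("temperature", 298.15),
    probe_radius = g("probe_radius", 1.4),
    ion_exclusion_radius = g("ion_exclusion_radius", 2.0))
  pk <- packing_config(clash_tolerance = g("clash_tolerance", 1.3),
                       dh_threshold = g("dh_threshold", 0.5))
  run_config(env = env, packing = pk,
             window = sensor_window(g("window_low", 6), g("window_high", 8),
                                    g("diagonal_tol", 0.5)),
             mc = list(steps = NULL, seed = g("mc_seed", 1)),
             tolerances = list(optimum = g("tol_optimum", 1.3),
                               low = g("tol_low", 0.8),
                               high = g("tol_high", 1.6)),
             scan_ph = g("scan_ph", 6.5),
             ph_grid = seq(g("ph_min", 0), g("ph_max", 14), g("ph_step", 0.1)),
             include_termini = g("include_termini", FALSE),
             include_tyr_cys = g("include_tyr_cys", FALSE))
}

# Polynomial rolling hash of the resolved configuration, for output
# provenance headers.
config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "grid")]), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# CSV with provenance comment header.
write_output_csv <- function(df, path, config = NULL, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fddh %s", as.character(utils::packageVersion("fddh"))),
             con)
  if (!is.null(config))
    writeLines(sprintf("# config %s", config_hash(config)), con)
  for (e in extra) writeLines(paste0("# ", e), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
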