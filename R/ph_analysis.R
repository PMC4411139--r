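# Candidate-functional-residue discovery and classification: conformer pKa
# differencing with a physiological window, repacking-tolerance perturbation
# scans, pH-sensor vs pH-coupled mutation classification, pH50 crossover.

#' Physiological sensor window
#' @param ph_low,ph_high pH range of physiological interest (default 6-8)
#' @param diagonal_tol minimum pKa difference between conditions to count as
#'   off-diagonal, pH units
#' @return a `fddh_sensor_window`
#' @export
sensor_window <- function(ph_low = 6, ph_high = 8, diagonal_tol = 0.5) {
  stopifnot(ph_low < ph_high)
  structure(list(ph_low = ph_low, ph_high = ph_high,
                 diagonal_tol = diagonal_tol), class = "fddh_sensor_window")
}

#' Scatter of per-site pKas between two conformers
#'
#' Pairs each site's pK-half in condition A (e.g. closed) with condition B
#' (e.g. open).  Site sets must match after trimming correspondence.
#'
#' @param pka_a,pka_b `fddh_pka_table`s of the two conditions
#' @return a `fddh_cfr_scan` data.frame (value_a, value_b per site)
#' @export
conformer_pka_scatter <- function(pka_a, pka_b) {
  a <- pka_a$per_site; b <- pka_b$per_site
  ka <- paste(a$chain, a$resno, a$restype)
  kb <- paste(b$chain, b$resno, b$restype)
  if (!setequal(ka, kb)) {
    missing <- c(setdiff(ka, kb), setdiff(kb, ka))
    stop("unmatched site(s) between conformers: ",
         paste(missing, collapse = ", "))
  }
  b <- b[match(ka, kb), , drop = FALSE]
  out <- data.frame(chain = a$chain, resno = a$resno, restype = a$restype,
                    value_a = a$pk_half, value_b = b$pk_half,
                    flag_a = a$flag, flag_b = b$flag,
                    flagged = NA, stringsAsFactors = FALSE)
  attr(out, "scan_kind") <- "conformer"
  class(out) <- c("fddh_cfr_scan", "data.frame")
  out
}

#' Flag candidate pH-sensor sites in a conformer scatter
#'
#' A site is flagged when its two pKas differ by at least the diagonal
#' tolerance and the pair is not entirely below or entirely above the
#' physiological window: points on the diagonal, or off-diagonal with both
#' values < ph_low or both > ph_high, are not of interest.
#'
#' @param scatter a conformer `fddh_cfr_scan`
#' @param window a [sensor_window()]
#' @return the scan with the `flagged` column filled
#' @export
flag_sensor_candidates <- function(scatter, window = sensor_window()) {
  if (!identical(attr(scatter, "scan_kind"), "conformer"))
    stop("flag_sensor_candidates expects a conformer scan")
  a <- scatter$value_a; b <- scatter$value_b
  scatter$flagged <- abs(a - b) >= window$diagonal_tol &
    !(a < window$ph_low & b < window$ph_low) &
    !(a > window$ph_high & b > window$ph_high)
  attr(scatter, "window") <- window
  scatter
}

# HH charge of one isolated site at a pH.
hh_site_charge <- function(site, ph) {
  if (site$ionized_charge < 0) -1 / (1 + 10^(site$model_pka - ph))
  else 1 / (1 + 10^(ph - site$model_pka))
}

#' Full pKa/energy pipeline for one conformer
#'
#' Repairs sidechains, parameterizes, enumerates sites, assesses attainable
#' accessibility at the optimum clash tolerance, builds the hybrid FD/DH
#' model, titrates (exact enumeration up to 16 sites, Monte Carlo beyond)
#' and integrates the pH-dependent ionization free energy (anchored at the
#' acidic end of the grid, where every group is protonated in both folded
#' and reference states).
#'
#' @param assembly an `fddh_assembly`
#' @param config a [run_config()]
#' @param clash_tolerance override of the packing tolerance
#' @param fdpb_only force FD treatment for all sites
#' @return list(model, curve, pka, energy, accessibility, sites)
#' @export
ph_energy_pipeline <- function(assembly, config = run_config(),
                               clash_tolerance = NULL, fdpb_only = FALSE) {
  asm <- repair_sidechains(assembly)
  asm <- parameterize(asm)
  sites <- enumerate_titratable_sites(asm,
                                      include_termini = config$include_termini,
                                      include_tyr_cys = config$include_tyr_cys)
  if (nrow(sites) == 0) stop("no titratable sites in ", assembly$label)
  pc <- config$packing
  if (!is.null(clash_tolerance)) pc$clash_tolerance <- clash_tolerance
  acc <- accessibility_scan(asm, sites, pc$clash_tolerance, pc)
  model <- if (fdpb_only)
    build_fdpb_only_model(asm, sites, env = config$env, grid = config$grid)
  else
    build_hybrid_model(asm, sites, acc, env = config$env, grid = config$grid)
  curve <- if (nrow(sites) <= 16)
    enumerate_exact(model, config$ph_grid)
  else
    monte_carlo_titrate(model, config$ph_grid, seed = config$mc$seed)
  pka <- compute_pkhalf(curve)
  energy <- ionization_free_energy_curve(curve, model,
                                         ph_ref = min(config$ph_grid))
  list(model = model, curve = curve, pka = pka, energy = energy,
       accessibility = acc, sites = sites, assembly = asm)
}

#' Repacking-tolerance perturbation scan
#'
#' A one-conformation probe for partially buried ionizable groups: the vdW
#' clash tolerance is set below and above its optimum (0.8 and 1.6 A), the
#' full accessibility/hybrid/titration pipeline is rebuilt at each value, and
#' per site the ionization difference from the isolated compound at the scan
#' pH, dq = q_folded - q_model, is differenced between tolerances.  Sites
#' whose ionization state responds to the packing perturbation (difference at
#' least `offdiag_charge_tol`) are flagged as candidates.
#'
#' @param assembly an `fddh_assembly`
#' @param tol_low,tol_high perturbation clash tolerances, Angstrom
#' @param scan_ph pH of the scan (default 6.5)
#' @param config a [run_config()]
#' @param offdiag_charge_tol flagging threshold on |dq(low) - dq(high)|, e
#' @return a repacking `fddh_cfr_scan`
#' @export
repack_perturbation_scan <- function(assembly, tol_low = 0.8, tol_high = 1.6,
                                     scan_ph = 6.5, config = run_config(),
                                     offdiag_charge_tol = 0.5) {
  dq_at <- function(tol) {
    pl <- ph_energy_pipeline(assembly, config, clash_tolerance = tol)
    ip <- which.min(abs(pl$curve$ph_grid - scan_ph))
    q_fold <- pl$curve$mean_charge[ip, ]
    q_model <- vapply(seq_len(nrow(pl$sites)), function(i)
      hh_site_charge(pl$sites[i, ], scan_ph), 0)
    list(sites = pl$sites, dq = q_fold - q_model)
  }
  lo <- dq_at(tol_low)
  hi <- dq_at(tol_high)
  out <- data.frame(chain = lo$sites$chain, resno = lo$sites$resno,
                    restype = lo$sites$restype,
                    value_a = lo$dq, value_b = hi$dq,
                    flagged = abs(lo$dq - hi$dq) >= offdiag_charge_tol,
                    stringsAsFactors = FALSE)
  attr(out, "scan_kind") <- "repacking"
  attr(out, "scan_ph") <- scan_ph
  attr(out, "tolerances") <- c(tol_low, tol_high)
  attr(out, "offdiag_charge_tol") <- offdiag_charge_tol
  class(out) <- c("fddh_cfr_scan", "data.frame")
  out
}

#' Difference of two pH-energy curves (open minus closed)
#' @param open_curve,closed_curve `fddh_energy_curve`s on the same pH grid
#' @return a `fddh_energy_curve` of the pointwise difference
#' @export
delta_energy_curve <- function(open_curve, closed_curve) {
  if (length(open_curve$ph) != length(closed_curve$ph) ||
      max(abs(open_curve$ph - closed_curve$ph)) > 1e-9)
    stop("pH grid mismatch between curves")
  out <- data.frame(ph = open_curve$ph, dG = open_curve$dG - closed_curve$dG)
  attr(out, "kT") <- attr(open_curve, "kT")
  class(out) <- c("fddh_energy_curve", "data.frame")
  out
}

#' Classify a mutation as pH-sensor, pH-coupled, or neither
#'
#' Straight lines are fitted (ordinary least squares) to the wild-type and
#' mutant open-minus-closed energy curves over the physiological window.  A
#' change of slope marks a pH-sensor (ionization differs between conformers
#' in the window); a parallel shift marks pH-coupling (the mutation moves
#' pH50 without sensing protons).
#'
#' @param wt_delta,mut_delta `fddh_energy_curve`s (open minus closed) on a
#'   grid covering the window
#' @param window a [sensor_window()]
#' @param slope_tol threshold on |slope difference|, kcal/mol per pH unit
#' @param offset_tol threshold on |mean shift|, kcal/mol
#' @return a `fddh_mutation_class`: slope_diff, offset, label
#' @export
classify_mutation <- function(wt_delta, mut_delta, window = sensor_window(),
                              slope_tol = 0.3, offset_tol = 0.3) {
  sel <- wt_delta$ph >= window$ph_low & wt_delta$ph <= window$ph_high
  if (sum(sel) < 2) stop("window outside the curve's pH grid")
  if (length(wt_delta$ph) != length(mut_delta$ph) ||
      max(abs(wt_delta$ph - mut_delta$ph)) > 1e-9)
    stop("pH grid mismatch between curves")
  ph <- wt_delta$ph[sel]
  fit_wt <- stats::lm(wt_delta$dG[sel] ~ ph)
  fit_mut <- stats::lm(mut_delta$dG[sel] ~ ph)
  slope_diff <- unname(coef(fit_mut)[2] - coef(fit_wt)[2])
  offset <- mean(mut_delta$dG[sel] - wt_delta$dG[sel])
  label <- if (abs(slope_diff) >= slope_tol) "pH-sensor"
           else if (abs(offset) >= offset_tol) "pH-coupled"
           else "neither"
  structure(list(slope_diff = slope_diff, offset = offset, label = label,
                 slope_wt = unname(coef(fit_wt)[2]),
                 slope_mut = unname(coef(fit_mut)[2]),
                 window = window, slope_tol = slope_tol,
                 offset_tol = offset_tol), class = "fddh_mutation_class")
}

#' @export
print.fddh_mutation_class <- function(x, ...) {
  cat(sprintf("%s (slope diff %.3f kcal/mol/pH, offset %.3f kcal/mol)\n",
              x$label, x$slope_diff, x$offset))
  invisible(x)
}

#' pH50 crossover of open and closed energy curves
#'
#' pH at which the open-minus-closed energy changes sign (half-maximal
#' activation), by linear interpolation.  Returns an empty vector when the
#' curves never cross; multiple crossings are all returned with a warning.
#'
#' @param open_curve,closed_curve `fddh_energy_curve`s on the same grid
#' @return numeric vector of crossover pH values (possibly empty)
#' @export
find_ph50_crossover <- function(open_curve, closed_curve) {
  d <- delta_energy_curve(open_curve, closed_curve)
  ph <- d$ph; y <- d$dG
  n <- length(y)
  idx <- which(y[-n] * y[-1] < 0)
  exact0 <- which(y == 0)
  res <- vapply(idx, function(k)
    ph[k] - y[k] * (ph[k + 1] - ph[k]) / (y[k + 1] - y[k]), 0)
  res <- sort(unique(c(res, ph[exact0])))
  if (length(res) > 1) warning("multiple pH50 crossovers found")
  res
}

#' Calcium-binding mimic by carboxylate charge deletion
#'
#' Runs the conformer-difference pipeline for the unmodified pair and for the
#' pair with acidic charge-deletion mutations applied to the closed form
#' (mimicking bound calcium neutralizing the acids).  The sign of the window
#' slope of each delta curve is reported: a positive slope means the open
#' form gains relative stability as pH falls.
#'
#' @param closed,open assemblies of the two conformers
#' @param deletions list of [mutation_spec()] charge deletions applied to the
#'   closed form
#' @param config a [run_config()]
#' @return list(wt_delta, mut_delta, slope_wt, slope_mut)
#' @export
calcium_mimic_run <- function(closed, deletions, open, config = run_config()) {
  tr <- trim_to_common_length(closed, open)
  closed <- tr$a; open <- tr$b
  closed_mut <- closed
  for (d in deletions) {
    if (d$operation != "charge_delete")
      stop("calcium mimic uses charge_delete mutations only")
    sel <- closed_mut$atoms$chain == d$chain & closed_mut$atoms$resno == d$resno
    if (!any(sel)) stop("deletion site ", res_key(d$chain, d$resno),
                        " missing from closed form")
    if (!closed_mut$atoms$resname[sel][1] %in% c("ASP", "GLU"))
      stop("calcium mimic deletions must target acidic sites")
    closed_mut <- apply_mutation(closed_mut, d)
  }
  p_open <- ph_energy_pipeline(open, config)
  p_closed <- ph_energy_pipeline(closed, config)
  wt_delta <- delta_energy_curve(p_open$energy, p_closed$energy)
  p_closed_mut <- ph_energy_pipeline(closed_mut, config)
  mut_delta <- delta_energy_curve(p_open$energy, p_closed_mut$energy)
  w <- config$window
  sel <- wt_delta$ph >= w$ph_low & wt_delta$ph <= w$ph_high
  sl <- function(cv) unname(coef(stats::lm(cv$dG[sel] ~ cv$ph[sel]))[2])
  list(wt_delta = wt_delta, mut_delta = mut_delta,
       slope_wt = sl(wt_delta), slope_mut = sl(mut_delta))
}

#' Compare two conformers end to end
#'
#' Trims the pair to common length, runs the pipeline on both, and returns
#' the pKa scatter with sensor-window flags plus the open-minus-closed
#' energy curve.
#'
#' @param closed,open assemblies ("condition A" and "condition B")
#' @param config a [run_config()]
#' @return list(scatter, delta, pipelines)
#' @export
compare_conformers <- function(closed, open, config = run_config()) {
  tr <- trim_to_common_length(closed, open)
  pa <- ph_energy_pipeline(tr$a, config)
  pb <- ph_energy_pipeline(tr$b, config)
  sc <- conformer_pka_scatter(pa$pka, pb$pka)
  sc <- flag_sensor_candidates(sc, config$window)
  delta <- delta_energy_curve(pb$energy, pa$energy)
  list(scatter = sc, delta = delta,
       pipelines = list(closed = pa, open = pb))
}
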