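# Finite-difference linearized Poisson-Boltzmann: focusing driver, energy
# terms, potential maps.

#' Dielectric environment
#'
#' Continuum parameters: relative dielectric 4 (protein interior) and 78.4
#' (solvent), 0.15 M ionic strength, 298.15 K, 1.4 A water probe for the
#' molecular boundary and a 2.0 A Stern (ion exclusion) layer.
#'
#' @param eps_protein,eps_solvent relative permittivities
#' @param ionic_strength mol/L (1:1 salt)
#' @param temperature Kelvin
#' @param probe_radius,ion_exclusion_radius Angstrom
#' @return a `fddh_env`
#' @export
dielectric_environment <- function(eps_protein = 4, eps_solvent = 78.4,
                                   ionic_strength = 0.15,
                                   temperature = 298.15,
                                   probe_radius = 1.4,
                                   ion_exclusion_radius = 2.0) {
  structure(list(eps_protein = eps_protein, eps_solvent = eps_solvent,
                 ionic_strength = ionic_strength, temperature = temperature,
                 probe_radius = probe_radius,
                 ion_exclusion_radius = ion_exclusion_radius,
                 kT = kT_kcal(temperature),
                 kappa = kappa_from_ionic_strength(ionic_strength, temperature,
                                                   eps_solvent)),
            class = "fddh_env")
}

#' Cubic grid specification
#'
#' Either an explicit single grid (`dims`, `spacing`, `center`) or a focusing
#' protocol (`focusing_levels`, coarse to fine) with boxes sized
#' automatically: the coarsest level covers the whole assembly, the finest is
#' centred on the source charges with a generous border.
#'
#' @param spacing grid spacing, Angstrom (finest level)
#' @param dims integer triple for an explicit grid (optional)
#' @param center grid centre for an explicit grid (optional)
#' @param focusing_levels spacings coarse to fine, Angstrom
#' @param max_dim cap on points per axis
#' @return a `fddh_grid_spec`
#' @export
grid_spec <- function(spacing = 0.6, dims = NULL, center = NULL,
                      focusing_levels = c(2.4, 1.2, 0.6), max_dim = 161) {
  stopifnot(spacing > 0)
  structure(list(spacing = spacing, dims = dims, center = center,
                 focusing_levels = focusing_levels, max_dim = max_dim),
            class = "fddh_grid_spec")
}

.odd_dim <- function(n) { n <- as.integer(ceiling(n)); n + (1L - n %% 2L) }

# Plan focusing levels: list of (dims, spacing, origin).
plan_levels <- function(assembly, charges, grid) {
  if (!is.null(grid$dims)) {
    d <- rep(grid$dims, length.out = 3)
    ctr <- if (is.null(grid$center)) c(mean(charges$x), mean(charges$y),
                                       mean(charges$z)) else grid$center
    org <- ctr - (d - 1) / 2 * grid$spacing
    return(list(list(dims = as.integer(d), spacing = grid$spacing, origin = org)))
  }
  spc <- sort(grid$focusing_levels, decreasing = TRUE)
  pts_chg <- as.matrix(charges[, c("x", "y", "z")])
  pts_all <- pts_chg
  if (!is.null(assembly) && nrow(assembly$atoms) > 0)
    pts_all <- rbind(pts_all, as.matrix(assembly$atoms[, c("x", "y", "z")]))
  lv <- list()
  for (li in seq_along(spc)) {
    h <- spc[li]
    if (li == 1) { pts <- pts_all; border <- 16 }
    else if (li == length(spc)) { pts <- pts_chg; border <- 6 }
    else { pts <- pts_chg; border <- 10 }
    lo <- apply(pts, 2, min) - border
    hi <- apply(pts, 2, max) + border
    d <- pmin(.odd_dim((hi - lo) / h + 1), .odd_dim(grid$max_dim))
    ctr <- (lo + hi) / 2
    org <- ctr - (d - 1) / 2 * h
    lv[[li]] <- list(dims = as.integer(d), spacing = h, origin = org)
  }
  lv
}

#' Solve the linearized Poisson-Boltzmann equation
#'
#' Iterative finite-difference relaxation with a molecular (probe-rolled)
#' dielectric boundary, Debye-Hueckel analytic values on the coarse-grid
#' boundary and successive focusing onto finer grids.  Potentials are in
#' kT/e.
#'
#' @param assembly parameterized `fddh_assembly` defining the dielectric
#'   boundary, or NULL for uniform solvent
#' @param charges data.frame(x, y, z, q) of source charges (e)
#' @param env a [dielectric_environment()]
#' @param grid a [grid_spec()]; NULL for the default focusing protocol
#' @param tol convergence threshold on the maximum potential update, kT/e
#' @param max_iter relaxation iteration cap per level
#' @return a `fddh_potential_map` (all focusing levels retained)
#' @export
solve_lpbe <- function(assembly, charges, env = dielectric_environment(),
                       grid = NULL, tol = 1e-6, max_iter = 5000) {
  if (is.null(grid)) grid <- grid_spec()
  stopifnot(all(c("x", "y", "z", "q") %in% names(charges)))
  atoms_xyz <- matrix(numeric(0), 0, 3); atoms_rad <- numeric(0)
  if (!is.null(assembly) && nrow(assembly$atoms) > 0) {
    if (is.null(assembly$atoms$radius) || anyNA(assembly$atoms$radius))
      stop("assembly must be parameterized")
    atoms_xyz <- as.matrix(assembly$atoms[, c("x", "y", "z")])
    atoms_rad <- assembly$atoms$radius
  }
  levels <- plan_levels(assembly, charges, grid)
  coul_kT <- .COULOMB / env$kT
  chg_xyz <- as.matrix(charges[, c("x", "y", "z")])
  chg_q <- charges$q
  maps <- list()
  for (li in seq_along(levels)) {
    lv <- levels[[li]]
    if (li == 1) {
      phi0 <- dh_grid_cpp(chg_xyz, chg_q, env$eps_solvent, env$kappa,
                          lv$dims, lv$spacing, lv$origin, coul_kT, FALSE)
    } else {
      prev <- maps[[li - 1]]
      nodes <- grid_nodes(lv)
      phi0 <- grid_interp_cpp(prev$phi, prev$dims, prev$origin, prev$spacing,
                              nodes)
      out <- is.na(phi0)
      if (any(out))
        phi0[out] <- dh_grid_cpp(chg_xyz, chg_q, env$eps_solvent, env$kappa,
                                 lv$dims, lv$spacing, lv$origin, coul_kT,
                                 FALSE)[out]
    }
    sol <- lpbe_level_cpp(atoms_xyz, atoms_rad, chg_xyz, chg_q,
                          env$eps_protein, env$eps_solvent, env$kappa,
                          env$probe_radius, env$ion_exclusion_radius,
                          lv$dims, lv$spacing, lv$origin, phi0, coul_kT,
                          tol, max_iter)
    if (!sol$converged)
      warning(sprintf("LPBE level %d: max update %.2e after %d iterations",
                      li, sol$max_update, sol$iterations))
    maps[[li]] <- list(phi = sol$phi, dims = lv$dims, spacing = lv$spacing,
                       origin = lv$origin, iterations = sol$iterations)
  }
  structure(list(levels = maps, env = env, charges = charges,
                 label = if (is.null(assembly)) "uniform" else assembly$label),
            class = "fddh_potential_map")
}

grid_nodes <- function(lv) {
  xs <- lv$origin[1] + (seq_len(lv$dims[1]) - 1) * lv$spacing
  ys <- lv$origin[2] + (seq_len(lv$dims[2]) - 1) * lv$spacing
  zs <- lv$origin[3] + (seq_len(lv$dims[3]) - 1) * lv$spacing
  as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
}

#' @export
print.fddh_potential_map <- function(x, ...) {
  f <- x$levels[[length(x$levels)]]
  cat(sprintf("fddh potential map '%s': %d level(s), finest %dx%dx%d @ %.2f A\n",
              x$label, length(x$levels), f$dims[1], f$dims[2], f$dims[3],
              f$spacing))
  invisible(x)
}

#' Evaluate a potential map at points
#'
#' Trilinear interpolation from the finest focusing level containing each
#' point, falling back to coarser levels outside it.
#'
#' @param map a `fddh_potential_map`
#' @param pts matrix or data.frame with columns x, y, z
#' @return potentials in kT/e (NA outside all levels)
#' @export
potential_at <- function(map, pts) {
  pts <- as.matrix(as.data.frame(pts)[, c("x", "y", "z")])
  val <- rep(NA_real_, nrow(pts))
  for (li in rev(seq_along(map$levels))) {
    lv <- map$levels[[li]]
    need <- is.na(val)
    if (!any(need)) break
    v <- grid_interp_cpp(lv$phi, lv$dims, lv$origin, lv$spacing,
                         pts[need, , drop = FALSE])
    val[need] <- v
  }
  val
}

# Grid interaction energy of a charge set with a map, in kT.
map_energy <- function(map, charges, self = FALSE) {
  phi <- potential_at(map, charges)
  e <- sum(charges$q * phi)
  if (self) e <- e / 2
  e
}

# Internal: solve with an explicit list of levels (identical grid placement).
solve_with_levels <- function(assembly, charges, env, levels,
                              tol = 1e-6, max_iter = 5000) {
  atoms_xyz <- matrix(numeric(0), 0, 3); atoms_rad <- numeric(0)
  if (!is.null(assembly) && nrow(assembly$atoms) > 0) {
    atoms_xyz <- as.matrix(assembly$atoms[, c("x", "y", "z")])
    atoms_rad <- assembly$atoms$radius
  }
  coul_kT <- .COULOMB / env$kT
  chg_xyz <- as.matrix(charges[, c("x", "y", "z")])
  chg_q <- charges$q
  maps <- list()
  for (li in seq_along(levels)) {
    lv <- levels[[li]]
    if (li == 1) {
      phi0 <- dh_grid_cpp(chg_xyz, chg_q, env$eps_solvent, env$kappa,
                          lv$dims, lv$spacing, lv$origin, coul_kT, FALSE)
    } else {
      prev <- maps[[li - 1]]
      phi0 <- grid_interp_cpp(prev$phi, prev$dims, prev$origin, prev$spacing,
                              grid_nodes(lv))
      out <- is.na(phi0)
      if (any(out))
        phi0[out] <- dh_grid_cpp(chg_xyz, chg_q, env$eps_solvent, env$kappa,
                                 lv$dims, lv$spacing, lv$origin, coul_kT,
                                 FALSE)[out]
    }
    sol <- lpbe_level_cpp(atoms_xyz, atoms_rad, chg_xyz, chg_q,
                          env$eps_protein, env$eps_solvent, env$kappa,
                          env$probe_radius, env$ion_exclusion_radius,
                          lv$dims, lv$spacing, lv$origin, phi0, coul_kT,
                          tol, max_iter)
    maps[[li]] <- list(phi = sol$phi, dims = lv$dims, spacing = lv$spacing,
                       origin = lv$origin, iterations = sol$iterations)
  }
  structure(list(levels = maps, env = env, charges = charges,
                 label = if (is.null(assembly)) "uniform" else assembly$label),
            class = "fddh_potential_map")
}

# Assembly restricted to one residue (the isolated model compound in place).
residue_subassembly <- function(assembly, chain, resno) {
  sel <- assembly$atoms$chain == chain & assembly$atoms$resno == resno
  new_assembly(assembly$atoms[sel, , drop = FALSE],
               label = paste0(assembly$label, "-model-compound"))
}

#' Born desolvation energy of a titratable site
#'
#' Self-energy of the site's ionization charges in the folded dielectric
#' environment minus the same quantity in a reference state, computed with
#' identical grid placement so that the grid self-energy cancels.
#' `reference = "model_compound"` (default) uses the site's residue alone in
#' solvent; `reference = "solvated"` uses a uniform interior-dielectric run
#' (the reaction-field route, matching the analytic Born expression for a
#' charge centred in a low-dielectric sphere).
#'
#' @param assembly parameterized `fddh_assembly`
#' @param site one row of [enumerate_titratable_sites()], or a
#'   data.frame(x, y, z, q) of explicit charges
#' @param env a [dielectric_environment()]
#' @param grid a [grid_spec()] or NULL
#' @param reference reference state (see Details)
#' @return kcal/mol
#' @export
born_desolvation <- function(assembly, site, env = dielectric_environment(),
                             grid = NULL,
                             reference = c("model_compound", "solvated")) {
  reference <- match.arg(reference)
  if (is.data.frame(site) && all(c("x", "y", "z", "q") %in% names(site)))
    chg <- site
  else chg <- site_charge_atoms(assembly, site)
  fold <- solve_lpbe(assembly, chg, env, grid)
  if (reference == "model_compound") {
    sub <- residue_subassembly(assembly, site$chain, site$resno)
    ref <- solve_with_levels(sub, chg, env,
                             lapply(fold$levels, function(l)
                               list(dims = l$dims, spacing = l$spacing,
                                    origin = l$origin)))
    env$kT * (map_energy(fold, chg, self = TRUE) -
              map_energy(ref, chg, self = TRUE))
  } else {
    env_u <- env
    env_u$eps_solvent <- env$eps_protein
    env_u$kappa <- 0
    ref <- solve_with_levels(NULL, chg, env_u,
                             lapply(fold$levels, function(l)
                               list(dims = l$dims, spacing = l$spacing,
                                    origin = l$origin)))
    env$kT * (map_energy(ref, chg, self = TRUE) -
              map_energy(fold, chg, self = TRUE))
  }
}

#' Per-site FDPB energy terms
#'
#' For each requested site: the Born desolvation penalty and the background
#' (permanent partial charge) interaction, both folded minus isolated model
#' compound with identical grid placement, plus the row of ionized-ionized
#' interactions with every other site.
#'
#' @param assembly parameterized `fddh_assembly`
#' @param sites all titratable sites (data.frame)
#' @param which_sites integer indices of sites to compute (default all)
#' @param env a [dielectric_environment()]
#' @param grid a [grid_spec()] or NULL
#' @return list with `terms` (data.frame: dG_desolv, dG_background, kcal/mol)
#'   and `W` (rows for computed sites, kcal/mol)
#' @export
site_energy_terms <- function(assembly, sites, which_sites = seq_len(nrow(sites)),
                              env = dielectric_environment(), grid = NULL) {
  n <- nrow(sites)
  W <- matrix(NA_real_, n, n)
  terms <- data.frame(site = which_sites, dG_desolv = NA_real_,
                      dG_background = NA_real_)
  all_chg <- lapply(seq_len(n), function(j)
    site_charge_atoms(assembly, sites[j, ]))
  atoms <- assembly$atoms
  atom_pts <- data.frame(x = atoms$x, y = atoms$y, z = atoms$z,
                         q = atoms$charge)
  for (ii in seq_along(which_sites)) {
    i <- which_sites[ii]
    chg <- all_chg[[i]]
    fold <- solve_lpbe(assembly, chg, env, grid)
    sub <- residue_subassembly(assembly, sites$chain[i], sites$resno[i])
    ref <- solve_with_levels(sub, chg, env,
                             lapply(fold$levels, function(l)
                               list(dims = l$dims, spacing = l$spacing,
                                    origin = l$origin)))
    g_fold <- map_energy(fold, chg, self = TRUE)
    g_ref <- map_energy(ref, chg, self = TRUE)
    terms$dG_desolv[ii] <- env$kT * (g_fold - g_ref)
    bg_fold <- map_energy(fold, atom_pts)
    sub_atoms <- sub$atoms
    bg_ref <- map_energy(ref, data.frame(x = sub_atoms$x, y = sub_atoms$y,
                                         z = sub_atoms$z, q = sub_atoms$charge))
    terms$dG_background[ii] <- env$kT * (bg_fold - bg_ref)
    for (j in seq_len(n)) {
      if (j == i) { W[i, j] <- 0; next }
      W[i, j] <- env$kT * map_energy(fold, all_chg[[j]])
    }
  }
  list(terms = terms, W = W)
}

#' Site-site interaction matrix from FDPB
#'
#' W_ij is the energy of site j's ionized charges in the potential map of
#' site i (both fully ionized), symmetrized by averaging; the diagonal is
#' zero.
#'
#' @inheritParams site_energy_terms
#' @return symmetric matrix, kcal/mol
#' @export
pairwise_matrix <- function(assembly, sites, env = dielectric_environment(),
                            grid = NULL) {
  stopifnot(nrow(sites) >= 2)
  W <- site_energy_terms(assembly, sites, env = env, grid = grid)$W
  Ws <- (W + t(W)) / 2
  diag(Ws) <- 0
  Ws
}

#' Export a potential map in OpenDX format
#'
#' Writes the finest focusing level as an OpenDX scalar field (values in
#' kT/e) for display in PyMOL or similar.
#'
#' @param map a `fddh_potential_map`
#' @param path output file
#' @return `path`, invisibly
#' @export
export_dx <- function(map, path) {
  lv <- map$levels[[length(map$levels)]]
  nx <- lv$dims[1]; ny <- lv$dims[2]; nz <- lv$dims[3]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field (kT/e)",
    sprintf("object 1 class gridpositions counts %d %d %d", nx, ny, nz),
    sprintf("origin %.6f %.6f %.6f", lv$origin[1], lv$origin[2], lv$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", lv$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", lv$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", lv$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", nx, ny, nz),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            nx * ny * nz)), con)
  arr <- array(lv$phi, dim = lv$dims)
  vals <- as.numeric(aperm(arr, c(3, 2, 1)))  # z fastest in file
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6e %.6e %.6e", m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vals))
    writeLines(paste(sprintf("%.6e", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Read an OpenDX scalar field
#' @param path DX file written by [export_dx()] (or APBS-style)
#' @return a single-level `fddh_potential_map`
#' @export
read_dx <- function(path) {
  lines <- readLines(path)
  gp <- grep("gridpositions", lines, value = TRUE)[1]
  dims <- as.integer(strsplit(sub(".*counts ", "", gp), "\\s+")[[1]])
  org <- as.numeric(strsplit(sub("origin ", "",
                                 grep("^origin", lines, value = TRUE)[1]),
                             "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  h <- as.numeric(strsplit(sub("delta ", "", deltas[1]), "\\s+")[[1]])[1]
  start <- grep("data follows", lines)[1] + 1
  end <- grep("attribute", lines)
  end <- if (length(end) > 0) min(end[end > start]) - 1 else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  arr <- array(vals, dim = rev(dims))       # z fastest in file
  phi <- as.numeric(aperm(arr, c(3, 2, 1)))
  structure(list(levels = list(list(phi = phi, dims = dims, spacing = h,
                                    origin = org)),
                 env = NULL, charges = NULL, label = basename(path)),
            class = "fddh_potential_map")
}

#' Pointwise difference of two potential maps
#' @param a,b maps on identical grids
#' @return map of a - b
#' @export
difference_map <- function(a, b) {
  if (length(a$levels) != length(b$levels))
    stop("grid mismatch: different focusing structure")
  out <- a
  for (li in seq_along(a$levels)) {
    la <- a$levels[[li]]; lb <- b$levels[[li]]
    if (!identical(la$dims, lb$dims) ||
        max(abs(la$origin - lb$origin)) > 1e-9 ||
        abs(la$spacing - lb$spacing) > 1e-12)
      stop("grid mismatch at level ", li)
    out$levels[[li]]$phi <- la$phi - lb$phi
  }
  out$label <- paste0(a$label, "-", b$label)
  out
}

#' Residues inside a potential contour envelope
#'
#' Returns residues with at least one atom at which the (trilinearly
#' interpolated) potential reaches the contour level: at or above a positive
#' level, at or below a negative one.
#'
#' @param map a `fddh_potential_map`
#' @param level contour level in kT/e (non-zero)
#' @param assembly an `fddh_assembly`
#' @return data.frame(chain, resno, resname)
#' @export
contour_envelope_members <- function(map, level, assembly) {
  stopifnot(level != 0)
  a <- assembly$atoms
  phi <- potential_at(map, a)
  hit <- if (level > 0) phi >= level else phi <= level
  hit[is.na(hit)] <- FALSE
  rt <- residue_table(assembly)
  keys <- res_key(a$chain, a$resno)[hit]
  rt[res_key(rt$chain, rt$resno) %in% unique(keys), , drop = FALSE]
}
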