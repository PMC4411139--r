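# Self-consistent mean-field rotamer packing on a fixed backbone, and the
# maximal-attainable-accessibility assessment that gates FD vs DH treatment.

#' Packing configuration
#'
#' @param clash_tolerance allowed hard-sphere vdW overlap in Angstrom.  The
#'   optimized value is 1.2-1.4 (default 1.3); the perturbation scan uses
#'   0.8 and 1.6 to mimic more and less restrictive packing.
#' @param max_iterations mean-field iteration cap
#' @param convergence_tol maximum per-rotamer probability change at
#'   convergence
#' @param temperature_like_factor energy scale (kcal/mol) for rotamer
#'   probabilities
#' @param dh_threshold relative accessibility at or above which a site is
#'   eligible for Debye-Huckel treatment
#' @param clash_k harmonic overlap penalty constant, kcal/(mol A^2)
#' @return a `fddh_packing_config`
#' @export
packing_config <- function(clash_tolerance = 1.3, max_iterations = 100,
                           convergence_tol = 1e-4,
                           temperature_like_factor = 1.0,
                           dh_threshold = 0.5, clash_k = 25) {
  stopifnot(clash_tolerance >= 0)
  structure(list(clash_tolerance = clash_tolerance,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 temperature_like_factor = temperature_like_factor,
                 dh_threshold = dh_threshold, clash_k = clash_k),
            class = "fddh_packing_config")
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-sampling SASA with 960 points per atom and a 1.4 A probe by
#' default.  Requires a parameterized assembly (radii).
#'
#' @param assembly parameterized `fddh_assembly`
#' @param subset integer atom indices to report (default all)
#' @param probe probe radius, Angstrom
#' @param n_points sampling points per atom
#' @return numeric vector of per-atom SASA in A^2
#' @export
sasa <- function(assembly, subset = NULL, probe = 1.4, n_points = 960) {
  a <- assembly$atoms
  if (is.null(a$radius) || anyNA(a$radius))
    stop("assembly must be parameterized before SASA")
  if (is.null(subset)) subset <- seq_len(nrow(a))
  sasa_cpp(as.matrix(a[, c("x", "y", "z")]), a$radius, probe,
           as.integer(n_points), as.integer(subset))
}

# forcefield lookup for rotamer atoms
.atom_radius <- function(resname, names, ff = default_forcefield()) {
  idx <- match(paste(resname, names), paste(ff$res, ff$atom))
  ff$radius[idx]
}

# All rotamer coordinate sets for one residue: native first, then library.
# Returns list of data.frames (name, x, y, z, radius).
residue_rotamer_set <- function(assembly, chain, resno,
                                include_native = TRUE) {
  a <- assembly$atoms
  sel <- a$chain == chain & a$resno == resno
  res <- a[sel, , drop = FALSE]
  resname <- res$resname[1]
  get1 <- function(nm) unlist(res[res$name == nm, c("x", "y", "z")])
  N <- get1("N"); CA <- get1("CA"); C <- get1("C")
  CB <- if ("CB" %in% res$name) get1("CB") else ideal_cb(N, CA, C)
  side_names <- vapply(.SIDECHAIN_TOPO[[resname]], function(r) r$atom, "")
  out <- list()
  mk <- function(coords) {
    nms <- names(coords)
    data.frame(name = nms,
               x = vapply(coords, `[`, 0, 1),
               y = vapply(coords, `[`, 0, 2),
               z = vapply(coords, `[`, 0, 3),
               radius = .atom_radius(resname, nms), stringsAsFactors = FALSE)
  }
  if (include_native && length(side_names) > 0 &&
      all(side_names %in% res$name)) {
    nat <- res[match(side_names, res$name), , drop = FALSE]
    out[["native"]] <- data.frame(name = nat$name, x = nat$x, y = nat$y,
                                  z = nat$z,
                                  radius = .atom_radius(resname, nat$name),
                                  stringsAsFactors = FALSE)
  }
  chis <- rotamer_chis(resname)
  if (ncol(chis) > 0 || length(side_names) == 0) {
    if (length(side_names) == 0) {
      if (length(out) == 0) out[["native"]] <- mk(list())
    } else {
      for (r in seq_len(nrow(chis)))
        out[[paste0("rot", r)]] <-
          mk(build_sidechain_coords(resname, N, CA, CB, chis[r, ]))
    }
  } else if (length(side_names) > 0 && length(out) == 0) {
    # non-rotatable sidechain missing from structure: build extended
    out[["rot1"]] <- mk(build_sidechain_coords(resname, N, CA, CB,
                                               extended_chis(resname)))
  }
  out
}

# Worst hard-sphere overlap (A) between rotamer atoms and context atoms.
worst_overlap <- function(rot, ctx_xyz, ctx_rad) {
  if (nrow(rot) == 0 || nrow(ctx_xyz) == 0) return(-Inf)
  mx <- -Inf
  for (i in seq_len(nrow(rot))) {
    d <- sqrt((ctx_xyz[, 1] - rot$x[i])^2 + (ctx_xyz[, 2] - rot$y[i])^2 +
              (ctx_xyz[, 3] - rot$z[i])^2)
    ov <- rot$radius[i] + ctx_rad - d
    m <- max(ov)
    if (m > mx) mx <- m
  }
  mx
}

clash_energy <- function(rot, ctx_xyz, ctx_rad, tol, k) {
  if (nrow(rot) == 0 || nrow(ctx_xyz) == 0) return(0)
  e <- 0
  for (i in seq_len(nrow(rot))) {
    d <- sqrt((ctx_xyz[, 1] - rot$x[i])^2 + (ctx_xyz[, 2] - rot$y[i])^2 +
              (ctx_xyz[, 3] - rot$z[i])^2)
    ov <- pmax(0, rot$radius[i] + ctx_rad - tol - d)
    e <- e + k * sum(ov^2)
  }
  e
}

#' Mean-field sidechain packing
#'
#' Iterative self-consistent mean-field optimization of rotamer probability
#' vectors on a fixed backbone.  Energies are hard-sphere overlap penalties
#' beyond the clash tolerance, between rotamer atoms and the fixed context
#' and between rotamer pairs of mobile residues.  Deterministic: residues are
#' visited in order and equal-probability ties select the lowest rotamer
#' index.
#'
#' @param assembly parameterized `fddh_assembly`
#' @param config a [packing_config()]
#' @param mobile data.frame(chain, resno) of mobile residues; default all
#'   residues with rotatable sidechains
#' @return a `fddh_packing_result`: probabilities, selected rotamers, the
#'   repacked assembly, convergence flag and free-energy trace
#' @export
mean_field_pack <- function(assembly, config = packing_config(), mobile = NULL) {
  a <- assembly$atoms
  if (is.null(a$radius) || anyNA(a$radius))
    stop("assembly must be parameterized before packing")
  rt <- residue_table(assembly)
  if (is.null(mobile)) {
    keep <- vapply(rt$resname, function(r) n_chi(r) > 0, TRUE)
    mobile <- rt[keep, c("chain", "resno"), drop = FALSE]
  }
  nres <- nrow(mobile)
  if (nres == 0) stop("no mobile residues")
  keys <- res_key(mobile$chain, mobile$resno)
  rotamers <- lapply(seq_len(nres), function(i)
    residue_rotamer_set(assembly, mobile$chain[i], mobile$resno[i]))
  # fixed context: everything except mobile sidechains beyond CB
  side_of <- function(i) {
    rn <- rt$resname[rt$chain == mobile$chain[i] & rt$resno == mobile$resno[i]]
    vapply(.SIDECHAIN_TOPO[[rn]], function(r) r$atom, "")
  }
  mob_side <- rep(FALSE, nrow(a))
  for (i in seq_len(nres))
    mob_side <- mob_side | (a$chain == mobile$chain[i] &
                            a$resno == mobile$resno[i] & a$name %in% side_of(i))
  own_res <- lapply(seq_len(nres), function(i)
    a$chain == mobile$chain[i] & a$resno == mobile$resno[i])
  fixed_sets <- lapply(seq_len(nres), function(i) {
    sel <- !mob_side & !own_res[[i]]
    list(xyz = as.matrix(a[sel, c("x", "y", "z")]), rad = a$radius[sel])
  })
  tol <- config$clash_tolerance; K <- config$clash_k
  Tmf <- config$temperature_like_factor
  e_self <- lapply(seq_len(nres), function(i)
    vapply(rotamers[[i]], function(r)
      clash_energy(r, fixed_sets[[i]]$xyz, fixed_sets[[i]]$rad, tol, K), 0))
  e_pair <- list()
  for (i in seq_len(nres)) {
    e_pair[[i]] <- list()
    for (j in seq_len(nres)) {
      if (j <= i) next
      m <- matrix(0, length(rotamers[[i]]), length(rotamers[[j]]))
      for (ri in seq_along(rotamers[[i]]))
        for (rj in seq_along(rotamers[[j]])) {
          rj_df <- rotamers[[j]][[rj]]
          m[ri, rj] <- clash_energy(rotamers[[i]][[ri]],
                                    as.matrix(rj_df[, c("x", "y", "z")]),
                                    rj_df$radius, tol, K)
        }
      e_pair[[i]][[j]] <- m
    }
  }
  probs <- lapply(e_self, function(e) rep(1 / length(e), length(e)))
  free_energy <- function() {
    f <- 0
    for (i in seq_len(nres)) {
      p <- probs[[i]]
      f <- f + sum(p * e_self[[i]]) + Tmf * sum(p[p > 0] * log(p[p > 0]))
      for (j in seq_len(nres)) if (j > i)
        f <- f + as.numeric(t(probs[[i]]) %*% e_pair[[i]][[j]] %*% probs[[j]])
    }
    f
  }
  trace <- free_energy()
  iter_converged <- FALSE
  it <- 0
  lambda <- 0.6
  for (it in seq_len(config$max_iterations)) {
    maxdiff <- 0
    for (i in seq_len(nres)) {
      e <- e_self[[i]]
      for (j in seq_len(nres)) {
        if (j == i) next
        m <- if (j > i) e_pair[[i]][[j]] else t(e_pair[[j]][[i]])
        e <- e + as.numeric(m %*% probs[[j]])
      }
      w <- exp(-(e - min(e)) / Tmf)
      pnew <- unname((1 - lambda) * probs[[i]] + lambda * w / sum(w))
      maxdiff <- max(maxdiff, max(abs(pnew - probs[[i]])))
      probs[[i]] <- pnew
    }
    trace <- c(trace, free_energy())
    if (maxdiff < config$convergence_tol) { iter_converged <- TRUE; break }
  }
  selected <- vapply(probs, function(p) which(p == max(p))[1], 0L)
  # apply selected rotamers
  out <- assembly
  for (i in seq_len(nres)) {
    rot <- rotamers[[i]][[selected[i]]]
    sel <- out$atoms$chain == mobile$chain[i] & out$atoms$resno == mobile$resno[i]
    for (r in seq_len(nrow(rot))) {
      asel <- sel & out$atoms$name == rot$name[r]
      if (any(asel)) {
        out$atoms$x[asel] <- rot$x[r]
        out$atoms$y[asel] <- rot$y[r]
        out$atoms$z[asel] <- rot$z[r]
      }
    }
  }
  # hard-clash check of the selected configuration
  clash_free <- TRUE
  for (i in seq_len(nres)) {
    rot <- rotamers[[i]][[selected[i]]]
    if (worst_overlap(rot, fixed_sets[[i]]$xyz, fixed_sets[[i]]$rad) > tol) {
      clash_free <- FALSE; break
    }
    for (j in seq_len(nres)) {
      if (j <= i) next
      rj <- rotamers[[j]][[selected[j]]]
      if (worst_overlap(rot, as.matrix(rj[, c("x", "y", "z")]), rj$radius) > tol) {
        clash_free <- FALSE; break
      }
    }
    if (!clash_free) break
  }
  converged <- iter_converged && clash_free
  if (!converged)
    warning("mean-field packing did not converge to a clash-free assignment")
  structure(list(probabilities = setNames(probs, keys),
                 selected = setNames(selected, keys),
                 converged = converged, iterations = it,
                 clash_free = clash_free,
                 free_energy = trace, assembly = out,
                 mobile = mobile), class = "fddh_packing_result")
}

# Reference SASA of a site's charge atoms: the rotamer-library maximum in
# the isolated model compound (cached per residue/atom-set).
model_compound_ref_sasa <- function(restype, charge_names) {
  key <- paste(restype, paste(charge_names, collapse = "+"))
  if (!is.null(.ff_cache$refsasa[[key]])) return(.ff_cache$refsasa[[key]])
  ref <- model_compound_assembly(restype)
  a <- ref$atoms
  side_names <- vapply(.SIDECHAIN_TOPO[[restype]], function(r) r$atom, "")
  best <- 0
  if (length(side_names) > 0 && any(charge_names %in% side_names)) {
    rots <- residue_rotamer_set(ref, "A", 1)
    bb <- a[!(a$name %in% side_names), , drop = FALSE]
    for (rot in rots) {
      xyz <- rbind(as.matrix(bb[, c("x", "y", "z")]),
                   as.matrix(rot[, c("x", "y", "z")]))
      rad <- c(bb$radius, rot$radius)
      tgt <- nrow(bb) + which(rot$name %in% charge_names)
      best <- max(best, sum(sasa_cpp(xyz, rad, 1.4, 960L, as.integer(tgt))))
    }
  } else {
    idx <- which(a$name %in% charge_names)
    best <- sum(sasa(ref, subset = idx))
  }
  if (is.null(.ff_cache$refsasa)) .ff_cache$refsasa <- list()
  .ff_cache$refsasa[[key]] <- best
  best
}

#' Maximal attainable solvent accessibility of a titratable site
#'
#' Over the site's allowed rotamers (worst hard-sphere overlap with the fixed
#' surroundings at most the clash tolerance), the maximum SASA of the
#' charge-bearing atoms, absolute and relative to the same atoms in an
#' isolated model compound (rotamer-library maximum).  A site that can reach
#' the configured relative accessibility is eligible for Debye-Huckel
#' treatment.  If no rotamer is allowed the site is flagged buried: the
#' least-clashing rotamers are reported descriptively (which keeps the
#' attainable SASA non-decreasing in the tolerance) and the site is never
#' DH-eligible.
#'
#' @param assembly parameterized `fddh_assembly`
#' @param site one row of [enumerate_titratable_sites()]
#' @param config a [packing_config()]
#' @return data.frame row: site id, max_attainable_sasa, relative
#'   accessibility, dh_eligible, buried
#' @export
max_attainable_accessibility <- function(assembly, site,
                                         config = packing_config()) {
  a <- assembly$atoms
  charge_names <- strsplit(site$charge_atoms, ",")[[1]]
  own <- a$chain == site$chain & a$resno == site$resno
  resname <- a$resname[own][1]
  ref_sasa <- model_compound_ref_sasa(
    if (site$restype %in% c("NTER", "CTER")) resname else site$restype,
    charge_names)
  side_names <- vapply(.SIDECHAIN_TOPO[[resname]], function(r) r$atom, "")
  backbone_like <- !(a$name %in% side_names) | !own
  if (site$restype %in% c("NTER", "CTER") || length(side_names) == 0 ||
      !any(charge_names %in% side_names)) {
    # charge atoms are backbone: no rotamer freedom
    idx <- which(own & a$name %in% charge_names)
    s <- sum(sasa(assembly, subset = idx))
    rel <- s / ref_sasa
    return(data.frame(chain = site$chain, resno = site$resno,
                      restype = site$restype, max_attainable_sasa = s,
                      relative_accessibility = rel,
                      dh_eligible = rel >= config$dh_threshold, buried = FALSE,
                      stringsAsFactors = FALSE))
  }
  rots <- residue_rotamer_set(assembly, site$chain, site$resno)
  ctx_sel <- !own
  ctx_xyz <- as.matrix(a[ctx_sel, c("x", "y", "z")])
  ctx_rad <- a$radius[ctx_sel]
  ov <- vapply(rots, function(r) worst_overlap(r, ctx_xyz, ctx_rad), 0)
  allowed <- ov <= config$clash_tolerance
  use <- if (any(allowed)) which(allowed) else which(ov <= min(ov) + 1e-9)
  own_bb <- a[own & !(a$name %in% side_names), , drop = FALSE]
  best <- 0
  for (ri in use) {
    rot <- rots[[ri]]
    xyz <- rbind(ctx_xyz, as.matrix(own_bb[, c("x", "y", "z")]),
                 as.matrix(rot[, c("x", "y", "z")]))
    rad <- c(ctx_rad, own_bb$radius, rot$radius)
    tgt <- nrow(ctx_xyz) + nrow(own_bb) + which(rot$name %in% charge_names)
    s <- sum(sasa_cpp(xyz, rad, 1.4, 960L, as.integer(tgt)))
    if (s > best) best <- s
  }
  rel <- best / ref_sasa
  buried <- !any(allowed)
  data.frame(chain = site$chain, resno = site$resno, restype = site$restype,
             max_attainable_sasa = best, relative_accessibility = rel,
             dh_eligible = !buried && rel >= config$dh_threshold,
             buried = buried, stringsAsFactors = FALSE)
}

#' Accessibility scan over clash tolerances
#'
#' Runs [max_attainable_accessibility()] for every site at every tolerance.
#' Attainable SASA is non-decreasing in the tolerance: loosening the clash
#' criterion can only admit more rotamers.
#'
#' @param assembly parameterized `fddh_assembly`
#' @param sites from [enumerate_titratable_sites()]
#' @param tolerances vector of clash tolerances, Angstrom
#' @param config base [packing_config()]
#' @return data.frame with one row per site per tolerance
#' @export
accessibility_scan <- function(assembly, sites, tolerances,
                               config = packing_config()) {
  stopifnot(length(tolerances) > 0)
  out <- list()
  for (tol in tolerances) {
    cfg <- config; cfg$clash_tolerance <- tol
    for (i in seq_len(nrow(sites))) {
      r <- max_attainable_accessibility(assembly, sites[i, ], cfg)
      r$clash_tolerance <- tol
      out[[length(out) + 1]] <- r
    }
  }
  if (length(out) == 0)
    return(data.frame(chain = character(0), resno = integer(0),
                      restype = character(0), max_attainable_sasa = numeric(0),
                      relative_accessibility = numeric(0),
                      dh_eligible = logical(0), buried = logical(0),
                      clash_tolerance = numeric(0)))
  do.call(rbind, out)
}
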