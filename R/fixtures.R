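# Synthetic PDB-format structures with planted ground truth: isolated model
# compounds, buried-charge cage toys, two-conformer salt-bridge and
# buried-acid toys, a symmetric homotrimer and a Born sphere.  All tests run
# from these generators; no downloads.

#' Build a peptide assembly from sequence
#'
#' Idealized backbone (default extended) with sidechains placed at given chi
#' angles (default the canonical extended rotamer).
#'
#' @param seq3 character vector of three-letter residue codes
#' @param chain chain id
#' @param label assembly label
#' @param resno_start first author residue number
#' @param phi,psi backbone torsions, degrees
#' @param chis optional named list: chis[["resno"]] = chi vector override
#' @return an `fddh_assembly`
#' @export
peptide_assembly <- function(seq3, chain = "A", label = "peptide",
                             resno_start = 1, phi = -180, psi = 180,
                             chis = list()) {
  bb <- build_backbone(seq3, phi = phi, psi = psi)
  rows <- list()
  for (i in seq_along(seq3)) {
    res <- bb[bb$resno == i, , drop = FALSE]
    for (r in seq_len(nrow(res))) rows[[length(rows) + 1]] <- res[r, ]
    restype <- seq3[i]
    topo <- .SIDECHAIN_TOPO[[restype]]
    if (!is.null(topo) && length(topo) > 0) {
      get1 <- function(nm) unlist(res[res$atom == nm, c("x", "y", "z")])
      ch <- chis[[as.character(i)]]
      if (is.null(ch)) ch <- extended_chis(restype)
      sc <- build_sidechain_coords(restype, get1("N"), get1("CA"),
                                   get1("CB"), ch)
      for (nm in names(sc))
        rows[[length(rows) + 1]] <-
          data.frame(resno = i, resname = restype, atom = nm,
                     x = sc[[nm]][1], y = sc[[nm]][2], z = sc[[nm]][3],
                     stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  atoms <- data.frame(serial = seq_len(nrow(df)), name = df$atom,
                      resname = df$resname, chain = chain,
                      resno = df$resno + resno_start - 1L, icode = "",
                      x = df$x, y = df$y, z = df$z, occ = 1,
                      element = substr(df$atom, 1, 1), stringsAsFactors = FALSE)
  new_assembly(atoms, label = label)
}

#' Isolated extended model compound for a residue type
#'
#' Single blocked residue (backbone plus sidechain in the canonical extended
#' rotamer), parameterized; the SASA reference state for relative
#' accessibility.
#'
#' @param restype three-letter code
#' @return parameterized `fddh_assembly`
#' @export
model_compound_assembly <- function(restype) {
  parameterize(peptide_assembly(restype, label = paste0("model-", restype)))
}

# rigid-body helpers ---------------------------------------------------------

rotation_from_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees: rotate about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * p[3] - a[3] * p[2], a[3] * p[1] - a[1] * p[3],
           a[1] * p[2] - a[2] * p[1])
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Rigid-transform (part of) an assembly
#' @param assembly an `fddh_assembly`
#' @param R 3x3 rotation (applied first)
#' @param t translation 3-vector
#' @param chains chains to move (default all)
#' @return transformed assembly
#' @export
transform_assembly <- function(assembly, R = diag(3), t = c(0, 0, 0),
                               chains = NULL) {
  sel <- if (is.null(chains)) rep(TRUE, nrow(assembly$atoms))
         else assembly$atoms$chain %in% chains
  xyz <- as.matrix(assembly$atoms[sel, c("x", "y", "z")])
  xyz <- xyz %*% t(R)
  assembly$atoms$x[sel] <- xyz[, 1] + t[1]
  assembly$atoms$y[sel] <- xyz[, 2] + t[2]
  assembly$atoms$z[sel] <- xyz[, 3] + t[3]
  assembly
}

merge_assemblies <- function(..., label = "merged") {
  parts <- list(...)
  common <- Reduce(intersect, lapply(parts, function(p) names(p$atoms)))
  atoms <- do.call(rbind, lapply(parts, function(p)
    p$atoms[, common, drop = FALSE]))
  atoms$serial <- seq_len(nrow(atoms))
  new_assembly(atoms, label = label,
               neutralized = unique(unlist(lapply(parts, `[[`, "neutralized"))))
}

# quasi-uniform sphere shell of single-atom CAG pseudo-residues
cage_shell <- function(center, radius = 4.5, n = 160, chain = "X",
                       resno_start = 1, jitter = 0) {
  ga <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- ga * i
  xyz <- cbind(center[1] + radius * r * cos(th),
               center[2] + radius * r * sin(th),
               center[3] + radius * z)
  if (jitter > 0) xyz <- xyz + matrix(runif(3 * n, -jitter, jitter), n, 3)
  atoms <- data.frame(serial = seq_len(n), name = "C", resname = "CAG",
                      chain = chain, resno = seq_len(n) + resno_start - 1L,
                      icode = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = 1, element = "C", stringsAsFactors = FALSE)
  new_assembly(atoms, label = "cage")
}

res_atom_xyz <- function(assembly, chain, resno, name) {
  a <- assembly$atoms
  sel <- a$chain == chain & a$resno == resno & a$name == name
  unlist(a[sel, c("x", "y", "z")])
}

# choose the library rotamer with max (escape) or min (compact) distance of
# the terminal atom from CA
pick_rotamer <- function(restype, N, CA, CB, terminal, what = c("escape", "compact")) {
  what <- match.arg(what)
  chis <- rotamer_chis(restype)
  d <- apply(chis, 1, function(ch) {
    sc <- build_sidechain_coords(restype, N, CA, CB, ch)
    mx <- sc[[terminal]]
    sqrt(sum((mx - CA)^2))
  })
  r <- if (what == "escape") which.max(d) else which.min(d)
  chis[r, ]
}

set_residue_chis <- function(assembly, chain, resno, chis_vec) {
  a <- assembly$atoms
  sel <- a$chain == chain & a$resno == resno
  restype <- a$resname[sel][1]
  N <- res_atom_xyz(assembly, chain, resno, "N")
  CA <- res_atom_xyz(assembly, chain, resno, "CA")
  CB <- res_atom_xyz(assembly, chain, resno, "CB")
  sc <- build_sidechain_coords(restype, N, CA, CB, chis_vec)
  for (nm in names(sc)) {
    asel <- sel & a$name == nm
    assembly$atoms$x[asel] <- sc[[nm]][1]
    assembly$atoms$y[asel] <- sc[[nm]][2]
    assembly$atoms$z[asel] <- sc[[nm]][3]
    a <- assembly$atoms
  }
  assembly
}

#' Buried-charge cage toy
#'
#' A Gly-Lys-Gly peptide whose lysine sits inside a spherical cage of
#' uncharged pseudo-atoms centred on its CA, with a solvent-exposed
#' aspartate control on a second chain.  Variants: `closed` (nested
#' shells: the amino group can never reach solvent), `open` (a wide porthole
#' is carved along the most extended rotamer: the group reaches solvent at
#' any clash tolerance) and `gated` (porthole plus a gate ring pinching the
#' escape rotamer at ~1.2 A overlap: the group escapes at 1.6 A tolerance
#' but not at 0.8 A - the repacking-scan sensor plant).
#'
#' @param variant cage openness
#' @param residue caged residue type (default LYS)
#' @param jitter uniform coordinate jitter applied to cage atoms (Angstrom)
#' @return an `fddh_assembly`
#' @export
fx_cage <- function(variant = c("closed", "open", "gated"), residue = "LYS",
                    jitter = 0) {
  variant <- match.arg(variant)
  pep <- peptide_assembly(c("GLY", residue, "GLY"),
                          label = paste0("cage-", variant))
  CA <- res_atom_xyz(pep, "A", 2, "CA")
  N <- res_atom_xyz(pep, "A", 2, "N")
  CB <- res_atom_xyz(pep, "A", 2, "CB")
  term <- strsplit(model_pka_table()$charge_atoms[
    model_pka_table()$restype == residue], ",")[[1]][1]
  ff <- default_forcefield()
  own <- pep$atoms$resno == 2
  ctx <- pep$atoms[!own, , drop = FALSE]
  ctx$radius <- ff$radius[match(paste(ctx$resname, ctx$name),
                                paste(ff$res, ff$atom))]
  side_rad <- function(nms) ff$radius[match(paste(residue, nms),
                                            paste(ff$res, ff$atom))]
  rot_ov_ctx <- function(sc) {
    rad <- side_rad(names(sc))
    mx <- -Inf
    for (i in seq_along(sc)) {
      d <- sqrt((ctx$x - sc[[i]][1])^2 + (ctx$y - sc[[i]][2])^2 +
                (ctx$z - sc[[i]][3])^2)
      mx <- max(mx, max(rad[i] + ctx$radius - d))
    }
    mx
  }
  # escape rotamer: longest reach among rotamers clean against the backbone
  chis <- rotamer_chis(residue)
  reach <- ov <- numeric(nrow(chis))
  for (r in seq_len(nrow(chis))) {
    sc <- build_sidechain_coords(residue, N, CA, CB, chis[r, ])
    reach[r] <- sqrt(sum((sc[[term]] - CA)^2))
    ov[r] <- rot_ov_ctx(sc)
  }
  cand <- which(ov <= 0.3)
  esc <- chis[cand[which.max(reach[cand])], ]
  cmp <- chis[which.min(reach), ]
  pep <- set_residue_chis(pep, "A", 2, cmp)  # native: tucked inside
  esc_sc <- build_sidechain_coords(residue, N, CA, CB, esc)
  esc_xyz <- do.call(rbind, esc_sc)
  esc_rad <- side_rad(rownames(esc_xyz))
  if (variant == "closed") {
    # nested solvent-tight shells: every rotamer position is occluded
    sh <- lapply(c(9.0, 7.5, 6.0), function(rr)
      cage_shell(CA, radius = rr, n = ceiling(4 * pi * rr^2 / 1.2^2),
                 chain = "X", jitter = jitter))
    cage <- sh[[1]]
    cage$atoms <- do.call(rbind, lapply(sh, `[[`, "atoms"))
    cage$atoms$resno <- seq_len(nrow(cage$atoms))
    ctrl <- transform_assembly(
      peptide_assembly(c("GLY", "ASP", "GLY"), chain = "B"), t = c(0, 25, 0))
    return(merge_assemblies(pep, ctrl, cage,
                            label = paste0("cage-", variant)))
  } else {
    # tight shell: all compact rotamers clash it at any tolerance; only the
    # carved porthole along the escape rotamer reaches solvent
    radius <- 4.5
  }
  n_shell <- ceiling(4 * pi * radius^2 / 1.2^2)
  cage <- cage_shell(CA, radius = radius, n = n_shell, chain = "X",
                     jitter = jitter)
  if (variant != "closed") {
    # carve the porthole: clearance 1.0 A around the escape rotamer
    keep <- rep(TRUE, nrow(cage$atoms))
    for (i in seq_len(nrow(esc_xyz))) {
      d <- sqrt((cage$atoms$x - esc_xyz[i, 1])^2 +
                (cage$atoms$y - esc_xyz[i, 2])^2 +
                (cage$atoms$z - esc_xyz[i, 3])^2)
      keep <- keep & (esc_rad[i] + 1.9 - d <= -1.0 + 1e-9)
    }
    cage$atoms <- cage$atoms[keep, , drop = FALSE]
  }
  if (variant == "gated") {
    # gate ring pinching the escape path mid-chain at ~1.2 A overlap, so the
    # rotamer is admitted at 1.6 A clash tolerance but rejected at 0.8 A
    axis <- esc_sc[[term]] - CA
    axis <- axis / sqrt(sum(axis^2))
    anchor <- if ("CD" %in% names(esc_sc)) esc_sc[["CD"]] else
      esc_sc[[max(1, length(esc_sc) - 1)]]
    p1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- p1 - sum(p1 * axis) * axis
    u <- u / sqrt(sum(u^2))
    v <- c(axis[2] * u[3] - axis[3] * u[2], axis[3] * u[1] - axis[1] * u[3],
           axis[1] * u[2] - axis[2] * u[1])
    ring_r <- 1.9 + 1.9 - 1.2   # target overlap 1.2 with the CD carbon
    gate <- list()
    for (k in 0:7) {
      ang <- (k + 0.5) * pi / 4
      g <- anchor + ring_r * (cos(ang) * u + sin(ang) * v)
      mx <- max(vapply(seq_along(esc_sc), function(i)
        esc_rad[i] + 1.9 - sqrt(sum((g - esc_sc[[i]])^2)), 0))
      if (mx > 0.9 && mx <= 1.45 && length(gate) < 4)
        gate[[length(gate) + 1]] <- g
    }
    if (length(gate) > 0) {
      gx <- do.call(rbind, gate)
      gdf <- data.frame(serial = seq_len(nrow(gx)), name = "C",
                        resname = "CAG", chain = "X",
                        resno = max(cage$atoms$resno) + seq_len(nrow(gx)),
                        icode = "", x = gx[, 1], y = gx[, 2], z = gx[, 3],
                        occ = 1, element = "C", stringsAsFactors = FALSE)
      cage$atoms <- rbind(cage$atoms, gdf)
    }
  }
  # solvent-exposed aspartate control on a second chain
  ctrl <- transform_assembly(
    peptide_assembly(c("GLY", "ASP", "GLY"), chain = "B"), t = c(0, 25, 0))
  merge_assemblies(pep, ctrl, cage, label = paste0("cage-", variant))
}

#' Two-conformer salt-bridge toy
#'
#' A Gly-Asp-Gly chain and a Gly-Lys-Gly chain arranged so the carboxylate
#' and amino groups form a salt bridge in the closed conformer and are
#' separated in the open conformer.  Both partners stay solvent-exposed
#' (DH-treated) and their pKas stay outside the physiological window, so
#' deleting the acid is pH-coupled, not pH-sensing.
#'
#' @param conformer "closed" (bridge made) or "open" (bridge broken)
#' @param bridge_distance N-O distance in the closed form, Angstrom
#' @param open_shift extra separation in the open form, Angstrom
#' @return an `fddh_assembly`
#' @export
fx_salt_bridge <- function(conformer = c("closed", "open"),
                           bridge_distance = 2.8, open_shift = 8) {
  conformer <- match.arg(conformer)
  a <- peptide_assembly(c("GLY", "ASP", "GLY"), chain = "A",
                        label = "salt-bridge")
  b <- peptide_assembly(c("GLY", "LYS", "GLY"), chain = "B")
  od <- res_atom_xyz(a, "A", 2, "OD1")
  ca_d <- res_atom_xyz(a, "A", 2, "CA")
  u <- od - ca_d; u <- u / sqrt(sum(u^2))
  nz <- res_atom_xyz(b, "B", 2, "NZ")
  ca_k <- res_atom_xyz(b, "B", 2, "CA")
  w <- nz - ca_k; w <- w / sqrt(sum(w^2))
  R <- rotation_from_to(w, -u)
  b <- transform_assembly(b, R = R)
  nz2 <- res_atom_xyz(b, "B", 2, "NZ")
  shift <- (od + (bridge_distance) * u) - nz2
  b <- transform_assembly(b, t = shift)
  if (conformer == "open")
    b <- transform_assembly(b, t = open_shift * u)
  out <- merge_assemblies(a, b, label = paste0("salt-bridge-", conformer))
  out
}

#' Two-conformer buried-acid sensor toy
#'
#' A Gly-Asp-Gly chain whose aspartate is enclosed in a pseudo-atom cage in
#' the closed conformer (large desolvation, pKa pushed far above its model
#' value) while the open conformer moves the cage away, leaving the acid
#' exposed (DH, model pKa).  The acid's ionization therefore differs between
#' conformers at physiological pH: deleting it changes the slope of the
#' open-minus-closed energy curve (a pH-sensor plant).  A solvent-exposed
#' lysine on a second chain is a negative control.
#'
#' @param conformer "closed" or "open"
#' @return an `fddh_assembly`
#' @export
fx_buried_acid <- function(conformer = c("closed", "open")) {
  conformer <- match.arg(conformer)
  a <- peptide_assembly(c("GLY", "ASP", "GLY"), chain = "A",
                        label = "buried-acid")
  k <- peptide_assembly(c("GLY", "LYS", "GLY"), chain = "B")
  k <- transform_assembly(k, t = c(0, 24, 0))
  cage <- cage_shell(res_atom_xyz(a, "A", 2, "CA"), radius = 4.5, chain = "X")
  if (conformer == "open")
    cage <- transform_assembly(cage, t = c(30, 0, 0))
  merge_assemblies(a, k, cage, label = paste0("buried-acid-", conformer))
}

#' Two-conformer calcium-mimic toy
#'
#' Two aspartates (separate chains) are caged (buried) in the closed
#' conformer and exposed in the open one, while a glutamate on a third chain
#' is exposed in the closed form and caged in the open form.  The wild-type
#' open-minus-closed energy slope over the physiological window is negative
#' (dominated by the acid pair); charge-deleting the pair (the
#' calcium-binding mimic) flips the slope sign.
#'
#' @param conformer "closed" or "open"
#' @return an `fddh_assembly`
#' @export
fx_calcium_toy <- function(conformer = c("closed", "open")) {
  conformer <- match.arg(conformer)
  d1 <- peptide_assembly(c("GLY", "ASP", "GLY"), chain = "A",
                         label = "calcium-toy")
  d2 <- peptide_assembly(c("GLY", "ASP", "GLY"), chain = "B")
  d2 <- transform_assembly(d2, t = c(0, 22, 0))
  e3 <- peptide_assembly(c("GLY", "GLU", "GLY"), chain = "C")
  e3 <- transform_assembly(e3, t = c(0, 44, 0))
  far <- c(30, 0, 0)
  c1 <- cage_shell(res_atom_xyz(d1, "A", 2, "CA"), chain = "X")
  c2 <- cage_shell(res_atom_xyz(d2, "B", 2, "CA"), chain = "Y")
  c3 <- cage_shell(res_atom_xyz(e3, "C", 2, "CA"), chain = "Z")
  if (conformer == "closed") {
    c3 <- transform_assembly(c3, t = far)
  } else {
    c1 <- transform_assembly(c1, t = far)
    c2 <- transform_assembly(c2, t = far)
  }
  merge_assemblies(d1, d2, e3, c1, c2, c3,
                   label = paste0("calcium-toy-", conformer))
}

#' C3-symmetric homotrimer fixture
#'
#' Three identical Gly-Asp-Lys-Gly monomers (chains A, B, C) related by
#' exact 120-degree rotations about z.  Per-monomer pK-half values must
#' agree and monomer averaging must be idempotent.
#'
#' @param radius distance of each monomer from the symmetry axis, Angstrom
#' @return an `fddh_assembly`
#' @export
fx_trimer <- function(radius = 10) {
  mono <- peptide_assembly(c("GLY", "ASP", "LYS", "GLY"), chain = "A",
                           label = "trimer")
  mono <- transform_assembly(mono, t = c(radius, 0, 0))
  rot_z <- function(deg) {
    th <- deg * pi / 180
    matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  }
  b <- transform_assembly(mono, R = rot_z(120)); b$atoms$chain <- "B"
  c_ <- transform_assembly(mono, R = rot_z(240)); c_$atoms$chain <- "C"
  merge_assemblies(mono, b, c_, label = "trimer")
}

#' Born sphere pseudo-structure
#'
#' A single uncharged pseudo-atom of radius 2.0 A at the origin: placing a
#' unit charge at its centre gives the analytic Born desolvation test case.
#'
#' @return parameterized `fddh_assembly`
#' @export
fx_born_sphere <- function() {
  atoms <- data.frame(serial = 1L, name = "X", resname = "SPH", chain = "A",
                      resno = 1L, icode = "", x = 0, y = 0, z = 0, occ = 1,
                      element = "X", stringsAsFactors = FALSE)
  parameterize(new_assembly(atoms, label = "born-sphere"),
               check_complete = FALSE)
}

#' Write the synthetic fixture set
#'
#' Deterministic (seeded) PDB fixtures plus a JSON manifest recording the
#' planted ground truth of each toy.
#'
#' @param out_dir output directory (created if needed)
#' @param seed RNG seed (drives only the cosmetic cage-atom jitter)
#' @return invisibly, the manifest as a list
#' @export
generate_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  put <- function(asm, name) write_pdb(asm, file.path(out_dir, name))
  for (rt in c("ASP", "GLU", "LYS", "ARG", "HIS"))
    put(peptide_assembly(rt, label = paste0("model-", rt)),
        paste0("model_", rt, ".pdb"))
  put(fx_cage("closed"), "cage_closed.pdb")
  put(fx_cage("open"), "cage_open.pdb")
  put(fx_cage("gated"), "cage_gated.pdb")
  put(fx_salt_bridge("closed"), "salt_bridge_closed.pdb")
  put(fx_salt_bridge("open"), "salt_bridge_open.pdb")
  put(fx_buried_acid("closed"), "buried_acid_closed.pdb")
  put(fx_buried_acid("open"), "buried_acid_open.pdb")
  put(fx_calcium_toy("closed"), "calcium_closed.pdb")
  put(fx_calcium_toy("open"), "calcium_open.pdb")
  put(fx_trimer(), "trimer.pdb")
  put(fx_born_sphere(), "born_sphere.pdb")
  manifest <- list(
    seed = seed,
    fixtures = list(
      cage_gated = list(files = "cage_gated.pdb",
                        planted = "A:2 LYS flips DH-eligibility between clash tolerances 0.8 and 1.6 A; only flagged site in the repacking scan at pH 6.5"),
      salt_bridge = list(files = c("salt_bridge_closed.pdb", "salt_bridge_open.pdb"),
                         planted = "deleting A:2 ASP is pH-coupled: offset, no slope change over pH 6-8"),
      buried_acid = list(files = c("buried_acid_closed.pdb", "buried_acid_open.pdb"),
                         planted = "deleting A:2 ASP is pH-sensing: slope change over pH 6-8; B:2 LYS is a negative control",
                         sensor_site = "A:2 ASP"),
      calcium_toy = list(files = c("calcium_closed.pdb", "calcium_open.pdb"),
                         planted = "charge-deleting A:2 and B:2 ASP in the closed form flips the window slope sign from negative to positive"),
      trimer = list(files = "trimer.pdb",
                    planted = "3 identical chains; per-monomer pK-half values equal"),
      born_sphere = list(files = "born_sphere.pdb",
                         planted = "unit charge at centre: analytic Born desolvation (332.06/2)*(1/4-1/78.4)/2.0 = 19.69 kcal/mol")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
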