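# Assembly container and structure operations: PDB I/O, parameterization,
# conformer trimming, sequence threading, mutations, titratable-site
# enumeration.

new_assembly <- function(atoms, label = "structure", neutralized = character()) {
  atoms$chain[is.na(atoms$chain) | atoms$chain == ""] <- "A"
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label, neutralized = neutralized),
            class = "fddh_assembly")
}

#' @export
print.fddh_assembly <- function(x, ...) {
  cat(sprintf("fddh assembly '%s': %d atoms, %d residues, chains %s\n",
              x$label, nrow(x$atoms), nrow(residue_table(x)),
              paste(assembly_chains(x), collapse = ",")))
  invisible(x)
}

#' Chain identifiers of an assembly in file order
#' @param assembly an `fddh_assembly`
#' @return character vector
#' @export
assembly_chains <- function(assembly) unique(assembly$atoms$chain)

res_key <- function(chain, resno) paste0(chain, ":", resno)

#' Residue table of an assembly
#' @param assembly an `fddh_assembly`
#' @return data.frame with chain, resno, resname in atom order
#' @export
residue_table <- function(assembly) {
  a <- assembly$atoms
  k <- res_key(a$chain, a$resno)
  keep <- !duplicated(k)
  data.frame(chain = a$chain[keep], resno = a$resno[keep],
             resname = a$resname[keep], stringsAsFactors = FALSE)
}

#' Read a PDB file into an assembly
#'
#' Parses ATOM records (via bio3d), resolving alternate locations to the
#' highest-occupancy copy and dropping waters/hetero groups with a message.
#' Author residue numbering is preserved verbatim.
#'
#' @param path PDB file
#' @param label conformer label (e.g. "closed", "open"); defaults to filename
#' @return an `fddh_assembly`
#' @export
read_pdb <- function(path, label = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- pdb$atom
  n_het <- sum(at$type != "ATOM" | at$resid %in% c("HOH", "WAT"))
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  if (n_het > 0)
    message("read_pdb: dropped ", n_het, " hetero/water atom records")
  # alternate locations: highest occupancy wins (first on ties)
  at$alt[is.na(at$alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- at$o; occ[is.na(occ)] <- 1
  ord <- order(match(key, unique(key)), -occ)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety, sep = "|")), ,
           drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "|"),
                       unique(paste(at$chain, at$resno, at$insert, sep = "|")))), ,
           drop = FALSE]
  ins <- at$insert; ins[is.na(ins)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  atoms <- data.frame(serial = at$eleno, name = at$elety, resname = at$resid,
                      chain = at$chain, resno = at$resno, icode = ins,
                      x = at$x, y = at$y, z = at$z, occ = occ,
                      element = substr(at$elety, 1, 1),
                      stringsAsFactors = FALSE)
  if (is.null(label)) label <- sub("\\.pdb$", "", basename(path))
  new_assembly(atoms, label = label)
}

#' Write an assembly to a PDB file
#'
#' @param assembly an `fddh_assembly`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb <- function(assembly, path) {
  a <- assembly$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
                   elety = a$name, chain = a$chain,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   o = a$occ, b = rep(0, nrow(a)))
  invisible(path)
}

#' Assign united-atom radii and partial charges
#'
#' Joins every atom against the parameter table; unknown atoms are an error
#' naming the offender.  With `check_complete = TRUE` (default) residues
#' missing heavy atoms relative to the sidechain topology are also an error;
#' use [repair_sidechains()] first to rebuild them.
#'
#' @param assembly an `fddh_assembly`
#' @param forcefield parameter table from [default_forcefield()]
#' @param check_complete error on missing sidechain atoms
#' @return assembly with `radius` and `charge` columns filled
#' @export
parameterize <- function(assembly, forcefield = default_forcefield(),
                         check_complete = TRUE) {
  a <- assembly$atoms
  key <- paste(a$resname, a$name)
  fkey <- paste(forcefield$res, forcefield$atom)
  idx <- match(key, fkey)
  any_idx <- match(paste("ANY", a$name), fkey)
  idx[is.na(idx)] <- any_idx[is.na(idx)]
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("parameterization error: unknown atom %s/%s %s:%d",
                 a$resname[bad], a$name[bad], a$chain[bad], a$resno[bad]))
  }
  a$radius <- forcefield$radius[idx]
  a$charge <- forcefield$charge[idx]
  if (check_complete) {
    miss <- missing_sidechain_atoms(assembly)
    if (nrow(miss) > 0)
      stop("missing sidechain atoms: ",
           paste(sprintf("%s:%d %s", miss$chain, miss$resno, miss$atom),
                 collapse = ", "))
  }
  assembly$atoms <- a
  assembly
}

# Expected heavy atoms per residue (backbone + topology sidechain).
expected_atoms <- function(resname) {
  if (resname %in% c("CAG", "SPH")) return(character(0))
  side <- vapply(.SIDECHAIN_TOPO[[resname]], function(r) r$atom, "")
  bb <- c("N", "CA", "C", "O")
  if (resname != "GLY") bb <- c(bb, "CB")
  c(bb, side)
}

missing_sidechain_atoms <- function(assembly) {
  rt <- residue_table(assembly)
  out <- list()
  a <- assembly$atoms
  for (i in seq_len(nrow(rt))) {
    if (!rt$resname[i] %in% names(.SIDECHAIN_TOPO)) next
    have <- a$name[a$chain == rt$chain[i] & a$resno == rt$resno[i]]
    miss <- setdiff(expected_atoms(rt$resname[i]), c(have, "OXT"))
    if (length(miss) > 0)
      out[[length(out) + 1]] <- data.frame(chain = rt$chain[i],
                                           resno = rt$resno[i], atom = miss,
                                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    data.frame(chain = character(0), resno = integer(0), atom = character(0))
  else do.call(rbind, out)
}

#' Rebuild missing sidechain atoms in the extended rotamer
#'
#' Residues missing heavy atoms beyond CB are completed from the sidechain
#' topology in the canonical extended conformation (they remain candidates
#' for repacking).  Residues missing backbone atoms are left untouched.
#'
#' @param assembly an `fddh_assembly`
#' @return repaired assembly
#' @export
repair_sidechains <- function(assembly) {
  miss <- missing_sidechain_atoms(assembly)
  if (nrow(miss) == 0) return(assembly)
  for (k in unique(res_key(miss$chain, miss$resno))) {
    sel <- res_key(assembly$atoms$chain, assembly$atoms$resno) == k
    res <- assembly$atoms[sel, , drop = FALSE]
    resname <- res$resname[1]
    get1 <- function(nm) unlist(res[res$name == nm, c("x", "y", "z")])
    if (!all(c("N", "CA", "C") %in% res$name)) next
    N <- get1("N"); CA <- get1("CA"); C <- get1("C")
    CB <- if ("CB" %in% res$name) get1("CB") else ideal_cb(N, CA, C)
    coords <- build_sidechain_coords(resname, N, CA, CB, extended_chis(resname))
    coords <- c(list(CB = CB), coords)
    need <- setdiff(expected_atoms(resname), c(res$name, "OXT"))
    for (nm in need) {
      p <- coords[[nm]]
      if (is.null(p)) next
      newrow <- res[1, , drop = FALSE]
      newrow$name <- nm
      newrow$x <- p[1]; newrow$y <- p[2]; newrow$z <- p[3]
      newrow$element <- substr(nm, 1, 1)
      if ("radius" %in% names(newrow)) { newrow$radius <- NA; newrow$charge <- NA }
      last <- max(which(sel))
      assembly$atoms <- rbind(assembly$atoms[seq_len(last), , drop = FALSE],
                              newrow,
                              if (last < nrow(assembly$atoms))
                                assembly$atoms[(last + 1):nrow(assembly$atoms), ,
                                               drop = FALSE])
      sel <- res_key(assembly$atoms$chain, assembly$atoms$resno) == k
      res <- assembly$atoms[sel, , drop = FALSE]
    }
  }
  rownames(assembly$atoms) <- NULL
  assembly
}

#' Trim two conformers to their common residue range
#'
#' Keeps, per corresponding chain, exactly the author residue numbers
#' structurally present in both inputs, so that differential (open vs closed)
#' analyses compare identical sequences.
#'
#' @param a,b assemblies of the same protein (same chain count, chains paired
#'   in order)
#' @return list of the two trimmed assemblies with a residue-correspondence
#'   attribute
#' @export
trim_to_common_length <- function(a, b) {
  ca <- assembly_chains(a); cb <- assembly_chains(b)
  if (length(ca) != length(cb))
    stop("conformers have different chain counts")
  keep_a <- rep(FALSE, nrow(a$atoms)); keep_b <- rep(FALSE, nrow(b$atoms))
  corr <- list()
  for (i in seq_along(ca)) {
    ra <- unique(a$atoms$resno[a$atoms$chain == ca[i]])
    rb <- unique(b$atoms$resno[b$atoms$chain == cb[i]])
    common <- intersect(ra, rb)
    if (length(common) == 0)
      stop("no common residues between chains ", ca[i], " and ", cb[i])
    keep_a <- keep_a | (a$atoms$chain == ca[i] & a$atoms$resno %in% common)
    keep_b <- keep_b | (b$atoms$chain == cb[i] & b$atoms$resno %in% common)
    corr[[i]] <- data.frame(chain_a = ca[i], chain_b = cb[i], resno = common)
  }
  ta <- new_assembly(a$atoms[keep_a, , drop = FALSE], a$label, a$neutralized)
  tb <- new_assembly(b$atoms[keep_b, , drop = FALSE], b$label, b$neutralized)
  out <- list(a = ta, b = tb)
  attr(out, "correspondence") <- do.call(rbind, corr)
  out
}

#' Thread a target sequence onto a template backbone
#'
#' Comparative modelling with unchanged mainchain geometry: backbone atoms
#' are copied from the template; where the target differs, the sidechain is
#' replaced (placed in the extended rotamer) and flagged for repacking.  The
#' alignment must be one-to-one with the template's modelled residues per
#' monomer; an oligomer is built by threading each monomer individually.
#' `-` in the target deletes the residue; insertions are unsupported.
#'
#' @param template an `fddh_assembly`
#' @param target_seq one-letter sequence aligned to one monomer chain
#' @return threaded assembly with attributes `percent_identity` and
#'   `repack_positions`
#' @export
thread_sequence <- function(template, target_seq) {
  letters1 <- strsplit(toupper(target_seq), "")[[1]]
  chains <- assembly_chains(template)
  out <- template
  repack <- character(0)
  n_match <- 0; n_tot <- 0
  for (ch in chains) {
    rt <- residue_table(template)
    rt <- rt[rt$chain == ch, , drop = FALSE]
    if (length(letters1) > nrow(rt))
      stop("unsupported insertion: target alignment longer than template chain ", ch)
    if (length(letters1) < nrow(rt))
      stop("alignment does not cover template chain ", ch)
    for (i in seq_len(nrow(rt))) {
      tl <- letters1[i]
      n_tot <- n_tot + 1
      tmpl1 <- aa_three_to_one(rt$resname[i])
      if (identical(tl, tmpl1)) { n_match <- n_match + 1; next }
      if (tl == "-") {
        out$atoms <- out$atoms[!(out$atoms$chain == ch &
                                 out$atoms$resno == rt$resno[i]), , drop = FALSE]
        next
      }
      new3 <- aa_one_to_three(tl)
      if (is.na(new3)) stop("unknown residue letter: ", tl)
      out <- replace_sidechain(out, ch, rt$resno[i], new3)
      repack <- c(repack, res_key(ch, rt$resno[i]))
    }
  }
  rownames(out$atoms) <- NULL
  attr(out, "percent_identity") <- 100 * n_match / n_tot
  attr(out, "repack_positions") <- repack
  out
}

# Replace one residue's sidechain (backbone untouched), renaming the residue.
replace_sidechain <- function(assembly, chain, resno, new_resname) {
  sel <- assembly$atoms$chain == chain & assembly$atoms$resno == resno
  if (!any(sel)) stop("no residue ", chain, ":", resno)
  res <- assembly$atoms[sel, , drop = FALSE]
  bb_names <- c("N", "CA", "C", "O", "OXT")
  keep_bb <- res[res$name %in% bb_names, , drop = FALSE]
  get1 <- function(nm) unlist(res[res$name == nm, c("x", "y", "z")])
  N <- get1("N"); CA <- get1("CA"); C <- get1("C")
  newrows <- keep_bb
  newrows$resname <- new_resname
  if (new_resname != "GLY") {
    CB <- ideal_cb(N, CA, C)
    coords <- c(list(CB = CB),
                build_sidechain_coords(new_resname, N, CA, CB,
                                       extended_chis(new_resname)))
    for (nm in names(coords)) {
      r <- keep_bb[1, , drop = FALSE]
      r$name <- nm; r$resname <- new_resname
      r$x <- coords[[nm]][1]; r$y <- coords[[nm]][2]; r$z <- coords[[nm]][3]
      r$element <- substr(nm, 1, 1)
      if ("radius" %in% names(r)) { r$radius <- NA; r$charge <- NA }
      newrows <- rbind(newrows, r)
    }
  }
  first <- min(which(sel))
  before <- if (first > 1) assembly$atoms[1:(first - 1), , drop = FALSE] else NULL
  after_idx <- which(!sel & seq_len(nrow(assembly$atoms)) >= first)
  after <- assembly$atoms[after_idx, , drop = FALSE]
  assembly$atoms <- rbind(before, newrows, after)
  rownames(assembly$atoms) <- NULL
  assembly
}

#' Mutation specification
#' @param chain,resno site location (author numbering)
#' @param operation `"charge_delete"` (permanently neutralize a titratable
#'   group, the calcium-binding mimic) or `"substitute"`
#' @param new_residue three-letter code for substitution
#' @return a `fddh_mutation` object
#' @export
mutation_spec <- function(chain, resno, operation = c("charge_delete", "substitute"),
                          new_residue = NULL) {
  operation <- match.arg(operation)
  if (operation == "substitute" && is.null(new_residue))
    stop("substitute requires new_residue")
  structure(list(chain = chain, resno = resno, operation = operation,
                 new_residue = new_residue), class = "fddh_mutation")
}

#' Apply a mutation to an assembly
#'
#' `charge_delete` marks a titratable group as permanently neutral (its
#' ionization charge is never applied and the site disappears from
#' [enumerate_titratable_sites()]); `substitute` replaces the sidechain and
#' flags it for repacking.
#'
#' @param assembly an `fddh_assembly`
#' @param spec a [mutation_spec()]
#' @return mutated assembly
#' @export
apply_mutation <- function(assembly, spec) {
  stopifnot(inherits(spec, "fddh_mutation"))
  sel <- assembly$atoms$chain == spec$chain & assembly$atoms$resno == spec$resno
  if (!any(sel)) stop("unknown site ", spec$chain, ":", spec$resno)
  resname <- assembly$atoms$resname[sel][1]
  if (spec$operation == "charge_delete") {
    if (!resname %in% model_pka_table()$restype)
      stop("charge_delete applies only to a titratable site, not ", resname)
    key <- res_key(spec$chain, spec$resno)
    if (key %in% assembly$neutralized)
      stop("site ", key, " already neutralized (absent)")
    assembly$neutralized <- c(assembly$neutralized, key)
    assembly
  } else {
    out <- replace_sidechain(assembly, spec$chain, spec$resno, spec$new_residue)
    attr(out, "repack_positions") <- res_key(spec$chain, spec$resno)
    out
  }
}

#' Enumerate titratable sites of an assembly
#'
#' One site per Asp/Glu/Lys/Arg/His (optionally Tyr/Cys) sidechain, and per
#' chain terminus when enabled.  Tyrosine, cysteine and the termini are
#' excluded by default, matching the physiological-window analyses.
#' Monomer indices group chains with identical residue sequences so that
#' per-monomer pKas can later be averaged.
#'
#' @param assembly parameterized `fddh_assembly`
#' @param include_termini add N-/C-terminal sites
#' @param include_tyr_cys add Tyr/Cys sidechain sites
#' @param pka_table from [model_pka_table()]
#' @return data.frame of sites (class `fddh_sites`)
#' @export
enumerate_titratable_sites <- function(assembly, include_termini = FALSE,
                                       include_tyr_cys = FALSE,
                                       pka_table = model_pka_table()) {
  rt <- residue_table(assembly)
  chains <- assembly_chains(assembly)
  seqs <- vapply(chains, function(ch)
    paste(rt$resname[rt$chain == ch], collapse = "-"), "")
  monomer_of <- integer(length(chains))
  for (i in seq_along(chains))
    monomer_of[i] <- sum(seqs[seq_len(i)] == seqs[i]) - 1L
  names(monomer_of) <- chains
  want <- c("ASP", "GLU", "LYS", "ARG", "HIS")
  if (include_tyr_cys) want <- c(want, "TYR", "CYS")
  out <- list()
  add_site <- function(chain, resno, restype, rowname) {
    p <- pka_table[pka_table$restype == rowname, ]
    out[[length(out) + 1]] <<- data.frame(
      chain = chain, resno = resno, restype = restype,
      model_pka = p$pka, ionized_charge = p$sign,
      charge_atoms = p$charge_atoms,
      monomer_index = unname(monomer_of[chain]), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(rt))) {
    if (!rt$resname[i] %in% want) next
    if (res_key(rt$chain[i], rt$resno[i]) %in% assembly$neutralized) next
    add_site(rt$chain[i], rt$resno[i], rt$resname[i], rt$resname[i])
  }
  if (include_termini) {
    for (ch in chains) {
      sub <- rt[rt$chain == ch, ]
      if (sub$resname[1] %in% names(.SIDECHAIN_TOPO))
        add_site(ch, sub$resno[1], "NTER", "NTER")
      if (sub$resname[nrow(sub)] %in% names(.SIDECHAIN_TOPO))
        add_site(ch, sub$resno[nrow(sub)], "CTER", "CTER")
    }
  }
  sites <- if (length(out) == 0)
    data.frame(chain = character(0), resno = integer(0), restype = character(0),
               model_pka = numeric(0), ionized_charge = integer(0),
               charge_atoms = character(0), monomer_index = integer(0))
  else do.call(rbind, out)
  class(sites) <- c("fddh_sites", "data.frame")
  sites
}

# Positions and fractional formal charges of a site's ionization increment.
# distributed = TRUE spreads the +-1 evenly over the group's terminal atoms.
site_charge_atoms <- function(assembly, site, distributed = TRUE) {
  nm <- strsplit(site$charge_atoms, ",")[[1]]
  a <- assembly$atoms
  sel <- a$chain == site$chain & a$resno == site$resno & a$name %in% nm
  sub <- a[sel, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("charge atoms ", site$charge_atoms, " not found for site ",
         site$chain, ":", site$resno)
  q <- if (distributed) rep(site$ionized_charge / nrow(sub), nrow(sub))
       else c(site$ionized_charge, rep(0, nrow(sub) - 1))
  data.frame(x = sub$x, y = sub$y, z = sub$z, q = q, name = sub$name,
             stringsAsFactors = FALSE)
}
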