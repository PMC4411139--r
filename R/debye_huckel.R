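# Uniform-solvent screened-Coulomb (Debye-Hueckel) model for
# solvent-accessible sites: no protein boundary, salt screening only.

#' Inverse Debye screening length
#'
#' kappa = sqrt(8 pi l_B n) with Bjerrum length l_B = 332.06/(eps kT) A and
#' 1:1 ion number density n (per A^3) at ionic strength I.  At 0.15 M, 298.15
#' K and eps 78.4 this gives kappa ~ 0.127 1/A (Debye length ~ 7.9 A).
#'
#' @param I ionic strength, mol/L
#' @param T temperature, Kelvin
#' @param eps relative permittivity of the solvent
#' @return kappa in 1/Angstrom
#' @export
kappa_from_ionic_strength <- function(I, T = 298.15, eps = 78.4) {
  if (I < 0) stop("ionic strength must be non-negative")
  if (I == 0) return(0)
  lB <- .COULOMB / (eps * kT_kcal(T))
  n <- .AVOGADRO * I * 1e-27   # ions per A^3 per species
  sqrt(8 * pi * lB * n)
}

#' Debye-Hueckel parameter set
#' @param eps_solvent relative permittivity (uniform)
#' @param ionic_strength mol/L
#' @param temperature Kelvin
#' @return a `fddh_dh_params` with derived kappa
#' @export
dh_params <- function(eps_solvent = 78.4, ionic_strength = 0.15,
                      temperature = 298.15) {
  structure(list(eps_solvent = eps_solvent, ionic_strength = ionic_strength,
                 temperature = temperature, kT = kT_kcal(temperature),
                 kappa = kappa_from_ionic_strength(ionic_strength, temperature,
                                                   eps_solvent)),
            class = "fddh_dh_params")
}

#' Screened Coulomb pair energy
#'
#' E = 332.06 q1 q2 exp(-kappa r) / (eps r), kcal/mol.
#'
#' @param q1,q2 charges in e
#' @param r separation in Angstrom (> 0)
#' @param params a [dh_params()]
#' @return kcal/mol
#' @export
screened_pair_energy <- function(q1, q2, r, params = dh_params()) {
  if (any(r <= 0)) stop("separation must be positive")
  .COULOMB * q1 * q2 * exp(-params$kappa * r) / (params$eps_solvent * r)
}

#' Debye-Hueckel site-site interaction matrix
#'
#' Screened Coulomb energies between the ionization charges of every site
#' pair, summed over charge-atom pairs.  Exactly symmetric with zero
#' diagonal.
#'
#' @param assembly parameterized `fddh_assembly`
#' @param sites titratable sites (data.frame)
#' @param params a [dh_params()]
#' @return symmetric matrix, kcal/mol
#' @export
dh_pairwise_matrix <- function(assembly, sites, params = dh_params()) {
  n <- nrow(sites)
  chg <- lapply(seq_len(n), function(i) site_charge_atoms(assembly, sites[i, ]))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    e <- 0
    ci <- chg[[i]]; cj <- chg[[j]]
    for (a in seq_len(nrow(ci))) {
      r <- sqrt((cj$x - ci$x[a])^2 + (cj$y - ci$y[a])^2 + (cj$z - ci$z[a])^2)
      if (any(r < 1e-6))
        stop("coincident charge atoms between sites ",
             res_key(sites$chain[i], sites$resno[i]), " and ",
             res_key(sites$chain[j], sites$resno[j]))
      e <- e + sum(screened_pair_energy(ci$q[a], cj$q, r, params))
    }
    W[i, j] <- W[j, i] <- e
  }
  W
}
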