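# Shared helpers: hand-built hybrid models and small utilities.

# A bare hybrid model from intrinsic pKas, charge signs and an interaction
# matrix (kcal/mol, fully-ionized convention).
mk_model <- function(pka, s, W = matrix(0, length(pka), length(pka)),
                     kT = 0.5922) {
  n <- length(pka)
  sites <- data.frame(chain = "A", resno = seq_len(n),
                      restype = ifelse(s < 0, "ASP", "LYS"),
                      model_pka = pka, ionized_charge = as.integer(s),
                      charge_atoms = ifelse(s < 0, "OD1,OD2", "NZ"),
                      monomer_index = 0L, stringsAsFactors = FALSE)
  env <- dielectric_environment()
  env$kT <- kT
  structure(list(sites = sites, treatment = rep("DH", n),
                 pka_intrinsic = pka, W = W,
                 provenance = matrix("DH", n, n), env = env, label = "toy"),
            class = "fddh_hybrid_model")
}

# synthetic linear energy curve
mk_curve <- function(ph, dG) {
  x <- data.frame(ph = ph, dG = dG)
  class(x) <- c("fddh_energy_curve", "data.frame")
  attr(x, "kT") <- 0.5922
  x
}

uniform_env <- function(ionic_strength = 0)
  dielectric_environment(eps_protein = 78.4, eps_solvent = 78.4,
                         ionic_strength = ionic_strength)

quiet_parameterize <- function(asm) parameterize(asm, check_complete = FALSE)
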