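# Hybrid FD/DH site model: FDPB treatment for buried groups, Debye-Hueckel
# for groups that can reach solvent by rotamer repacking.

#' Build the hybrid FD/DH site model
#'
#' Buried sites (not DH-eligible from the accessibility assessment) get FDPB
#' intrinsic pKas: the model pKa shifted by the desolvation and background
#' terms, with the shift direction set by the ionized-form charge sign.
#' DH-eligible sites keep their model pKa (the protein-solvent boundary is
#' removed for them).  Interaction-matrix entries use the FD solve when both
#' members are FD-treated and the screened-Coulomb closed form when either
#' member is DH-treated.
#'
#' @param assembly parameterized `fddh_assembly`
#' @param sites from [enumerate_titratable_sites()]
#' @param accessibility per-site assessment from [accessibility_scan()] or
#'   [max_attainable_accessibility()] (one row per site, matched by
#'   chain/resno)
#' @param env a [dielectric_environment()]
#' @param grid a [grid_spec()] or NULL for the default focusing protocol
#' @param dh_background also shift DH sites by a screened background term
#'   (default off)
#' @return a `fddh_hybrid_model`
#' @export
build_hybrid_model <- function(assembly, sites, accessibility,
                               env = dielectric_environment(), grid = NULL,
                               dh_background = FALSE) {
  n <- nrow(sites)
  if (n == 0) stop("no titratable sites")
  key_s <- res_key(sites$chain, sites$resno)
  key_a <- res_key(accessibility$chain, accessibility$resno)
  idx <- match(key_s, key_a)
  if (anyNA(idx)) stop("accessibility missing for site ", key_s[is.na(idx)][1])
  dh <- accessibility$dh_eligible[idx]
  treatment <- ifelse(dh, "DH", "FD")
  ln10kT <- log(10) * env$kT
  pka_int <- sites$model_pka
  W <- matrix(0, n, n)
  prov <- matrix("DH", n, n)
  fd_idx <- which(!dh)
  if (length(fd_idx) > 0) {
    fd <- site_energy_terms(assembly, sites, which_sites = fd_idx,
                            env = env, grid = grid)
    shift <- (fd$terms$dG_desolv + fd$terms$dG_background) / ln10kT
    pka_int[fd_idx] <- sites$model_pka[fd_idx] -
      sites$ionized_charge[fd_idx] * shift
    for (a in seq_along(fd_idx)) for (b in seq_along(fd_idx)) {
      i <- fd_idx[a]; j <- fd_idx[b]
      if (i != j) prov[i, j] <- "FD"
    }
    Wfd <- fd$W
    Wfd_s <- (Wfd[fd_idx, fd_idx, drop = FALSE] +
              t(Wfd[fd_idx, fd_idx, drop = FALSE])) / 2
    W[fd_idx, fd_idx] <- Wfd_s
  }
  if (any(dh) && n > 1) {
    params <- dh_params(env$eps_solvent, env$ionic_strength, env$temperature)
    Wdh <- dh_pairwise_matrix(assembly, sites, params)
    mixed <- outer(dh, dh, "|")
    W[mixed] <- Wdh[mixed]
  }
  diag(W) <- 0
  diag(prov) <- ""
  terms <- data.frame(dG_desolv = rep(0, n), dG_background = rep(0, n))
  if (length(fd_idx) > 0) {
    terms$dG_desolv[fd_idx] <- fd$terms$dG_desolv
    terms$dG_background[fd_idx] <- fd$terms$dG_background
  }
  if (dh_background && any(dh)) {
    params <- dh_params(env$eps_solvent, env$ionic_strength, env$temperature)
    for (i in which(dh)) {
      chg <- site_charge_atoms(assembly, sites[i, ])
      others <- assembly$atoms[!(assembly$atoms$chain == sites$chain[i] &
                                 assembly$atoms$resno == sites$resno[i]), ]
      e <- 0
      for (a in seq_len(nrow(chg))) {
        r <- sqrt((others$x - chg$x[a])^2 + (others$y - chg$y[a])^2 +
                  (others$z - chg$z[a])^2)
        r[r < 0.5] <- 0.5
        e <- e + sum(screened_pair_energy(chg$q[a], others$charge, r, params))
      }
      terms$dG_background[i] <- e
      pka_int[i] <- pka_int[i] - sites$ionized_charge[i] * e / ln10kT
    }
  }
  structure(list(sites = sites, treatment = treatment,
                 pka_intrinsic = pka_int, W = W, provenance = prov,
                 terms = terms, env = env,
                 label = assembly$label), class = "fddh_hybrid_model")
}

#' Build an FDPB-only site model
#'
#' As [build_hybrid_model()] but with every site forced to FD treatment,
#' for comparing the single-conformation FDPB picture with the hybrid one.
#'
#' @inheritParams build_hybrid_model
#' @return a `fddh_hybrid_model` with all-FD treatment
#' @export
build_fdpb_only_model <- function(assembly, sites,
                                  env = dielectric_environment(),
                                  grid = NULL) {
  acc <- data.frame(chain = sites$chain, resno = sites$resno,
                    restype = sites$restype, max_attainable_sasa = 0,
                    relative_accessibility = 0, dh_eligible = FALSE,
                    buried = TRUE)
  build_hybrid_model(assembly, sites, acc, env = env, grid = grid)
}

#' @export
print.fddh_hybrid_model <- function(x, ...) {
  cat(sprintf("fddh hybrid model '%s': %d sites (%d FD, %d DH)\n", x$label,
              nrow(x$sites), sum(x$treatment == "FD"),
              sum(x$treatment == "DH")))
  invisible(x)
}

#' Drop a site from a hybrid model
#'
#' Removes one row/column of the interaction matrix and the corresponding
#' intrinsic pKa, leaving every other entry unchanged (used for
#' charge-deletion mutants constructed after model building).
#'
#' @param model a `fddh_hybrid_model`
#' @param chain,resno site to remove
#' @return reduced model
#' @export
drop_site <- function(model, chain, resno) {
  i <- which(model$sites$chain == chain & model$sites$resno == resno)
  if (length(i) == 0) stop("unknown site ", res_key(chain, resno))
  keep <- setdiff(seq_len(nrow(model$sites)), i)
  model$sites <- model$sites[keep, , drop = FALSE]
  model$treatment <- model$treatment[keep]
  model$pka_intrinsic <- model$pka_intrinsic[keep]
  model$W <- model$W[keep, keep, drop = FALSE]
  model$provenance <- model$provenance[keep, keep, drop = FALSE]
  model$terms <- model$terms[keep, , drop = FALSE]
  model
}

#' Serialize a hybrid model to JSON
#'
#' Writes sites, treatments, intrinsic pKas and the interaction matrix so
#' the titration engine can run standalone from the file.
#'
#' @param model a `fddh_hybrid_model`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_hybrid_model <- function(model, path) {
  obj <- list(label = model$label,
              kT = model$env$kT,
              sites = model$sites,
              treatment = model$treatment,
              pka_intrinsic = model$pka_intrinsic,
              W = model$W,
              provenance = model$provenance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a hybrid model from JSON
#' @param path file from [write_hybrid_model()]
#' @return a `fddh_hybrid_model`
#' @export
read_hybrid_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  env <- dielectric_environment()
  env$kT <- obj$kT
  structure(list(sites = as.data.frame(obj$sites),
                 treatment = obj$treatment,
                 pka_intrinsic = obj$pka_intrinsic,
                 W = as.matrix(obj$W),
                 provenance = as.matrix(obj$provenance),
                 terms = NULL, env = env, label = obj$label),
            class = "fddh_hybrid_model")
}
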