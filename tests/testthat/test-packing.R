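# Mean-field rotamer packing and attainable-accessibility assessment.

test_that("single mobile residue selects the best one-body rotamer", {
  pep <- parameterize(peptide_assembly(c("GLY", "SER", "GLY")))
  res <- mean_field_pack(pep, packing_config(),
                         mobile = data.frame(chain = "A", resno = 2))
  expect_true(res$converged)
  # selected rotamer is an argmax of the probability vector
  p <- res$probabilities[["A:2"]]
  expect_equal(res$selected[["A:2"]], which.max(p))
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("forced leucine clash fails at zero tolerance, passes at 1.6 A", {
  # two leucines facing each other, CB axes aligned, 7 A apart: every
  # rotamer pair interpenetrates, yet an assignment fits at 1.6 A tolerance
  a <- peptide_assembly(c("GLY", "LEU", "GLY"), chain = "A")
  ca <- fddh:::res_atom_xyz(a, "A", 2, "CA")
  cb <- fddh:::res_atom_xyz(a, "A", 2, "CB")
  R1 <- fddh:::rotation_from_to(cb - ca, c(0, 1, 0))
  a <- transform_assembly(a, R = R1, t = -as.numeric(R1 %*% ca))
  b <- transform_assembly(a, R = diag(c(1, -1, -1)), t = c(0, 7, 0))
  b$atoms$chain <- "B"
  ab <- parameterize(fddh:::merge_assemblies(a, b))
  mob <- data.frame(chain = c("A", "B"), resno = c(2, 2))
  # brute force over all rotamer pairs verifies the plant
  rots_a <- fddh:::residue_rotamer_set(ab, "A", 2)
  rots_b <- fddh:::residue_rotamer_set(ab, "B", 2)
  worst <- Inf
  for (ra in rots_a) for (rb in rots_b) {
    ov <- fddh:::worst_overlap(ra, as.matrix(rb[, c("x", "y", "z")]), rb$radius)
    worst <- min(worst, ov)
  }
  expect_gt(worst, 0)      # no clash-free pair exists at tolerance 0
  expect_lte(worst, 1.6)   # but some pair fits at 1.6
  r0 <- suppressWarnings(mean_field_pack(ab, packing_config(clash_tolerance = 0),
                                         mobile = mob))
  r16 <- mean_field_pack(ab, packing_config(clash_tolerance = 1.6), mobile = mob)
  expect_false(r0$converged)
  expect_true(r16$converged)
})

test_that("probability vectors stay normalized and free energy non-increasing", {
  pep <- parameterize(peptide_assembly(c("LEU", "GLY", "LEU")))
  res <- mean_field_pack(pep, packing_config(clash_tolerance = 1.3))
  for (p in res$probabilities) {
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
  expect_true(all(diff(res$free_energy) < 1e-6))
})

test_that("isolated model compound reaches full relative accessibility", {
  for (rt in c("ASP", "LYS", "HIS")) {
    mc <- model_compound_assembly(rt)
    site <- enumerate_titratable_sites(mc)[1, ]
    r <- max_attainable_accessibility(mc, site)
    expect_equal(r$relative_accessibility, 1, tolerance = 0.05)
    expect_true(r$dh_eligible)
  }
})

test_that("exposed peptide lysine is accessible; caged lysine is not", {
  gkg <- parameterize(peptide_assembly(c("GLY", "LYS", "GLY")))
  s <- enumerate_titratable_sites(gkg)[1, ]
  r <- max_attainable_accessibility(gkg, s)
  expect_gt(r$relative_accessibility, 0.8)
  expect_true(r$dh_eligible)
  caged <- quiet_parameterize(fx_cage("closed"))
  sc <- enumerate_titratable_sites(caged)
  lys <- sc[sc$restype == "LYS", ]
  rc <- max_attainable_accessibility(caged, lys)
  expect_lt(rc$relative_accessibility, 0.1)
  expect_false(rc$dh_eligible)
})

test_that("gated cage flips DH eligibility between 0.8 and 1.6 A tolerance", {
  asm <- quiet_parameterize(fx_cage("gated"))
  sites <- enumerate_titratable_sites(asm)
  lys <- sites[sites$restype == "LYS", ]
  lo <- max_attainable_accessibility(asm, lys, packing_config(clash_tolerance = 0.8))
  hi <- max_attainable_accessibility(asm, lys, packing_config(clash_tolerance = 1.6))
  expect_false(lo$dh_eligible)
  expect_true(lo$buried)
  expect_true(hi$dh_eligible)
})

test_that("attainable SASA is non-decreasing in the clash tolerance", {
  tolerances <- c(0.8, 1.3, 1.6)
  for (fx in list(fx_cage("gated"), fx_cage("open"),
                  fx_salt_bridge("closed"))) {
    asm <- quiet_parameterize(fx)
    sites <- enumerate_titratable_sites(asm)
    tab <- accessibility_scan(asm, sites, tolerances)
    expect_equal(nrow(tab), nrow(sites) * length(tolerances))
    for (i in seq_len(nrow(sites))) {
      sub <- tab[tab$chain == sites$chain[i] & tab$resno == sites$resno[i], ]
      sub <- sub[order(sub$clash_tolerance), ]
      expect_true(all(diff(sub$max_attainable_sasa) >= -1e-9))
    }
  }
})

test_that("accessibility scan edge cases: single tolerance and empty sites", {
  asm <- quiet_parameterize(fx_cage("open"))
  sites <- enumerate_titratable_sites(asm)
  one <- accessibility_scan(asm, sites[1, ], 1.3)
  direct <- max_attainable_accessibility(asm, sites[1, ],
                                         packing_config(clash_tolerance = 1.3))
  expect_equal(one$max_attainable_sasa, direct$max_attainable_sasa)
  empty <- accessibility_scan(asm, sites[0, ], c(0.8, 1.6))
  expect_equal(nrow(empty), 0)
})

test_that("packing of a symmetric oligomer is identical per monomer", {
  tri <- quiet_parameterize(fx_trimer())
  res <- mean_field_pack(tri, packing_config(clash_tolerance = 1.3))
  expect_true(res$converged)
  for (resno in c(2, 3)) {
    pa <- res$probabilities[[paste0("A:", resno)]]
    pb <- res$probabilities[[paste0("B:", resno)]]
    pc <- res$probabilities[[paste0("C:", resno)]]
    expect_equal(pa, pb, tolerance = 1e-8)
    expect_equal(pa, pc, tolerance = 1e-8)
  }
})
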