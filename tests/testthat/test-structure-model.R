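# Structure model: PDB I/O, parameterization, trimming, threading,
# mutations, titratable-site enumeration.

test_that("PDB write/read round-trips atoms, chains and coordinates", {
  asm <- fx_salt_bridge("closed")
  p <- tempfile(fileext = ".pdb")
  write_pdb(asm, p)
  back <- read_pdb(p)
  expect_equal(nrow(back$atoms), nrow(asm$atoms))
  expect_identical(assembly_chains(back), c("A", "B"))
  expect_identical(back$atoms$name, asm$atoms$name)
  # PDB format precision is 1e-3 A
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                    as.matrix(asm$atoms[, c("x", "y", "z")]))), 1e-3)
  # second round trip is exact
  p2 <- tempfile(fileext = ".pdb")
  write_pdb(back, p2)
  back2 <- read_pdb(p2)
  expect_identical(back$atoms$x, back2$atoms$x)
  expect_error(read_pdb(tempfile()), "cannot read")
})

test_that("single alanine fixture parses to 6 heavy atoms in one chain", {
  p <- tempfile(fileext = ".pdb")
  write_pdb(peptide_assembly(c("ALA")), p)
  asm <- read_pdb(p)
  # N CA C O CB = 5 heavy atoms for a lone (un-capped) alanine
  expect_equal(nrow(asm$atoms), 5)
  expect_identical(assembly_chains(asm), "A")
})

test_that("alternate locations resolve to the highest-occupancy copy", {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       1.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "END")
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  asm <- read_pdb(p)
  expect_equal(nrow(asm$atoms), 2)
  expect_equal(asm$atoms$x[asm$atoms$name == "N"], 1.0)
})

test_that("parameterize assigns radii/charges and neutral residues sum to zero", {
  for (rt in c("ALA", "ASP", "LYS", "HIS", "SER", "ARG")) {
    asm <- parameterize(peptide_assembly(rt))
    expect_true(all(asm$atoms$radius > 0))
    expect_lt(abs(sum(asm$atoms$charge)), 1e-6)
  }
  # ionized-form increment sums to the formal charge
  asm <- parameterize(peptide_assembly("ASP"))
  site <- enumerate_titratable_sites(asm)[1, ]
  chg <- fddh:::site_charge_atoms(asm, site)
  expect_equal(sum(chg$q), -1)
  expect_equal(chg$q, c(-0.5, -0.5))
})

test_that("parameterize errors name the offending or missing atom", {
  asm <- peptide_assembly("ALA")
  asm$atoms$name[asm$atoms$name == "CB"] <- "XQ"
  expect_error(parameterize(asm), "ALA/XQ")
  asm2 <- peptide_assembly("LYS")
  asm2$atoms <- asm2$atoms[asm2$atoms$name != "NZ", ]
  expect_error(parameterize(asm2), "A:1 NZ")
  fixed <- repair_sidechains(asm2)
  expect_true("NZ" %in% fixed$atoms$name)
  expect_silent(parameterize(fixed))
})

test_that("trimming keeps the common residue range and is symmetric", {
  a <- peptide_assembly(rep("GLY", 25), resno_start = 45)   # 45..69
  b <- peptide_assembly(rep("GLY", 16), resno_start = 50)   # 50..65
  tr <- trim_to_common_length(a, b)
  expect_equal(range(tr$a$atoms$resno), c(50, 65))
  expect_equal(range(tr$b$atoms$resno), c(50, 65))
  sw <- trim_to_common_length(b, a)
  expect_identical(sort(unique(sw$a$atoms$resno)),
                   sort(unique(tr$b$atoms$resno)))
  # identity
  tid <- trim_to_common_length(a, a)
  expect_equal(nrow(tid$a$atoms), nrow(a$atoms))
  # disjoint ranges error
  c_ <- peptide_assembly(rep("GLY", 5), resno_start = 500)
  expect_error(trim_to_common_length(a, c_), "no common residues")
})

test_that("threading keeps the backbone, replaces sidechains, reports identity", {
  tmpl <- peptide_assembly(c("ALA", "ALA", "ALA"))
  same <- thread_sequence(tmpl, "AAA")
  expect_equal(attr(same, "percent_identity"), 100)
  expect_identical(same$atoms$x, tmpl$atoms$x)
  sub <- thread_sequence(tmpl, "AVA")
  expect_equal(attr(sub, "percent_identity"), 100 * 2 / 3)
  expect_identical(residue_table(sub)$resname, c("ALA", "VAL", "ALA"))
  # backbone untouched
  bb <- c("N", "CA", "C", "O")
  for (nm in bb) {
    t_bb <- tmpl$atoms[tmpl$atoms$resno == 2 & tmpl$atoms$name == nm, c("x", "y", "z")]
    s_bb <- sub$atoms[sub$atoms$resno == 2 & sub$atoms$name == nm, c("x", "y", "z")]
    expect_equal(unlist(s_bb), unlist(t_bb), ignore_attr = TRUE)
  }
  expect_identical(attr(sub, "repack_positions"), "A:2")
  # deletions shrink, insertions error
  del <- thread_sequence(tmpl, "A-A")
  expect_equal(nrow(residue_table(del)), 2)
  expect_error(thread_sequence(tmpl, "AAAA"), "insertion")
  # oligomer: threading applies to each monomer
  tri <- fx_trimer()
  th <- thread_sequence(tri, "GDKG")
  expect_equal(attr(th, "percent_identity"), 100)
})

test_that("charge deletion removes exactly one titratable site", {
  asm <- fx_buried_acid("closed")
  before <- enumerate_titratable_sites(quiet_parameterize(asm))
  mut <- apply_mutation(asm, mutation_spec("A", 2, "charge_delete"))
  after <- enumerate_titratable_sites(quiet_parameterize(mut))
  expect_equal(nrow(after), nrow(before) - 1)
  expect_false(any(after$chain == "A" & after$resno == 2))
  expect_error(apply_mutation(mut, mutation_spec("A", 2, "charge_delete")),
               "already neutralized")
  expect_error(apply_mutation(asm, mutation_spec("Q", 99, "charge_delete")),
               "unknown site")
  # charge_delete only applies to titratable residues
  gly <- peptide_assembly(c("GLY", "GLY"))
  expect_error(apply_mutation(gly, mutation_spec("A", 1, "charge_delete")),
               "titratable")
})

test_that("substitution replaces the sidechain and removes the site", {
  asm <- fx_buried_acid("closed")
  mut <- apply_mutation(asm, mutation_spec("A", 2, "substitute",
                                           new_residue = "ASN"))
  expect_identical(residue_table(mut)$resname[2], "ASN")
  sites <- enumerate_titratable_sites(quiet_parameterize(mut))
  expect_false(any(sites$chain == "A" & sites$resno == 2))
})

test_that("titratable-site enumeration counts sidechains, termini, monomers", {
  dke <- parameterize(peptide_assembly(c("ASP", "LYS", "GLU")))
  expect_equal(nrow(enumerate_titratable_sites(dke)), 3)
  expect_equal(nrow(enumerate_titratable_sites(dke, include_termini = TRUE)), 5)
  aaa <- parameterize(peptide_assembly(c("ALA", "ALA")))
  expect_equal(nrow(enumerate_titratable_sites(aaa)), 0)
  tri <- quiet_parameterize(fx_trimer())
  sites <- enumerate_titratable_sites(tri)
  expect_equal(nrow(sites), 6)
  expect_setequal(unique(sites$monomer_index), c(0, 1, 2))
  # total ionized charge equals the sum of site signs
  expect_equal(sum(sites$ionized_charge), 0)  # 3 Asp + 3 Lys
})

test_that("tyrosine/cysteine sites are off by default and switchable", {
  yc <- parameterize(peptide_assembly(c("TYR", "CYS")))
  expect_equal(nrow(enumerate_titratable_sites(yc)), 0)
  on <- enumerate_titratable_sites(yc, include_tyr_cys = TRUE)
  expect_equal(nrow(on), 2)
  expect_equal(on$ionized_charge, c(-1L, -1L))
})
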