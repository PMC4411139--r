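# Finite-difference LPBE solver: analytic oracles, superposition, maps.

test_that("uniform-dielectric solve matches the Coulomb closed form", {
  env <- uniform_env()
  m <- solve_lpbe(NULL, data.frame(x = 0, y = 0, z = 0, q = 1), env,
                  grid_spec(spacing = 0.6, dims = c(61, 61, 61),
                            center = c(0, 0, 0)))
  rs <- c(5, 7, 10, 12, 15)
  pts <- data.frame(x = rs / sqrt(3), y = rs / sqrt(3), z = rs / sqrt(3))
  num <- potential_at(m, pts)
  ana <- 332.06 / (78.4 * rs) / env$kT
  expect_lt(max(abs(num - ana) / ana), 0.02)
})

test_that("salt screening reproduces the Debye-Hueckel form", {
  env <- uniform_env(ionic_strength = 0.15)
  m <- solve_lpbe(NULL, data.frame(x = 0, y = 0, z = 0, q = 1), env,
                  grid_spec(spacing = 0.6, dims = c(61, 61, 61),
                            center = c(0, 0, 0)))
  rs <- c(5, 8, 12, 15)
  pts <- data.frame(x = rs, y = 0, z = 0)
  num <- potential_at(m, pts)
  ana <- 332.06 * exp(-env$kappa * rs) / (78.4 * rs) / env$kT
  expect_lt(max(abs(num - ana) / ana), 0.03)
})

test_that("zero charges give an identically zero map", {
  env <- uniform_env()
  m <- solve_lpbe(NULL, data.frame(x = 0, y = 0, z = 0, q = 0), env,
                  grid_spec(spacing = 1.0, dims = c(33, 33, 33),
                            center = c(0, 0, 0)))
  expect_equal(max(abs(m$levels[[1]]$phi)), 0)
})

test_that("superposition: two-charge potential is the sum of single-charge maps", {
  env <- uniform_env()
  gr <- grid_spec(spacing = 0.5, dims = c(49, 49, 49), center = c(2.5, 0, 0))
  m1 <- solve_lpbe(NULL, data.frame(x = 0, y = 0, z = 0, q = 1), env, gr)
  m2 <- solve_lpbe(NULL, data.frame(x = 5, y = 0, z = 0, q = 1), env, gr)
  m12 <- solve_lpbe(NULL, data.frame(x = c(0, 5), y = 0, z = 0, q = 1), env, gr)
  dev <- m12$levels[[1]]$phi - (m1$levels[[1]]$phi + m2$levels[[1]]$phi)
  expect_lt(max(abs(dev)), 1e-4)
})

test_that("Born desolvation of the 2.0 A sphere matches the analytic value", {
  env <- dielectric_environment(ionic_strength = 0)
  dg <- born_desolvation(fx_born_sphere(), data.frame(x = 0, y = 0, z = 0, q = 1),
                         env, grid = grid_spec(focusing_levels = c(1.6, 0.8, 0.4)),
                         reference = "solvated")
  ana <- (332.06 / 2) * (1 / 4 - 1 / 78.4) / 2.0
  expect_lt(abs(dg - ana) / ana, 0.05)
})

test_that("desolvation identities: exposed ~ 0, self-difference exactly 0", {
  env <- dielectric_environment()
  mc <- model_compound_assembly("ASP")
  site <- enumerate_titratable_sites(mc)[1, ]
  # folded state is the model compound: identical runs cancel exactly
  expect_equal(born_desolvation(mc, site, env), 0)
  # site whose surroundings add no boundary near the charges: ~ 0
  far <- transform_assembly(peptide_assembly(c("GLY", "GLY"), chain = "B"),
                            t = c(25, 0, 0))
  asm <- parameterize(fddh:::merge_assemblies(mc, far))
  asm$label <- "asp-with-remote-chain"
  expect_lt(abs(born_desolvation(asm, site, env)), 0.3)
  # exposed peptide site: small but non-negative (neighbours displace water)
  gdg <- parameterize(peptide_assembly(c("GLY", "ASP", "GLY")))
  s2 <- enumerate_titratable_sites(gdg)[1, ]
  d <- born_desolvation(gdg, s2, env)
  expect_gt(d, -0.05)
  expect_lt(d, 1.0)
})

test_that("buried site pays a positive desolvation penalty", {
  asm <- quiet_parameterize(fx_buried_acid("closed"))
  sites <- enumerate_titratable_sites(asm)
  st <- site_energy_terms(asm, sites, which_sites = 1,
                          env = dielectric_environment())
  expect_gt(st$terms$dG_desolv[1], 2)
})

test_that("pairwise interaction matches Coulomb and flips with charge sign", {
  env <- uniform_env()
  gr <- grid_spec(spacing = 0.5, dims = c(49, 49, 49), center = c(2.5, 0, 0))
  m <- solve_lpbe(NULL, data.frame(x = 0, y = 0, z = 0, q = 1), env, gr)
  w <- env$kT * potential_at(m, data.frame(x = 5, y = 0, z = 0))
  expect_lt(abs(w - 332.06 / (78.4 * 5)) / w, 0.05)
  mneg <- solve_lpbe(NULL, data.frame(x = 0, y = 0, z = 0, q = -1), env, gr)
  wneg <- env$kT * potential_at(mneg, data.frame(x = 5, y = 0, z = 0))
  expect_equal(wneg, -w, tolerance = 1e-9)
})

test_that("site-site matrix is near-symmetric before averaging, zero diagonal", {
  asm <- quiet_parameterize(fx_salt_bridge("closed"))
  sites <- enumerate_titratable_sites(asm)
  st <- site_energy_terms(asm, sites, env = dielectric_environment())
  W <- st$W
  expect_lt(abs(W[1, 2] - W[2, 1]) / abs(W[1, 2]), 0.05)
  Ws <- pairwise_matrix(asm, sites, env = dielectric_environment())
  expect_equal(Ws, t(Ws))
  expect_equal(diag(Ws), rep(0, nrow(sites)))
})

test_that("grid refinement changes the desolvation term by < 5%", {
  asm <- quiet_parameterize(fx_buried_acid("closed"))
  sites <- enumerate_titratable_sites(asm)
  env <- dielectric_environment()
  d1 <- site_energy_terms(asm, sites, which_sites = 1, env = env,
                          grid = grid_spec(focusing_levels = c(2.4, 1.2, 0.6)))
  d2 <- site_energy_terms(asm, sites, which_sites = 1, env = env,
                          grid = grid_spec(focusing_levels = c(2.4, 1.2, 0.6, 0.3)))
  expect_lt(abs(d1$terms$dG_desolv - d2$terms$dG_desolv) /
            abs(d2$terms$dG_desolv), 0.05)
})

test_that("energies are invariant under 90-degree rotation about a grid axis", {
  env <- dielectric_environment(ionic_strength = 0)
  mc <- model_compound_assembly("ASP")
  site <- enumerate_titratable_sites(mc)[1, ]
  d1 <- born_desolvation(mc, site, env, reference = "solvated")
  rot <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  d2 <- born_desolvation(transform_assembly(mc, R = rot), site, env,
                         reference = "solvated")
  expect_lt(abs(d2 - d1) / abs(d1), 0.01)
})

test_that("OpenDX export round-trips and has consistent header counts", {
  env <- uniform_env()
  m <- solve_lpbe(NULL, data.frame(x = 0, y = 0, z = 0, q = 1), env,
                  grid_spec(spacing = 1.0, dims = c(25, 27, 29),
                            center = c(0, 0, 0)))
  p <- tempfile(fileext = ".dx")
  export_dx(m, p)
  hdr <- grep("gridpositions", readLines(p), value = TRUE)
  expect_match(hdr, "25 27 29")
  back <- read_dx(p)
  expect_equal(back$levels[[1]]$dims, c(25L, 27L, 29L))
  expect_lt(max(abs(back$levels[[1]]$phi - m$levels[[1]]$phi)), 1e-5)
  # zero map
  z <- m; z$levels[[1]]$phi <- rep(0, length(m$levels[[1]]$phi))
  pz <- tempfile(fileext = ".dx")
  export_dx(z, pz)
  expect_equal(max(abs(read_dx(pz)$levels[[1]]$phi)), 0)
})

test_that("difference maps obey linearity of the LPBE", {
  env <- uniform_env()
  gr <- grid_spec(spacing = 0.5, dims = c(49, 49, 49), center = c(2.5, 0, 0))
  ma <- solve_lpbe(NULL, data.frame(x = c(0, 5), y = 0, z = 0, q = c(1, 1)), env, gr)
  mb <- solve_lpbe(NULL, data.frame(x = 0, y = 0, z = 0, q = 1), env, gr)
  d <- difference_map(ma, mb)
  mc_ <- solve_lpbe(NULL, data.frame(x = 5, y = 0, z = 0, q = 1), env, gr)
  expect_lt(max(abs(d$levels[[1]]$phi - mc_$levels[[1]]$phi)), 1e-4)
  # self-difference and antisymmetry
  expect_equal(max(abs(difference_map(ma, ma)$levels[[1]]$phi)), 0)
  expect_equal(difference_map(ma, mb)$levels[[1]]$phi,
               -difference_map(mb, ma)$levels[[1]]$phi)
  # grid mismatch
  other <- solve_lpbe(NULL, data.frame(x = 0, y = 0, z = 0, q = 1), env,
                      grid_spec(spacing = 1.0, dims = c(33, 33, 33),
                                center = c(0, 0, 0)))
  expect_error(difference_map(ma, other), "mismatch")
})

test_that("contour envelope membership follows the analytic iso-radius", {
  env <- uniform_env(ionic_strength = 0.15)
  m <- solve_lpbe(NULL, data.frame(x = 0, y = 0, z = 0, q = 1), env,
                  grid_spec(spacing = 0.6, dims = c(61, 61, 61),
                            center = c(0, 0, 0)))
  lvl <- 0.5  # kT/2e
  f <- function(r) 332.06 * exp(-env$kappa * r) / (78.4 * r) / env$kT - lvl
  iso <- stats::uniroot(f, c(1, 17))$root
  inside <- transform_assembly(peptide_assembly("GLY"), t = c(iso - 2.5, 0, 0))
  outside <- transform_assembly(peptide_assembly("GLY"), t = c(iso + 4, 0, 0))
  expect_equal(nrow(contour_envelope_members(m, lvl, inside)), 1)
  expect_equal(nrow(contour_envelope_members(m, lvl, outside)), 0)
  # level above the global maximum -> empty
  expect_equal(nrow(contour_envelope_members(m, 1e6, inside)), 0)
  expect_error(contour_envelope_members(m, 0, inside))
})
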