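# Titration engines: exact enumeration, Monte Carlo, pK-half extraction,
# pH-dependent ionization free energy.

test_that("a single site follows Henderson-Hasselbalch exactly", {
  m <- mk_model(4.0, -1)
  cv <- enumerate_exact(m)
  i4 <- which(cv$ph_grid == 4.0)
  expect_equal(cv$mean_charge[i4, 1], -0.5)
  i3 <- which(cv$ph_grid == 3.0)
  expect_equal(cv$mean_protonation[i3, 1], 1 / (1 + 10^(3 - 4)))
  expect_true(all(cv$mean_charge[, 1] >= -1 & cv$mean_charge[, 1] <= 0))
  base <- enumerate_exact(mk_model(10.4, 1))
  expect_true(all(base$mean_charge[, 1] >= 0 & base$mean_charge[, 1] <= 1))
})

test_that("two coupled acids reproduce the hand-built 4-state partition function", {
  W <- matrix(c(0, 1.364, 1.364, 0), 2, 2)
  m <- mk_model(c(4, 4), c(-1, -1), W)
  cv <- enumerate_exact(m)
  kT <- 0.5922; l <- log(10) * kT
  hand <- vapply(cv$ph_grid, function(p) {
    e <- c(0, l * (4 - p), l * (4 - p), 2 * l * (4 - p) + 1.364)
    w <- exp(-(e - min(e)) / kT)
    (w[2] + w[4]) / sum(w)   # ionization of site 1
  }, 0)
  expect_equal(-cv$mean_charge[, 1], hand, tolerance = 1e-12)
  # repulsive coupling delays per-site half-ionization past the model pKa;
  # by symmetry both sites shift identically
  pk <- compute_pkhalf(cv)$per_site$pk_half
  expect_gt(pk[1], 4.0)
  expect_lt(pk[1], 4.0 + 1.364 / 1.364 + 0.5)
  expect_equal(pk[1], pk[2])
})

test_that("exact enumeration refuses more than 20 sites", {
  m <- mk_model(rep(4, 21), rep(-1, 21))
  expect_error(enumerate_exact(m), "20 sites")
})

test_that("Monte Carlo agrees with enumeration and is seed-reproducible", {
  W <- matrix(c(0, 2.5, 2.5, 0), 2, 2)   # strongly coupled: pair moves active
  m <- mk_model(c(4.5, 5.5), c(-1, -1), W)
  ex <- enumerate_exact(m)
  mc <- monte_carlo_titrate(m, seed = 11)
  dev <- abs(mc$mean_protonation - ex$mean_protonation)
  expect_true(all(dev <= 3 * mc$se + 5e-3))
  mc2 <- monte_carlo_titrate(m, seed = 11)
  expect_identical(mc$mean_protonation, mc2$mean_protonation)
  mc3 <- monte_carlo_titrate(m, seed = 12)
  expect_false(identical(mc$mean_protonation, mc3$mean_protonation))
  expect_error(monte_carlo_titrate(m), "seed")
})

test_that("zero-interaction Monte Carlo recovers closed-form HH curves", {
  m <- mk_model(c(4.0, 10.4), c(-1, 1))
  mc <- monte_carlo_titrate(m, seed = 3)
  hh_acid <- 1 / (1 + 10^(mc$ph_grid - 4.0))
  hh_base <- 1 / (1 + 10^(mc$ph_grid - 10.4))
  expect_true(all(abs(mc$mean_protonation[, 1] - hh_acid) <= 3 * mc$se[, 1] + 5e-3))
  expect_true(all(abs(mc$mean_protonation[, 2] - hh_base) <= 3 * mc$se[, 2] + 5e-3))
})

test_that("pK-half interpolation, clamping and monomer averaging behave", {
  cv <- enumerate_exact(mk_model(4.0, -1))
  pk <- compute_pkhalf(cv)
  expect_equal(pk$per_site$pk_half, 4.0, tolerance = 0.02)
  expect_identical(pk$per_site$flag, "ok")
  # protonated across the whole grid: clamped and flagged
  hi <- enumerate_exact(mk_model(20, -1))
  pkhi <- compute_pkhalf(hi)
  expect_identical(pkhi$per_site$flag, ">14")
  expect_equal(pkhi$per_site$pk_half, 14)
  lo <- enumerate_exact(mk_model(-3, -1))
  expect_identical(compute_pkhalf(lo)$per_site$flag, "<0")
  # trimer: per-monomer values equal, averaging idempotent
  tri <- ph_energy_pipeline(fx_trimer())
  per <- tri$pka$per_site
  for (rt in unique(per$restype)) {
    v <- per$pk_half[per$restype == rt]
    expect_lt(diff(range(v)), 1e-6)
    expect_equal(tri$pka$averaged$pk_half[tri$pka$averaged$restype == rt],
                 mean(v))
  }
})

test_that("mean protonation is non-increasing in pH for uncoupled sites", {
  m <- mk_model(c(4, 6.3, 10.4), c(-1, 1, 1))
  cv <- enumerate_exact(m)
  for (i in 1:3) expect_true(all(diff(cv$mean_protonation[, i]) <= 1e-12))
})

test_that("ionization free energy matches the partition-function oracle", {
  # acid shifted from model 4.0 to intrinsic 6.0
  m <- mk_model(4.0, -1)
  m$pka_intrinsic <- 6.0
  cv <- enumerate_exact(m)
  ec <- ionization_free_energy_curve(cv, m, ph_ref = 0)
  kT <- 0.5922
  oracle <- function(p) (-kT * log(1 + 10^(p - 6))) - (-kT * log(1 + 10^(p - 4)))
  for (p in c(2, 5, 8, 14))
    expect_lt(abs(ec$dG[which.min(abs(ec$ph - p))] - (oracle(p) - oracle(0))),
              2e-3)
  # model identical to reference: identically zero
  m0 <- mk_model(4.0, -1)
  ec0 <- ionization_free_energy_curve(enumerate_exact(m0), m0, ph_ref = 7)
  expect_equal(max(abs(ec0$dG)), 0, tolerance = 1e-12)
  expect_equal(ec0$dG[ec0$ph == 7], 0)
})

test_that("Wyman linkage: dG slope equals ln10 kT times the charge difference", {
  W <- matrix(c(0, 1.0, 1.0, 0), 2, 2)
  m <- mk_model(c(4.2, 5.1), c(-1, -1), W)
  m$pka_intrinsic <- c(5.4, 6.2)
  cv <- enumerate_exact(m)
  ec <- ionization_free_energy_curve(cv, m, ph_ref = 0)
  dq <- attr(ec, "net_charge") - attr(ec, "ref_charge")
  ln10kT <- log(10) * 0.5922
  n <- nrow(ec)
  h <- ec$ph[2] - ec$ph[1]
  slope <- (ec$dG[3:n] - ec$dG[1:(n - 2)]) / (2 * h)
  mid <- ln10kT * dq[2:(n - 1)]
  # trapezoid truncation: central difference of the cumulative trapezoid is
  # the average of adjacent interval means
  expect_lt(max(abs(slope - mid)), ln10kT * h)
})

test_that("dG is invariant to site ordering", {
  W <- matrix(c(0, -0.8, -0.8, 0), 2, 2)
  m <- mk_model(c(4.0, 10.4), c(-1, 1), W)
  cv <- enumerate_exact(m)
  ec <- ionization_free_energy_curve(cv, m, ph_ref = 0)
  m2 <- mk_model(c(10.4, 4.0), c(1, -1), W)
  cv2 <- enumerate_exact(m2)
  ec2 <- ionization_free_energy_curve(cv2, m2, ph_ref = 0)
  expect_equal(ec$dG, ec2$dG, tolerance = 1e-12)
})
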