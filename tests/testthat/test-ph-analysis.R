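# CFR discovery and classification: scatter, sensor window, repack scan,
# mutation classification, pH50.

test_that("conformer scatter pairs sites and mirrors under input swap", {
  pl <- ph_energy_pipeline(fx_salt_bridge("closed"))
  sc_same <- conformer_pka_scatter(pl$pka, pl$pka)
  expect_equal(sc_same$value_a, sc_same$value_b)
  pl2 <- ph_energy_pipeline(fx_salt_bridge("open"))
  sc <- conformer_pka_scatter(pl$pka, pl2$pka)
  sw <- conformer_pka_scatter(pl2$pka, pl$pka)
  expect_equal(sc$value_a, sw$value_b)
  expect_equal(sc$value_b, sw$value_a)
  # unmatched site errors with its name
  pk3 <- pl2$pka
  pk3$per_site <- pk3$per_site[-1, ]
  expect_error(conformer_pka_scatter(pl$pka, pk3), "unmatched")
})

test_that("sensor-window rule matches a brute-force reimplementation", {
  w <- sensor_window(6, 8, 0.5)
  grid <- expand.grid(a = seq(2, 12, 0.5), b = seq(2, 12, 0.5))
  sc <- data.frame(chain = "A", resno = seq_len(nrow(grid)), restype = "ASP",
                   value_a = grid$a, value_b = grid$b,
                   flag_a = "ok", flag_b = "ok", flagged = NA)
  attr(sc, "scan_kind") <- "conformer"
  class(sc) <- c("fddh_cfr_scan", "data.frame")
  got <- flag_sensor_candidates(sc, w)$flagged
  brute <- mapply(function(a, b) {
    off_diagonal <- abs(a - b) >= 0.5
    both_below <- a < 6 && b < 6
    both_above <- a > 8 && b > 8
    off_diagonal && !both_below && !both_above
  }, grid$a, grid$b)
  expect_identical(got, unname(brute))
  # rule examples
  ex <- sc[1:3, ]
  ex$value_a <- c(5, 7, 3); ex$value_b <- c(7, 7, 5.5)
  expect_identical(flag_sensor_candidates(ex, w)$flagged, c(TRUE, FALSE, FALSE))
  # invariance under exchanging the two conditions
  sc_sw <- sc; sc_sw$value_a <- sc$value_b; sc_sw$value_b <- sc$value_a
  expect_identical(flag_sensor_candidates(sc_sw, w)$flagged, got)
})

test_that("the planted window-crossing acid is flagged; the exposed base is not", {
  res <- compare_conformers(fx_buried_acid("closed"), fx_buried_acid("open"))
  sc <- res$scatter
  acid <- sc$restype == "ASP"
  expect_true(all(sc$flagged[acid]))
  expect_false(any(sc$flagged[!acid]))
})

test_that("repacking scan flags exactly the planted gated lysine", {
  sc <- repack_perturbation_scan(fx_cage("gated"))
  expect_identical(sc$flagged, sc$restype == "LYS")
  lys <- sc[sc$restype == "LYS", ]
  # acid dq in [0, +1], base dq in [-1, 0] (bound charge convention)
  expect_true(all(sc$value_a[sc$restype == "ASP"] >= -1e-6 &
                  sc$value_a[sc$restype == "ASP"] <= 1 + 1e-6))
  expect_true(lys$value_a >= -1 - 1e-6 && lys$value_a <= 1e-6)
  # buried at 0.8 A: ionization suppressed; DH at 1.6 A: model behaviour
  expect_lt(lys$value_a, -0.5)
  expect_lt(abs(lys$value_b), 0.05)
})

test_that("repacking scan with equal tolerances flags nothing", {
  sc <- repack_perturbation_scan(fx_cage("gated"), tol_low = 1.6,
                                 tol_high = 1.6)
  expect_equal(sc$value_a, sc$value_b)
  expect_false(any(sc$flagged))
})

test_that("fully exposed structure produces no repacking flags", {
  sc <- repack_perturbation_scan(fx_salt_bridge("open"))
  expect_false(any(sc$flagged))
  expect_true(all(abs(sc$value_a - sc$value_b) < 0.1))
})

test_that("delta curves subtract pointwise with the expected symmetries", {
  ph <- seq(0, 14, 0.1)
  a <- mk_curve(ph, ph - 7)
  b <- mk_curve(ph, 0.5 * ph)
  d <- delta_energy_curve(a, b)
  expect_equal(d$dG, (ph - 7) - 0.5 * ph)
  expect_equal(delta_energy_curve(b, a)$dG, -d$dG)
  expect_equal(max(abs(delta_energy_curve(a, a)$dG)), 0)
  expect_error(delta_energy_curve(a, mk_curve(seq(0, 10, 0.1), seq(0, 10, 0.1))),
               "mismatch")
})

test_that("classification rules on synthetic linear curves", {
  ph <- seq(0, 14, 0.1)
  wt <- mk_curve(ph, 0.2 * ph)
  coupled <- mk_curve(ph, 0.2 * ph + 1.0)
  sensor <- mk_curve(ph, 0.2 * ph + 2.0 * (ph - 7))
  same <- mk_curve(ph, 0.2 * ph)
  expect_identical(classify_mutation(wt, coupled)$label, "pH-coupled")
  expect_identical(classify_mutation(wt, sensor)$label, "pH-sensor")
  expect_identical(classify_mutation(wt, same)$label, "neither")
  # gauge invariance: adding a constant to both curves changes nothing
  shift <- function(cv, c0) mk_curve(cv$ph, cv$dG + c0)
  c1 <- classify_mutation(wt, coupled)
  c2 <- classify_mutation(shift(wt, 5), shift(coupled, 5))
  expect_identical(c1$label, c2$label)
  expect_equal(c1$slope_diff, c2$slope_diff)
  expect_equal(c1$offset, c2$offset)
  expect_error(classify_mutation(mk_curve(0:3, 0:3), mk_curve(0:3, 0:3)),
               "window")
})

test_that("pH50 crossover mechanics: location, absence, offset shift", {
  ph <- seq(0, 14, 0.1)
  open <- mk_curve(ph, ph - 7)
  closed <- mk_curve(ph, rep(0, length(ph)))
  expect_equal(find_ph50_crossover(open, closed), 7.0)
  # strictly positive difference: none
  expect_length(find_ph50_crossover(mk_curve(ph, ph + 20), closed), 0)
  # uniform +1 shift moves the crossover by shift/slope = 1
  shifted <- mk_curve(ph, ph - 7 + 1)
  expect_equal(find_ph50_crossover(shifted, closed), 6.0)
  # multiple crossings warn
  wavy <- mk_curve(ph, sin(ph))
  expect_warning(res <- find_ph50_crossover(wavy, closed), "multiple")
  expect_gt(length(res), 1)
})

test_that("salt-bridge deletion is pH-coupled, buried-acid deletion pH-sensing", {
  cfg <- run_config()
  # salt bridge: both partners ionized throughout the window in both forms
  trb <- trim_to_common_length(fx_salt_bridge("closed"), fx_salt_bridge("open"))
  wt_b <- delta_energy_curve(ph_energy_pipeline(trb$b, cfg)$energy,
                             ph_energy_pipeline(trb$a, cfg)$energy)
  del <- mutation_spec("A", 2, "charge_delete")
  mut_b <- delta_energy_curve(
    ph_energy_pipeline(apply_mutation(trb$b, del), cfg)$energy,
    ph_energy_pipeline(apply_mutation(trb$a, del), cfg)$energy)
  expect_identical(classify_mutation(wt_b, mut_b, cfg$window)$label, "pH-coupled")
  # buried acid: ionization differs between conformers inside the window
  tra <- trim_to_common_length(fx_buried_acid("closed"), fx_buried_acid("open"))
  wt_a <- delta_energy_curve(ph_energy_pipeline(tra$b, cfg)$energy,
                             ph_energy_pipeline(tra$a, cfg)$energy)
  mut_a <- delta_energy_curve(
    ph_energy_pipeline(apply_mutation(tra$b, del), cfg)$energy,
    ph_energy_pipeline(apply_mutation(tra$a, del), cfg)$energy)
  expect_identical(classify_mutation(wt_a, mut_a, cfg$window)$label, "pH-sensor")
})

test_that("calcium-mimic deletions flip the window slope sign", {
  res <- calcium_mimic_run(fx_calcium_toy("closed"),
                           list(mutation_spec("A", 2, "charge_delete"),
                                mutation_spec("B", 2, "charge_delete")),
                           fx_calcium_toy("open"))
  expect_lt(res$slope_wt, 0)
  expect_gt(res$slope_mut, 0)
  # empty deletion list reduces to the plain delta
  res0 <- calcium_mimic_run(fx_calcium_toy("closed"), list(),
                            fx_calcium_toy("open"))
  expect_equal(res0$wt_delta$dG, res0$mut_delta$dG)
  # deletion site must exist in the closed form
  expect_error(calcium_mimic_run(fx_calcium_toy("closed"),
                                 list(mutation_spec("Q", 1, "charge_delete")),
                                 fx_calcium_toy("open")), "missing|unknown")
})
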