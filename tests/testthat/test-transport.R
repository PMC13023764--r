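# Monte Carlo kernel: Klein-Nishina sampler, Beer-Lambert limit, energy
# conservation, determinism, uncertainty scaling, physical orderings.

kn_density <- function(energy, mu) {
  a <- energy / 510.99895
  k <- 1 / (1 + a * (1 - mu))
  0.5 * k^2 * (k + 1 / k - (1 - mu^2))    # ~ dsigma/dOmega, r_e^2 dropped
}

test_that("Klein-Nishina samples respect the Compton kinematic bounds", {
  for (e in c(10, 60, 150)) {
    s <- kn_sample(e, 2e4, seed = 5)
    emin <- e / (1 + 2 * e / 510.99895)
    expect_true(all(s$energy <= e + 1e-12))
    expect_true(all(s$energy >= emin - 1e-12))
    expect_true(all(abs(s$cos_theta) <= 1))
    # scattered energy and angle obey the Compton relation
    pred <- e / (1 + e / 510.99895 * (1 - s$cos_theta))
    expect_equal(s$energy, pred, tolerance = 1e-10)
  }
})

test_that("sampled angular distribution matches the analytic KN density", {
  e <- 10
  s <- kn_sample(e, 1e6, seed = 11)
  breaks <- seq(-1, 1, length.out = 21)
  obs <- table(cut(s$cos_theta, breaks))
  p <- vapply(seq_len(20), function(i) {
    integrate(function(m) kn_density(e, m), breaks[i], breaks[i + 1])$value
  }, 0)
  p <- p / sum(p)
  gof <- chisq.test(as.numeric(obs), p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("mean Compton energy transfer matches the analytic fraction", {
  e <- 60
  s <- kn_sample(e, 1e6, seed = 13)
  frac <- mean(1 - s$energy / e)
  num <- integrate(function(m) kn_density(e, m) *
                     (1 - 1 / (1 + e / 510.99895 * (1 - m))), -1, 1)$value
  den <- integrate(function(m) kn_density(e, m), -1, 1)$value
  expect_equal(frac, num / den, tolerance = 0.01)
})

test_that("pure-absorber depth dose follows Beer-Lambert within 3 SE", {
  ph <- build_model("C")
  e0 <- 30
  cfg <- transport_config(4e5, seed = 21, incoherent = FALSE,
                          coherent = FALSE, fluorescence = FALSE)
  g <- run_transport(ph, mono_spectrum(e0), cfg, xs_tables)
  mu <- mixture_mu(material_water(), e0, "photoelectric",
                   xs_tables)$linear   # 1/cm
  dd <- depth_dose(g)
  z0 <- (seq_len(25) - 1) * 0.02      # layer bounds, cm
  z1 <- seq_len(25) * 0.02
  frac <- exp(-mu * z0) - exp(-mu * z1)
  conv <- 1.602176634e-16 / 8e-9      # keV -> Gy in a 0.2 mm water voxel
  expected <- cfg$n_photons * e0 * frac / 625 * conv
  expect_true(all(abs(dd$values - expected) <= 3 * dd$uncertainties + 1e-30))
  # analytic primary-only profile is monotone decreasing, like the MC here
  bl <- beer_lambert_depth_profile(mono_spectrum(e0), material_water(),
                                   dd$depths, xs_tables)
  expect_true(all(diff(bl$values) < 0))
})

test_that("energy is conserved exactly per history", {
  ph <- build_model("B")
  sp <- generate_spectrum(tube_config(100), xs_tables)
  cfg <- transport_config(2000, seed = 31, n_batches = 2)
  g <- run_transport(ph, sp, cfg, xs_tables, instrument = TRUE)
  bal <- g$instrument$emitted - g$instrument$deposited - g$instrument$escaped
  expect_lt(max(abs(bal)), 1e-9)
  tot <- g$totals
  expect_equal(tot$emitted,
               tot$deposited_tumor + tot$deposited_outside + tot$escaped,
               tolerance = 1e-12)
  expect_true(all(g$energy_dep >= 0))
})

test_that("transport is deterministic for a fixed seed", {
  ph <- build_model("C")
  sp <- generate_spectrum(tube_config(60), xs_tables)
  cfg <- transport_config(2e4, seed = 77)
  g1 <- run_transport(ph, sp, cfg, xs_tables)
  g2 <- run_transport(ph, sp, cfg, xs_tables)
  expect_identical(g1$energy_dep, g2$energy_dep)
  expect_identical(g1$rel_uncertainty, g2$rel_uncertainty)
  g3 <- run_transport(ph, sp, transport_config(2e4, seed = 78), xs_tables)
  expect_false(identical(g1$energy_dep, g3$energy_dep))
})

test_that("relative uncertainty scales as one over root N", {
  ph <- build_model("C")
  sp <- generate_spectrum(tube_config(60), xs_tables)
  g1 <- run_transport(ph, sp, transport_config(2e5, seed = 41), xs_tables)
  g4 <- run_transport(ph, sp, transport_config(8e5, seed = 42), xs_tables)
  sel <- g1$dose > 0 & g4$dose > 0
  ratio <- median(g1$rel_uncertainty[sel]) / median(g4$rel_uncertainty[sel])
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("dose conversion implements energy over voxel mass", {
  ph <- build_model("C")
  g <- toy_dose_grid(array(0, dim = c(25, 25, 25)), ph)
  g$energy_dep[1, 1, 1] <- 1    # 1 keV
  g <- convert_to_dose(g, ph)
  expect_equal(g$dose[1, 1, 1], 1.602176634e-16 / 8e-9)
  expect_equal(g$dose[2, 1, 1], 0)
  # doubling the density halves the dose
  ph2 <- ph
  ph2$materials$tumor <- material("heavy", c(H = 0.1119, O = 0.8881), 2)
  g2 <- convert_to_dose(g, ph2)
  expect_equal(g2$dose[1, 1, 1], g$dose[1, 1, 1] / 2)
})

test_that("the nanoprobe raises tumor dose and backing tissue matters", {
  sp <- generate_spectrum(tube_config(60), xs_tables)
  cfg <- transport_config(3e5, seed = 51)
  gA <- run_transport(build_model("A"), sp, cfg, xs_tables)
  gB <- run_transport(build_model("B"), sp, cfg, xs_tables)
  gC <- run_transport(build_model("C"), sp, cfg, xs_tables)
  expect_gt(aad(gB), aad(gA))          # radiosensitization
  expect_gt(aad(gA), aad(gC))          # scatter/backscatter from the slab
})

test_that("DER of a model against itself is unity within noise", {
  sp <- generate_spectrum(tube_config(60), xs_tables)
  ph <- build_model("A")
  g1 <- run_transport(ph, sp, transport_config(3e5, seed = 61), xs_tables)
  g2 <- run_transport(ph, sp, transport_config(3e5, seed = 62), xs_tables)
  der <- der_curve(depth_dose(g1), depth_dose(g2))
  expect_true(all(abs(der$values - 1) <= 5 * der$uncertainties))
  expect_equal(aad_der(g1, g2), 1, tolerance = 0.02)
})
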