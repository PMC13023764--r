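# Tube spectrum model: kinematics, Kramers limit, filtration, summaries,
# text round-trip.

test_that("generated spectra respect the kinematic endpoint", {
  for (kvp in c(20, 60, 160)) {
    s <- generate_spectrum(tube_config(kvp), xs_tables)
    expect_true(all(s$energies < kvp))
    expect_true(all(s$fluence >= 0))
    expect_gt(sum(s$fluence), 0)
    expect_equal(sum(s$fluence), 1, tolerance = 1e-12)
  }
  expect_error(generate_spectrum(tube_config(10, min_energy = 10),
                                 xs_tables), "min_energy")
})

test_that("pure-Kramers mode matches the closed-form mean by quadrature", {
  cfg <- tube_config(60, target_selffilter_mm = 0, filters = list(),
                     bin_width = 0.1)
  s <- generate_spectrum(cfg, xs_tables, lines = FALSE)
  num <- integrate(function(e) (60 - e), 1, 60)$value
  den <- integrate(function(e) (60 - e) / e, 1, 60)$value
  expect_equal(mean_energy(s), num / den, tolerance = 0.01)
})

test_that("mean energy reduces to the fluence-weighted average", {
  expect_equal(mean_energy(mono_spectrum(50)), 50)
  expect_equal(mean_energy(mono_spectrum(c(20, 40), c(1, 1))), 30)
  expect_error(mean_energy(structure(list(energies = 1, fluence = 0),
                                     class = "xray_spectrum")), "all-zero")
})

test_that("filtering obeys Beer-Lambert and its semigroup property", {
  s <- generate_spectrum(tube_config(80), xs_tables)
  expect_equal(apply_filter(s, "Be", 0, xs_tables)$fluence, s$fluence)
  once2 <- apply_filter(apply_filter(s, "Be", 1, xs_tables), "Be", 1,
                        xs_tables)
  twice <- apply_filter(s, "Be", 2, xs_tables)
  expect_equal(once2$fluence, twice$fluence, tolerance = 1e-12)
  # scalar hand check on a single-bin spectrum
  m <- mono_spectrum(30)
  mu <- mixture_mu(material_water(), 30, "total", xs_tables)$linear
  got <- apply_filter(m, material_water(), 2.5, xs_tables)
  expect_equal(got$fluence, exp(-mu * 0.25))
  # attenuation never increases fluence; hardening raises the mean
  filt <- apply_filter(s, "Be", 5, xs_tables)
  expect_true(all(filt$fluence <= s$fluence + 1e-15))
  expect_gt(mean_energy(filt), mean_energy(s))
})

test_that("mean energy rises strictly with tube potential below the K lines", {
  m <- vapply(c(20, 30, 40, 50, 60),
              function(k) mean_energy(generate_spectrum(tube_config(k),
                                                        xs_tables)), 0)
  expect_true(all(diff(m) > 0))
})

test_that("spectrum text files round-trip and are validated", {
  s <- generate_spectrum(tube_config(40), xs_tables)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, f)
  r <- read_spectrum(f)
  expect_equal(r$energies, s$energies, tolerance = 1e-9)
  expect_equal(r$fluence, s$fluence, tolerance = 1e-9)

  writeLines(c("# c", "10\t1", "20\t-0.5"), f)
  expect_error(read_spectrum(f), "negative fluence")
  writeLines(c("30\t1", "10\t2"), f)
  expect_warning(r2 <- read_spectrum(f), "not sorted")
  expect_equal(r2$energies, c(10, 30))
  writeLines(c("10\t1", "oops"), f)
  expect_error(read_spectrum(f), "line 2")
})
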