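test_that("inositol-phosphate species carry consistent names and formulas", {
  p6 <- insp_species(1:6)
  expect_equal(p6$name, "InsP6")
  expect_equal(p6$formula, c(C = 6, H = 18, O = 24, P = 6))

  p3 <- insp_species(c(4, 2, 6))
  expect_equal(p3$name, "Ins(2,4,6)P3")
  expect_equal(p3$formula[["P"]], 3)

  p1 <- insp_species(2)
  expect_equal(p1$name, "Ins(2)P")
  expect_equal(p1$formula, c(C = 6, H = 13, O = 9, P = 1))

  expect_equal(insp_species(integer(0))$name, "Ins")
  expect_error(insp_species(7), "1..6")
})

test_that("mass additivity: each phosphate adds one HPO3", {
  hpo3 <- monoisotopic_mass(c(H = 1, P = 1, O = 3))
  for (n in 0:5) {
    m_lo <- monoisotopic_mass(insp_species(seq_len(n))$formula)
    m_hi <- monoisotopic_mass(insp_species(seq_len(n + 1))$formula)
    expect_equal(m_hi - m_lo, hpo3, tolerance = 1e-10)
  }
  expect_error(monoisotopic_mass(c(Zn = 1)), "unsupported")
})

test_that("negative-mode m/z values are internally consistent", {
  mz1 <- insp_monoisotopic_mz(1:6, -1)
  mz2 <- insp_monoisotopic_mz(1:6, -2)
  proton <- 1.00727646688
  expect_equal(mz2, (mz1 - proton) / 2, tolerance = 1e-6)
  expect_error(insp_monoisotopic_mz(1:6, 0), "charge")

  # independent element-sum oracle for Ins(2)P as C6H13O9P minus a proton
  masses <- c(C = 12, H = 1.0078250319, O = 15.9949146221, P = 30.97376151)
  oracle <- 6 * masses["C"] + 13 * masses["H"] + 9 * masses["O"] +
    masses["P"] - proton
  expect_equal(insp_monoisotopic_mz(2, -1), unname(oracle),
               tolerance = 1e-9)
})

test_that("dephosphorylation paths honor class terminal products", {
  bpp <- simulate_dephosphorylation("BPP")
  expect_equal(bpp$terminal$name, "Ins(2,4,6)P3")
  expect_equal(bpp$phosphates_released, 3L)

  for (acid in c("HAP", "CP", "PAP")) {
    res <- simulate_dephosphorylation(acid)
    expect_equal(res$terminal$name, "Ins(2)P", info = acid)
    expect_equal(res$phosphates_released, 5L, info = acid)
  }

  # terminal input: no reaction
  noop <- simulate_dephosphorylation("BPP", insp_species(c(2, 4, 6)))
  expect_equal(noop$phosphates_released, 0L)
  expect_length(noop$products, 0L)

  expect_error(simulate_dephosphorylation("BPP", insp_species(integer(0))),
               "no phosphate")
})

test_that("phosphates released plus remaining always equals the start", {
  for (fam in c("BPP", "HAP", "CP", "PAP")) {
    for (start in list(1:6, c(1, 2, 3, 5), c(2, 5))) {
      sp <- insp_species(start)
      res <- simulate_dephosphorylation(fam, sp)
      expect_equal(res$phosphates_released + res$terminal$n_phosphates,
                   sp$n_phosphates, info = fam)
    }
  }
})

test_that("the Michaelis-Menten rate law holds at its landmarks", {
  expect_equal(mm_rate(2, Km = 2, Vmax = 10), 5)
  expect_equal(mm_rate(0, Km = 2, Vmax = 10), 0)
  expect_equal(mm_rate(2e6, Km = 2, Vmax = 10), 10, tolerance = 1e-5)
  expect_error(mm_rate(1, Km = 0, Vmax = 1), "positive")
})

test_that("double-reciprocal fitting recovers noiseless parameters", {
  S <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32)
  v <- mm_rate(S, Km = 2, Vmax = 10)
  f <- fit_lineweaver_burk(S, v)
  expect_equal(f$Km, 2, tolerance = 1e-9)
  expect_equal(f$Vmax, 10, tolerance = 1e-9)

  # property: exact recovery for random positive parameters
  withr::with_seed(11, {
    for (i in 1:8) {
      Km <- runif(1, 0.05, 5); Vmax <- runif(1, 1, 2000)
      S2 <- Km * c(0.2, 0.5, 1, 2, 5, 10)
      f2 <- fit_lineweaver_burk(S2, mm_rate(S2, Km, Vmax))
      expect_equal(f2$Km, Km, tolerance = 1e-9 * Km)
      expect_equal(f2$Vmax, Vmax, tolerance = 1e-9 * Vmax)
    }
  })

  expect_error(fit_lineweaver_burk(c(1, 2, 3), c(1, -1, 2)), "positive")
  expect_error(fit_lineweaver_burk(c(1, 2), c(1, 2)), "3 points")
})

test_that("double-reciprocal and nonlinear fits are both reported and differ under noise", {
  d <- simulate_kinetics_data(Km = 1.5, Vmax = 20,
                              S_grid = c(0.2, 0.5, 1, 2, 4, 8),
                              noise_sd = 1, seed = 9)
  d$v <- pmax(d$v, 0.05)
  lb <- fit_lineweaver_burk(d$S, d$v)
  nl <- fit_mm_nls(d$S, d$v)
  expect_equal(lb$method, "lineweaver-burk")
  expect_equal(nl$method, "nls")
  expect_false(isTRUE(all.equal(lb$Km, nl$Km)))
})

test_that("kcat conversion matches its defining formula", {
  expect_equal(kcat_from_vmax(60, 1000), 1.0)
  expect_equal(kcat_from_vmax(1633.82, 37000), 1007.522, tolerance = 1e-4)
  expect_equal(kcat_from_vmax(2 * 60, 1000), 2.0)  # linear in Vmax
  expect_error(kcat_from_vmax(-1, 1000), "positive")
})

test_that("qPCR abundance is the reference-to-target Cp ratio", {
  expect_equal(qpcr_gene_abundance(20, 25), 0.8)
  expect_equal(qpcr_gene_abundance(25, 25), 1.0)
  expect_equal(qpcr_gene_abundance(18.4, 23.0), 0.8)
  expect_error(qpcr_gene_abundance(0, 5), "positive")
})

test_that("degradation rates derive from the concentration slope per gram", {
  expect_equal(phytate_degradation_rate(c(0, 1), c(2000, 0), 1), 2000)
  expect_equal(phytate_degradation_rate(c(0, 1, 2), c(5, 5, 5), 1), 0)
  expect_equal(
    phytate_degradation_rate(c(0, 1, 2, 3), c(2000, 1800, 1600, 1400), 2),
    100)
  # blank subtraction
  expect_equal(
    phytate_degradation_rate(c(0, 1, 2), c(2000, 1800, 1600), 1,
                             control = list(day = c(0, 1, 2),
                                            concentration = c(2000, 1950,
                                                              1900))),
    150)
  expect_warning(
    r <- phytate_degradation_rate(c(0, 1), c(100, 200), 1), "negative")
  expect_equal(r, 0)
  expect_error(phytate_degradation_rate(1, 100, 1), "2 timepoints")
})
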