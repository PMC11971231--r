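# Direct, indirect and total dose-mean lineal energy assembly.

kin100 <- proton_kinematics(100)
sph1000 <- target_sphere(1000)
LET100 <- 0.744                      # keV/um at 100 MeV, model value
d2_100 <- delta2(5.56, "fitted")

test_that("both spectrum modes reproduce the closed-form yD for untruncated families", {
  cf <- yd_direct_closed_form(f_ion(kin100, 5.56), LET100, d2_100,
                              sph1000$lbar_um)
  for (fam in c("lognormal", "erlang_gamma")) {
    for (mode in c("single", "chord_convolved")) {
      sp <- direct_yd(sph1000, kin100, LET100, d2_100, family = fam,
                      mode = mode)
      expect_lt(abs(sp$yD_dir / cf - 1), 5e-3)
    }
  }
})

test_that("log-normal and gamma-Erlang give practically identical direct yD", {
  a <- direct_yd(sph1000, kin100, LET100, d2_100, "lognormal")
  b <- direct_yd(sph1000, kin100, LET100, d2_100, "erlang_gamma")
  expect_lt(abs(a$yD_dir / b$yD_dir - 1), 1e-3)
})

test_that("spectra are normalized with yF <= yD and yF matching f_ion x LET", {
  for (fam in c("lognormal", "erlang_gamma", "logistic")) {
    sp <- direct_yd(sph1000, kin100, LET100, d2_100, fam)
    expect_true(all(sp$f >= 0))
    norm <- sum(diff(log(sp$y)) * ((sp$f * sp$y)[-1] +
                                   (sp$f * sp$y)[-length(sp$y)]) / 2)
    expect_equal(norm, 1, tolerance = 1e-3)
    expect_lte(sp$yF, sp$yD)
  }
  sp <- direct_yd(sph1000, kin100, LET100, d2_100, "lognormal")
  expect_equal(sp$yF, f_ion(kin100, 5.56) * LET100, tolerance = 1e-3)
})

test_that("truncated logistic direct yD differs from the untruncated families", {
  # strong truncation regime: small site, sizable variance
  sph10 <- target_sphere(10)
  LET <- 0.744; d2 <- delta2(0.180, "fitted")
  a <- direct_yd(sph10, kin100, LET, d2, "lognormal")$yD_dir
  b <- direct_yd(sph10, kin100, LET, d2, "logistic")$yD_dir
  expect_gt(abs(a / b - 1), 0.02)
})

test_that("increasing the straggling factor strictly increases direct yD", {
  y <- vapply(c(0.3, 0.45, 0.6), function(d2)
    direct_yd(sph1000, kin100, LET100, d2, "lognormal")$yD_dir, numeric(1))
  expect_true(all(diff(y) > 0))
})

test_that("indirect yD is the DICS-weighted table average with its contracts", {
  # constant table: weighted mean of a constant is that constant
  tab <- electron_yd_table(c(0.05, 1, 10, 100, 4000), c(10, 1000),
                           matrix(2.5, 5, 2), source = "flat")
  ind <- indirect_yd(wm, kin100, sph1000, tab)
  expect_equal(ind$yD_ind, 2.5, tolerance = 1e-9)
  # linear table vs an independent quadrature oracle
  E_keV <- exp(seq(log(0.05), log(4000), length.out = 200))
  alpha <- 0.02
  tabl <- electron_yd_table(E_keV, c(10, 1000),
                            matrix(alpha * E_keV, 200, 2), source = "linear")
  ind2 <- indirect_yd(wm, kin100, sph1000, tabl)
  E <- exp(seq(log(5.56e3), log(kin100$Emax_eV), length.out = 600))
  w <- dics(wm, kin100, E)$total_sum
  tr <- function(y) sum(diff(log(E)) * (y[-1] + y[-length(y)]) / 2)
  oracle <- tr(alpha * E * 1e-3 * w * E) / tr(w * E)
  expect_lt(abs(ind2$yD_ind / oracle - 1), 5e-3)
  # result stays inside the table's range over the integration window
  expect_gt(ind2$yD_ind, alpha * 5.56)
  expect_lt(ind2$yD_ind, alpha * kin100$Emax_keV)
  # empty integration range is an error, not zero
  tiny <- proton_kinematics(2)       # Emax 4.36 keV < Delta = 5.56 keV
  expect_error(indirect_yd(wm, tiny, sph1000, tab), "range empty")
  # coverage gaps are an error
  short <- electron_yd_table(c(10, 50), c(10, 1000), matrix(1, 2, 2))
  expect_error(indirect_yd(wm, kin100, sph1000, short), "coverage")
})

test_that("total yD is the f_ion-weighted convex combination", {
  dir <- direct_yd(sph1000, kin100, LET100, d2_100, "lognormal")
  tab <- synth_electron_yd_table(7)
  ind <- indirect_yd(wm, kin100, sph1000, tab)
  tot <- total_yd(dir, ind)
  expect_equal(tot$yD_total,
               tot$f_ion * dir$yD_dir + (1 - tot$f_ion) * ind$yD_ind)
  expect_gte(tot$yD_total, min(dir$yD_dir, ind$yD_ind))
  expect_lte(tot$yD_total, max(dir$yD_dir, ind$yD_ind))
  # boundary: all weight on the direct part
  tot1 <- total_yd(dir, ind, f_ion = 1)
  expect_identical(tot1$yD_total, dir$yD_dir)
  # mismatched components rejected
  ind_wrong <- indirect_yd(wm, kin100, target_sphere(100), tab)
  expect_error(total_yd(dir, ind_wrong), "different")
})

test_that("electron table IO round-trips and interpolation is exact at nodes", {
  tab <- synth_electron_yd_table(11)
  p <- tempfile(fileext = ".csv")
  write_electron_yd_table(tab, p)
  back <- read_electron_yd_table(p)
  expect_identical(back$yD, tab$yD)
  expect_identical(back$energy_keV, tab$energy_keV)
  iE <- 7; id <- 2
  expect_equal(interp_electron_yd(tab, tab$energy_keV[iE],
                                  tab$diameter_nm[id]),
               tab$yD[iE, id], tolerance = 1e-12)
  # distinct errors for malformed input
  bad1 <- tempfile(); writeLines("a,b\n1,2", bad1)
  expect_error(read_electron_yd_table(bad1), "malformed")
  expect_error(electron_yd_table(c(2, 1), 10, matrix(1, 2, 1)),
               "increasing")
  expect_error(electron_yd_table(c(1, 2), 10, matrix(c(1, -1), 2, 1)),
               "positive")
})

test_that("synthetic electron tables are seed-reproducible", {
  t1 <- synth_electron_yd_table(5)
  t2 <- synth_electron_yd_table(5)
  t3 <- synth_electron_yd_table(6)
  expect_identical(t1$yD, t2$yD)
  expect_false(identical(t1$yD, t3$yD))
  expect_true(all(t1$yD > 0))
  expect_match(t1$source, "synthetic")
})

test_that("yD(T) curve decreases with energy for the large sphere", {
  tab <- synth_electron_yd_table(3, jitter_sd = 0)   # smooth surface
  cur <- yd_curve(wm, c(2, 10, 50, 200, 1000), sph1000, tab,
                  family = "logistic", delta2_method = "fitted")
  expect_identical(cur$energy_MeV, sort(cur$energy_MeV))
  expect_true(all(diff(cur$yD_total) < 0))
  expect_true(all(cur$f_ion > 0 & cur$f_ion <= 1))
  expect_named(cur, c("energy_MeV", "diameter_nm", "distribution",
                      "f_ion", "yD_dir", "yD_ind", "yD_total"))
})
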