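test_that("sphere carries the canonical cut-offs and exact mean chord", {
  for (i in seq_along(canonical_d_nm)) {
    s <- target_sphere(canonical_d_nm[i])
    expect_identical(s$delta_keV, canonical_deltas[i])
    expect_identical(s$lbar_nm, 2 * canonical_d_nm[i] / 3)
  }
  expect_error(target_sphere(-10), "positive")
  expect_message(s <- target_sphere(50), "interpolated")
  expect_gt(s$delta_keV, 0.180); expect_lt(s$delta_keV, 1.37)
})

test_that("chord distribution has mean 2d/3 and relative variance 1/8", {
  for (d in c(10, 320, 1000)) {
    cd <- chord_distribution(target_sphere(d))
    expect_identical(cd$mean_nm, 2 * d / 3)
    expect_identical(cd$relative_variance, 1 / 8)
    # quadrature cross-check of the closed forms
    l <- seq(1e-6, d, length.out = 20001)
    p <- cd$pdf(l)
    m0 <- sum(diff(l) * (p[-1] + p[-length(p)]) / 2)
    m1 <- sum(diff(l) * ((l * p)[-1] + (l * p)[-length(p)]) / 2)
    m2 <- sum(diff(l) * ((l^2 * p)[-1] + (l^2 * p)[-length(p)]) / 2)
    expect_equal(m0, 1, tolerance = 1e-6)
    expect_equal(m1, 2 * d / 3, tolerance = 1e-6)
    expect_equal(m2 / m1^2 - 1, 0.125, tolerance = 1e-5)
  }
})

test_that("inverse-CDF chord sampler reproduces the mean within 3 SE", {
  d <- 1000
  cd <- chord_distribution(target_sphere(d))
  set.seed(424242)
  l <- cd$sampler(1e6)
  se <- stats::sd(l) / sqrt(length(l))
  expect_lt(abs(mean(l) - 2 * d / 3), 3 * se)
  expect_true(all(l > 0 & l <= d))
})

test_that("closed-form straggling comparators match their printed values", {
  expect_equal(delta2(5.56, "kellerer"), 5.56 / (2 * log(5.56 / 0.078)))
  expect_equal(delta2(5.56, "kellerer"), 0.65157, tolerance = 1e-4)
  expect_equal(delta2(1.37, "xapsos"), 0.23629, tolerance = 1e-4)
  expect_equal(delta2(1.37, "fitted"), 0.0074 + 0.174 * 1.37^0.651)
  expect_error(delta2(0.05, "kellerer"), "Delta > I")
})

test_that("toy 1/eps^2 spectrum recovers the closed-form straggling factor", {
  I_eV <- 78; Emax_eV <- 229e3
  shells <- list(list(B_eV = 0,
                      dsdE = function(E) ifelse(E >= I_eV & E <= Emax_eV,
                                                1 / E^2, 0)))
  for (D in c(0.5, 1.37, 5.56)) {
    expect_equal(delta2_from_spectrum(shells, D),
                 (D - I_eV * 1e-3) / log(D * 1e3 / I_eV),
                 tolerance = 1e-3)
  }
})

test_that("first-principles delta2 sits below Kellerer's and grows with Delta", {
  kin <- proton_kinematics(100)
  d2 <- delta2(canonical_deltas, "rpwba", model = wm, kin = kin)
  expect_true(all(diff(d2) > 0))
  expect_true(all(d2 < delta2(canonical_deltas, "kellerer")))
  expect_true(all(d2 > 0))
  expect_true(all(d2 < canonical_deltas + max(wm$B) * 1e-3))
  expect_error(delta2(10, "rpwba", model = wm, kin = proton_kinematics(2)),
               "Emax")
})

test_that("delta2 varies weakly with proton energy for small spheres", {
  for (D in c(0.180, 1.37)) {
    d2 <- vapply(c(2, 10, 100, 1000), function(T)
      delta2(D, "rpwba", model = wm, kin = proton_kinematics(T)), numeric(1))
    expect_lt((max(d2) - min(d2)) / mean(d2), 0.20)
  }
})

test_that("f_ion honors its boundary, range and monotonicity contracts", {
  kin <- proton_kinematics(100)
  expect_equal(f_ion(kin, kin$Emax_keV), 1)
  expect_equal(f_ion(kin, 1.37), 0.72440, tolerance = 1e-4)
  fi <- f_ion(kin, canonical_deltas)
  expect_true(all(fi > 0 & fi <= 1))
  expect_true(all(diff(fi) > 0))
  expect_error(f_ion(kin, 0), "Delta")
  expect_error(f_ion(kin, kin$Emax_keV * 1.01), "Delta")
})

test_that("variance budget satisfies its identities", {
  sph <- target_sphere(100)
  kin <- proton_kinematics(100)
  vb <- variance_budget(sph, kin, LET_keV_um = 0.75, delta2_keV = 0.22)
  expect_equal(vb$eps_keV, vb$f_ion * 0.75 * sph$lbar_um)
  expect_equal(vb$Vdelta * vb$eps_keV, 0.22)
  expect_equal(vb$V, 0.125 + vb$Vdelta)
  # degenerate straggling: V collapses to the chord term alone
  vb0 <- variance_budget(sph, kin, 0.75, 0)
  expect_identical(vb0$V, 0.125)
  # smaller spheres: straggling variance share grows
  vb10 <- variance_budget(target_sphere(10), kin, 0.75,
                          delta2(0.180, "fitted"))
  vb1000 <- variance_budget(target_sphere(1000), kin, 0.75,
                            delta2(5.56, "fitted"))
  expect_gt(vb10$Vdelta, vb1000$Vdelta)
})

test_that("straggling families satisfy their parameter identities", {
  eps <- 0.8; V <- 0.4
  g <- make_straggling_distribution("erlang_gamma", eps, V)
  expect_equal(unname(g$params["kappa"] / g$params["lambda"]), eps)
  expect_equal(unname(g$params["kappa"] / g$params["lambda"]^2), V * eps^2)
  lg <- make_straggling_distribution("logistic", eps, V)
  expect_equal(unname(pi^2 * lg$params["s"]^2 / 3), V * eps^2)
  ln <- make_straggling_distribution("lognormal", 1, 0.5)
  mom <- straggling_moments(ln)
  expect_equal(mom$m1, 1, tolerance = 1e-4)
  expect_equal(mom$relvar, 0.5, tolerance = 1e-3)
  expect_error(make_straggling_distribution("lognormal", -1, 0.5))
})

test_that("gamma density with integer shape reproduces the Erlang factorial form", {
  eps <- 2; V <- 0.25          # kappa = 4, an integer
  g <- make_straggling_distribution("erlang_gamma", eps, V)
  lam <- unname(g$params["lambda"]); kap <- unname(g$params["kappa"])
  x <- seq(0.01, 8, length.out = 200)
  erlang <- lam^kap / factorial(kap - 1) * x^(kap - 1) * exp(-lam * x)
  expect_equal(g$d(x), erlang, tolerance = 1e-12)
})

test_that("truncated logistic renormalizes and keeps positive support", {
  lg <- make_straggling_distribution("logistic", 0.3, 1.2)  # heavy truncation
  expect_gt(lg$trunc_mass, 0.05)
  x <- seq(0, 5, length.out = 40000)
  f <- lg$d(x)
  expect_true(all(f >= 0))
  expect_identical(lg$d(-0.1), 0)
  Z <- sum(diff(x) * (f[-1] + f[-length(f)]) / 2)
  expect_equal(Z, 1, tolerance = 1e-3)
  # truncated mean exceeds the untruncated target
  mom <- straggling_moments(lg)
  expect_gt(mom$m1, 0.3)
})
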