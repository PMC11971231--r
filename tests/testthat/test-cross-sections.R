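test_that("proton kinematics reproduce the exact maximum delta-electron energy", {
  expect_error(proton_kinematics(0), "positive")
  expect_error(proton_kinematics(-5), "positive")
  # T equal to the proton rest energy: gamma = 2, beta^2 gamma^2 = 3
  k <- proton_kinematics(938.272)
  expect_equal(k$gamma, 2)
  expect_equal(k$Emax_keV, 3059.3, tolerance = 1e-4)
  k100 <- proton_kinematics(100)
  expect_equal(k100$Emax_keV, 229.18, tolerance = 1e-4)
  # the 2 m c^2 beta^2 gamma^2 approximation always exceeds the exact value
  expect_gt(k100$Emax_approx_keV, k100$Emax_keV)
  # T -> 0+: Emax -> 0
  expect_lt(proton_kinematics(1e-6)$Emax_keV, 1e-5)
})

test_that("recoil limits collapse at W = T and are positive and ordered", {
  kin <- proton_kinematics(1)
  rl <- recoil_limits(kin, kin$T_eV)
  expect_equal(rl$q_min_eV, rl$q_max_eV, tolerance = 1e-9)
  W <- c(1e-3, 1, 100, 1e4, 1e5)
  rl <- recoil_limits(kin, W)
  expect_true(all(rl$q_min_eV > 0))
  expect_true(all(rl$q_min_eV <= rl$q_max_eV))
  expect_error(recoil_limits(kin, kin$T_eV * 1.01), "closed")
})

test_that("relativistic recoil minimum matches its series expansion", {
  # second-order Taylor of the outgoing momentum in W, evaluated through
  # the same stable q(x) map: agreement to much better than 0.1%
  kin <- proton_kinematics(1)
  mc2 <- 0.511e6; Mc2 <- 938.272e6
  T <- kin$T_eV; W <- 100
  pc <- sqrt(T * (T + 2 * Mc2))
  x_series <- W * (T + Mc2) / pc + W^2 / 2 * Mc2^2 / pc^3
  q_series <- x_series^2 / (sqrt(x_series^2 + mc2^2) + mc2)
  rl <- recoil_limits(kin, W)
  expect_equal(rl$q_min_eV, q_series, tolerance = 1e-3)
})

test_that("closed shells contribute exactly zero to the DICS", {
  kin <- proton_kinematics(2)          # Emax = 4.36 keV
  v <- dics(wm, kin, c(1e3, kin$Emax_eV))  # second point closes every shell
  expect_true(all(v$total[2, ] == 0))
  # per-shell closure at E = Emax - B + 1
  for (j in seq_along(colnames(v$total))) {
    B <- wm$B[wm$kind == "ionization"][j]
    vj <- dics(wm, kin, kin$Emax_eV - B + 1)
    expect_identical(unname(vj$total[1, j]), 0)
  }
  expect_error(dics(wm, kin, -1), ">= 0")
})

test_that("DICS is non-negative and the transverse term vanishes at low velocity", {
  kin <- proton_kinematics(10)
  E <- exp(seq(log(0.1), log(8e3), length.out = 40))
  v <- dics(wm, kin, E)
  expect_true(all(v$long >= 0) && all(v$trans >= 0))
  # low-velocity limit: {ln(1/(1-b^2)) - b^2} ~ b^4/2, so at 1 MeV the
  # transverse share is far below a percent
  k1 <- proton_kinematics(1)
  v1 <- dics(wm, k1, c(10, 100, 1000))
  expect_lt(max(rowSums(v1$trans) / rowSums(v1$total)), 1e-2)
})

test_that("secondary-electron spectrum follows an inverse-square pattern", {
  kin <- proton_kinematics(10)
  v <- dics(wm, kin, c(1e3, 4e3))
  ratio <- v$total_sum[1] / v$total_sum[2]
  expect_lt(abs(ratio / 16 - 1), 0.25)
})

test_that("stopping power decreases over 1 MeV-1 GeV and warns outside", {
  sp <- vapply(c(1, 10, 100, 1000), function(T) stopping_power(wm, T),
               numeric(1))
  expect_true(all(diff(sp) < 0))
  expect_gt(sp[1], 20)               # tens of keV/um at 1 MeV
  expect_lt(sp[4], 0.3)              # fraction of keV/um at 1 GeV
  expect_warning(stopping_power(wm, 0.5), "extrapolated")
})

test_that("stopping-power quadrature is converged and scheme-independent", {
  s1 <- stopping_power(wm, 100, density = 1)
  s2 <- stopping_power(wm, 100, density = 2)
  expect_lt(abs(s1 / s2 - 1), 1e-3)
  sa <- stopping_power(wm, 100, method = "adaptive")
  expect_lt(abs(s1 / sa - 1), 5e-3)
})

test_that("transverse share of the stopping power grows with energy", {
  fr <- vapply(c(100, 300, 1000), function(T) {
    sp <- stopping_power(wm, T, parts = TRUE)
    p <- attr(sp, "parts")
    p[["transverse"]] / sum(p)
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("stopping-power reference comparison reads the documented CSV contract", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("# toy reference", "energy_MeV,stopping_power_MeV_cm2_g",
               "10,45.0", "100,7.5"), tmp)
  cmp <- compare_stopping_power(wm, tmp)
  expect_equal(cmp$sp_ref_keV_um, c(4.5, 0.75))
  expect_true(all(is.finite(cmp$rel_dev)))
  bad <- tempfile(fileext = ".csv")
  writeLines("energy,sp\n1,2", bad)
  expect_error(compare_stopping_power(wm, bad), "columns")
})
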