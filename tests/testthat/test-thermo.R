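test_that("solid-solution lattice energy reproduces hand-evaluated cases", {
  a <- energy_accounting(-400, -90, 0, 4, 4, 0)
  expect_equal(lattice_energy_ss(a), -10)
  b <- energy_accounting(-390, -90, -80, 4, 3, 1)
  expect_equal(lattice_energy_ss(b), (-390 + 3 * 90 + 80) / 4)  # -10
  c0 <- energy_accounting(-120, 0, 0, 4, 2, 2)
  expect_equal(lattice_energy_ss(c0), -30)
  expect_error(energy_accounting(-1, 0, 0, 4, 2, 1), "N_h \\+ N_g")
})

test_that("lattice energy is invariant under supercell replication", {
  a1 <- energy_accounting(-390, -90, -80, 4, 3, 1)
  a2 <- energy_accounting(-780, -90, -80, 8, 6, 2)
  expect_equal(lattice_energy_ss(a1), lattice_energy_ss(a2))
})

test_that("kcal inputs are converted to kJ at construction", {
  a <- energy_accounting(-100, 0, 0, 4, 4, 0, unit = "kcal")
  expect_equal(lattice_energy_ss(a), -100 * 4.184 / 4)
})

test_that("ideal mixing entropy has the closed-form values and symmetry", {
  R <- 8.314462618
  expect_equal(mixing_entropy(0.5), R * log(2), tolerance = 1e-12)
  expect_equal(mixing_entropy(0.5), 5.763146, tolerance = 1e-6)
  expect_equal(mixing_entropy(0.25),
               -R * (0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(mixing_entropy(0), 0)
  expect_equal(mixing_entropy(1), 0)
  x <- seq(0, 1, by = 0.05)
  expect_equal(mixing_entropy(x), mixing_entropy(1 - x), tolerance = 1e-12)
  expect_true(all(mixing_entropy(x) >= 0))
  expect_equal(which.max(mixing_entropy(x)), which(x == 0.5))
})

test_that("cubic vibrational trendline interpolates and matches normal equations", {
  x <- c(0, 0.25, 0.5, 0.75, 1)
  truth <- function(x) 1.2 - 0.8 * x + 0.3 * x^2 + 2.1 * x^3
  fit <- vib_trendline(x, truth(x))
  expect_equal(fit$coef, c(1.2, -0.8, 0.3, 2.1), tolerance = 1e-9)
  expect_equal(predict(fit, 0.33), truth(0.33), tolerance = 1e-9)
  cfit <- vib_trendline(x, rep(2.5, 5))
  expect_equal(predict(cfit, c(0.1, 0.9)), c(2.5, 2.5), tolerance = 1e-9)
  ## noisy samples: residuals equal the explicit normal-equations solution
  set.seed(1)
  xn <- seq(0, 1, length.out = 9)
  y <- truth(xn) + rnorm(9, sd = 0.3)
  fitn <- vib_trendline(xn, y)
  X <- cbind(1, xn, xn^2, xn^3)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fitn$residuals), as.numeric(y - X %*% beta),
               tolerance = 1e-8)
  expect_error(vib_trendline(c(0, 0.5, 1), c(1, 2, 3)), ">= 4")
})

test_that("free-energy curve assembles G = E + F - T dS", {
  lat <- data.frame(x_g = c(0, 0.5, 1), E_latt = c(-10, -8, -6))
  cv <- free_energy_curve(lat, NULL, T = 300)
  expect_equal(cv$G[cv$x_g == 0], -10)           # no entropy at endpoints
  expect_equal(cv$G[cv$x_g == 1], -6)
  expect_equal(cv$G[cv$x_g == 0.5],
               -8 - 300 * 8.314462618 * log(2) / 1000, tolerance = 1e-9)
  ## zero lattice and vibrational terms leave only the mixing term
  cv0 <- free_energy_curve(data.frame(x_g = c(0, 0.5), E_latt = c(0, 0)),
                           T = 300)
  expect_equal(cv0$G[cv0$x_g == 0.5], -1.728944, tolerance = 1e-6)
  ## entropy can only lower G
  expect_true(all(cv$G <= cv$E_latt + 1e-12))
  expect_error(free_energy_curve(lat, T = -5), "> 0")
  expect_error(free_energy_curve(data.frame(x_g = 0.5, E_latt = 1)),
               ">= 2 compositions")
})

test_that("physical mixture line interpolates linearly", {
  line <- mixture_line(-10, -6)
  expect_equal(physical_mixture(line, 0), -10)
  expect_equal(physical_mixture(line, 1), -6)
  expect_equal(physical_mixture(line, 0.5), -8)
  expect_equal(physical_mixture(line, 0.3), -8.8)
  expect_error(physical_mixture(line, 1.5), "\\[0, 1\\]")
})

test_that("stability classification applies the 2RT threshold", {
  lat <- data.frame(x_g = c(0, 0.25, 0.5, 1), E_latt = c(-10, -9, -8, -6))
  cv <- free_energy_curve(lat, T = 300)
  line <- mixture_line(cv$G[1], cv$G[4])
  v0 <- classify_stability(cv, line)
  expect_equal(attr(v0, "threshold"), 2 * 8.314462618e-3 * 300,
               tolerance = 1e-12)          # ~4.99 kJ/mol
  ## identical curve and line at the endpoints -> stable there
  expect_equal(v0$class[v0$x_g %in% c(0, 1)], c("stable", "stable"))
  ## shifted curves
  shift <- function(d) {
    cv2 <- cv; cv2$G <- physical_mixture(line, cv$x_g) + d
    classify_stability(cv2, line)$class
  }
  expect_true(all(shift(0) == "stable"))
  expect_true(all(shift(3) == "metastable_accessible"))
  expect_true(all(shift(10) == "inaccessible"))
  ## polymorph-gap report
  cv3 <- cv; cv3$G <- physical_mixture(line, cv$x_g) + c(0.5, 0.5, 3, 3)
  v3 <- classify_stability(cv3, line, polymorph_gap = 2)
  expect_equal(v3$below_gap, c(TRUE, TRUE, FALSE, FALSE))
})
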