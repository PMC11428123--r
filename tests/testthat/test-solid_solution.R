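test_that("self-substitution aligns exactly and updates bookkeeping", {
  st <- beta_fixture()
  sc <- build_supercell(st, c(3, 3, 1))
  g <- purine_template("guanine")
  ss <- substitute_site(sc, 1, g)
  expect_lt(ss$base$molecules[[1]]$align_rmsd, 1e-9)
  expect_equal(ss$N_g, 0L)           # guanine onto guanine is still host
  h <- purine_template("hypoxanthine")
  ss <- substitute_site(sc, 5, h)
  expect_equal(ss$N_g, 1L)
  expect_equal(ss$N_h, 35L)
  expect_equal(ss$N_cell, 36L)
  ss2 <- substitute_site(ss, 7, h)
  expect_equal(ss2$N_g, 2L)
  expect_equal(ss2$N_h, 34L)
  expect_error(substitute_site(sc, 99, h), "out of range")
})

test_that("substitution matches an independent rigid-superposition oracle", {
  skip_if_not_installed("bio3d")
  st <- beta_fixture()
  sc <- build_supercell(st, c(2, 1, 1))
  h <- purine_template("hypoxanthine")
  ss <- substitute_site(sc, 3, h)
  mol <- sc$molecules[[3]]
  shared <- intersect(names(mol$scaffold), names(h$scaffold))
  Xh <- frac_to_cart(sc$cell, mol$frac[mol$scaffold[shared], ])
  Xg <- h$xyz[h$scaffold[shared], ]
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(Xh)), mobile = as.numeric(t(Xg)),
                   fixed.inds = 1:30, mobile.inds = 1:30))
  oracle_rmsd <- bio3d::rmsd(as.numeric(t(Xh)), fit)
  placed <- frac_to_cart(ss$base$cell,
                         ss$base$molecules[[3]]$frac[h$scaffold[shared], ])
  got_rmsd <- sqrt(mean(rowSums((placed - Xh)^2)))
  expect_equal(got_rmsd, oracle_rmsd, tolerance = 1e-6)
})

test_that("kabsch recovers a known rigid transform", {
  set.seed(5)
  P <- matrix(rnorm(30), 10, 3)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  Q <- P %*% t(R) + matrix(rep(c(1, -2, 3), each = 10), 10, 3)
  fit <- kabsch(P, Q)
  expect_lt(fit$rmsd, 1e-12)
  expect_equal(fit$R, R, tolerance = 1e-10)
})

test_that("substitution alignment-quality and compatibility errors fire", {
  st <- beta_fixture()
  sc <- build_supercell(st, c(1, 1, 1))
  ## guest sharing no scaffold labels
  alien <- molecule_template("toy", "none", rep("C", 3),
                             rbind(c(0, 0, 0), c(1.4, 0, 0), c(0, 1.4, 0)),
                             scaffold = stats::setNames(1:3, c("Q1", "Q2", "Q3")))
  expect_error(substitute_site(sc, 1, alien), "share no scaffold")
  ## distorted guest exceeds the RMSD gate
  g <- purine_template("guanine")
  gbad <- molecule_template("guanine", "keto-N9H", g$elements,
                            g$xyz %*% diag(c(2, 0.5, 1)), scaffold = g$scaffold)
  expect_error(substitute_site(sc, 1, gbad, rmsd_max = 0.3),
               "alignment quality")
})

test_that("mole fraction is exact rational bookkeeping", {
  st <- beta_fixture()
  sc <- build_supercell(st, c(3, 3, 1))
  ss <- substitute_site(sc, 17, purine_template("hypoxanthine"))
  expect_identical(mole_fraction(ss)$x_g, 1 / 36)
  expect_equal(mole_fraction(xtalgrow:::.as_solid_solution(sc))$x_g, 0)
  expect_error(composition(1.2), "\\[0, 1\\]")
})

test_that("configuration enumeration matches exhaustive pattern counting", {
  toy <- simple_p1_purine()
  h <- purine_template("hypoxanthine")
  cases <- list(c(4, 1, 1, 2), c(2, 2, 1, 2), c(3, 1, 1, 1), c(2, 2, 1, 3))
  for (cs in cases) {
    sc <- build_supercell(toy, cs[1:3])
    ens <- enumerate_configurations(sc, h, cs[4], max_members = 500)
    expect_equal(ens$n_patterns, brute_force_patterns(cs[1:3], 1L, cs[4]),
                 info = paste(cs, collapse = "x"))
  }
})

test_that("enumeration endpoints and stoichiometry invariants hold", {
  toy <- simple_p1_purine()
  sc <- build_supercell(toy, c(4, 1, 1))
  h <- purine_template("hypoxanthine")
  e0 <- enumerate_configurations(sc, h, 0)
  expect_length(e0$members, 1)
  expect_equal(e0$members[[1]]$N_g, 0L)
  eN <- enumerate_configurations(sc, h, 4)
  expect_length(eN$members, 1)
  expect_equal(mole_fraction(eN$members[[1]])$x_g, 1)
  e2 <- enumerate_configurations(sc, h, 2)
  expect_true(all(vapply(e2$members, function(m) m$N_g, integer(1)) == 2L))
  expect_true(all(vapply(e2$members, function(m) m$N_cell, integer(1)) == 4L))
  expect_error(enumerate_configurations(sc, h, 9), "out of range")
})

test_that("axis permutation adds equal-volume supercell shapes", {
  toy <- simple_p1_purine()
  sc <- build_supercell(toy, c(2, 1, 1))
  h <- purine_template("hypoxanthine")
  ens <- enumerate_configurations(sc, h, 1, permute_axes = TRUE)
  expect_setequal(unique(ens$provenance$shape), c("2x1x1", "1x2x1"))
})

test_that("substituting the host back restores the occupancy labels", {
  st <- beta_fixture()
  sc <- build_supercell(st, c(2, 1, 1))
  h <- purine_template("hypoxanthine")
  g <- purine_template("guanine")
  ss <- substitute_site(sc, 2, h)
  back <- substitute_site(ss, 2, g)
  expect_equal(back$occupants, xtalgrow:::.as_solid_solution(sc)$occupants)
  expect_equal(back$N_g, 0L)
})
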