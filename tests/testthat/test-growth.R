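RKJ <- 8.314462618e-3

## tiny graph: frozen occupied anchor -- focal site -- frozen empty vent,
## so the focal site stays a surface site in both states
logistic_run <- function(U, iters = 3e5, seed = 42, T = 300) {
  nbr <- matrix(c(2L, 0L,
                  1L, 3L,
                  2L, 0L), 3, 2, byrow = TRUE)
  typ <- matrix(1L, 3, 2)
  set.seed(seed)
  res <- xtalgrow:::.run_growth_raw(nbr, typ, matrix(U, 1, 2), 1 / (RKJ * T),
                                    dmu0 = 0, descent_start = 1,
                                    equilibrium_iter = 2, total_iter = iters,
                                    init_sites = 1L,
                                    frozen = c(TRUE, FALSE, TRUE),
                                    measure_from = iters / 10,
                                    check_connectivity = FALSE)
  res$occ_frac[2]
}

test_that("single-site occupancy matches the analytic logistic equilibrium", {
  beta <- 1 / (RKJ * 300)
  for (U in c(-4, -2, 0, 1, 3)) {
    p <- exp(beta * U) / (1 + exp(beta * U))
    got <- logistic_run(U)
    ## 3 sigma with a conservative effective sample size (autocorrelation)
    n_eff <- (3e5 - 3e4) / 50
    expect_lt(abs(got - p), max(3 * sqrt(p * (1 - p) / n_eff), 0.01),
              label = sprintf("U = %g: got %.4f expected %.4f", U, got, p))
  }
})

test_that("trajectories are reproducible under a fixed seed and diverge across seeds", {
  st <- make_toy_structure()
  tab <- make_interaction_table(st, "vacuum")
  cfg <- growth_config(preset = "desk", total_iterations = 2e4, seed = 3,
                       dims = c(16, 10, 12))
  s1 <- run_growth(tab, st, cfg)
  s2 <- run_growth(tab, st, cfg)
  expect_identical(s1$occ, s2$occ)
  expect_identical(s1$trace, s2$trace)
  cfg$seed <- 4
  s3 <- run_growth(tab, st, cfg)
  expect_false(identical(s1$occ, s3$occ))
})

test_that("driving force schedule follows the printed protocol", {
  cfg <- growth_config()                      # reference preset
  expect_equal(cfg$total_iterations, 1e6)
  expect_equal(schedule_driving_force(cfg, 0), 100 * 4.184)
  expect_equal(schedule_driving_force(cfg, 499999), 418.4)
  expect_equal(schedule_driving_force(cfg, 550000), 418.4 / 2)
  expect_equal(schedule_driving_force(cfg, 600000), 0)
  expect_equal(schedule_driving_force(cfg, 1e6), 0)
  it <- seq(0, 1e6, by = 5e4)
  expect_true(all(diff(schedule_driving_force(cfg, it)) <= 0))
  expect_error(schedule_driving_force(cfg, -1), "out of range")
  expect_error(schedule_driving_force(cfg, 2e6), "out of range")
  expect_error(growth_config(descent_start = 7e5, equilibrium_iter = 6e5),
               "descent_start")
})

test_that("isotropic interactions on a cubic lattice grow isotropic crystals", {
  st <- make_toy_structure(motif = "cubic")
  cont <- enumerate_neighbors(st, 4.1)
  tab <- classify_unique(cont, st)
  tab <- assemble_dg_cryst(tab, dg_vacuum = rep(10, nrow(tab)))
  asp <- replicate(10, NA_real_)
  for (r in 1:10) {
    cfg <- growth_config(preset = "desk", total_iterations = 3e4, seed = 100 + r,
                         dims = c(20, 20, 20), dmu_initial = 10,
                         dmu_unit = "kJ", nucleus = 4, frozen_nucleus = TRUE)
    stt <- run_growth(tab, st, cfg, cutoff = 4.1)
    m <- morphology_metrics(stt)
    asp[r] <- m$aspect[["ab"]]
  }
  expect_lt(abs(mean(asp) - 1), 0.1)
})

test_that("a crystal equilibrated at zero driving force shows no net drift", {
  ## anchored crystal at the kink-referenced equilibrium bias: after a
  ## burn-in the chain is stationary, so the size drift over a further
  ## 1e5 cycles is statistically zero
  st <- make_toy_structure(motif = "cubic")
  cont <- enumerate_neighbors(st, 4.1)
  ctab <- classify_unique(cont, st)
  ct <- attr(ctab, "contact_type")
  tab <- assemble_dg_cryst(ctab, dg_vacuum = rep(10, nrow(ctab)))
  dims <- c(16L, 16L, 16L)
  lat <- xtalgrow:::.growth_lattice(st, cont, ct, dims)
  inside <- function(p, w) all(p >= 8 - w & p <= 7 + w)
  core <- which(apply(lat$site_frac, 1, inside, w = 3))   # 6^3 anchor
  frozen <- rep(FALSE, lat$n); frozen[core] <- TRUE
  dg <- cbind(tab$dg_cryst, tab$dg_cryst)
  beta <- 1 / (8.314462618e-3 * 300)
  U_kink <- sum(tabulate(ct[cont$i == 1], nbins = nrow(ctab)) *
                  tab$dg_cryst) / 2
  drifts <- vapply(1:8, function(r) {
    set.seed(600 + r)
    res <- xtalgrow:::.run_growth_raw(lat$nbr, lat$type, dg, beta,
                                      dmu0 = 0, dmu_offset = -U_kink,
                                      descent_start = 1, equilibrium_iter = 2,
                                      total_iter = 3e5, init_sites = core,
                                      frozen = frozen,
                                      record_every = 1e4, measure_from = 0)
    sizes <- res$trace_size
    its <- res$trace_iter
    sizes[its == 3e5] - sizes[its == 2e5]
  }, numeric(1))
  if (stats::sd(drifts) == 0) {
    expect_equal(mean(drifts), 0)
  } else {
    expect_gt(stats::t.test(drifts)$p.value, 0.01)
  }
})

test_that("the grown crystal remains a single connected component", {
  st <- make_toy_structure()
  tab <- make_interaction_table(st, "water")
  cfg <- growth_config(preset = "desk", total_iterations = 3e4, seed = 9,
                       dims = c(16, 10, 12))
  s <- run_growth(tab, st, cfg)
  occ <- which(s$occ > 0)
  expect_gt(length(occ), 10)
  ## BFS over the occupied subgraph
  adj <- new.env(hash = TRUE)
  lat <- xtalgrow:::.growth_lattice(st, s$contacts, s$contact_type, s$dims)
  visited <- integer(0)
  queue <- occ[1]
  occset <- rep(FALSE, length(s$occ)); occset[occ] <- TRUE
  seen <- rep(FALSE, length(s$occ)); seen[occ[1]] <- TRUE
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nb <- lat$nbr[u, ]; nb <- nb[nb > 0]
    new <- nb[occset[nb] & !seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  expect_equal(sum(seen), length(occ))
})

test_that("guest occupancy mode deposits guests at the configured rate", {
  st <- make_toy_structure()
  tab <- make_interaction_table(st, "water")
  ## strong sustained driving force: the crystal grows well past the seed
  cfg <- growth_config(total_iterations = 4e4, descent_start = 3e4,
                       equilibrium_iter = 3.5e4, dmu_initial = 20,
                       dmu_unit = "kJ", seed = 12, guest_fraction = 0.3,
                       dims = c(20, 12, 14), nucleus = 3,
                       frozen_nucleus = TRUE)
  s <- run_growth(list(host = tab, guest = tab), st, cfg)
  n <- sum(s$occ > 0)
  expect_gt(n, 1000)
  ## the frozen all-host seed (27 sites) never re-samples its species
  frac <- sum(s$occ == 2) / (n - 27)
  expect_lt(abs(frac - 0.3), 0.08)
})

test_that("degenerate configurations raise the documented errors", {
  st <- make_toy_structure()
  tab <- make_interaction_table(st, "vacuum")
  expect_error(run_growth(tab[0, ], st, growth_config(preset = "desk")),
               "empty interaction table")
  zero <- tab; zero$dg_cryst <- 0
  expect_warning(
    run_growth(zero, st, growth_config(preset = "desk",
                                       total_iterations = 2000,
                                       descent_start = 500,
                                       equilibrium_iter = 600,
                                       dmu_initial = 0, dmu_unit = "kJ",
                                       dims = c(8, 8, 8))),
    "random walk")
})
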