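test_that("the layered toy structure exposes the documented contact motif", {
  st <- make_toy_structure()
  tab <- make_interaction_table(st, "vacuum")
  labs <- rep(tab$label, tab$multiplicity)
  expect_equal(sum(labs == "pi-stack"), 2L)
  expect_equal(sum(labs == "3H-bond"), 2L)
  expect_equal(sum(labs == "2H-bond"), 2L)
  expect_equal(make_toy_structure(motif = "cubic")$Z, 1L)
})

test_that("structure generators are deterministic", {
  f1 <- tempfile(fileext = ".cif"); f2 <- tempfile(fileext = ".cif")
  write_cif(make_toy_structure(), f1)
  write_cif(make_toy_structure(), f2)
  expect_identical(readLines(f1), readLines(f2))
  write_cif(synth_beta_guanine(), f1)
  write_cif(synth_beta_guanine(), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("overlapping motifs are rejected", {
  expect_error(synth_beta_guanine(params = list(a = 0.8)), "overlap")
})

test_that("packaged fixture matches the generator and documents synthesis", {
  path <- system.file("extdata", "beta-guanine-synthetic.cif",
                      package = "xtalgrow")
  expect_true(grepl("SYNTHETIC", readLines(path)[1]))
  st <- read_cif(path)
  gen <- synth_beta_guanine()
  expect_equal(st$Z, gen$Z)
  expect_equal(st$cell$a, gen$cell$a, tolerance = 1e-6)
})

test_that("interaction tables respect the documented orderings", {
  st <- beta_fixture()
  pick <- function(tab, lab) tab$dg_cryst[tab$label == lab][1]
  vac <- make_interaction_table(st, "vacuum")
  expect_equal(vac$dg_cryst, vac$dg_vacuum)          # vacuum limit
  expect_gt(pick(vac, "3H-bond"), pick(vac, "2H-bond"))
  expect_gt(pick(vac, "2H-bond"), pick(vac, "pi-stack"))
  wat <- make_interaction_table(st, "water")
  expect_gt(pick(wat, "pi-stack"), pick(vac, "pi-stack"))  # strengthened
  expect_lt(pick(wat, "3H-bond"), pick(vac, "3H-bond"))    # weakened
  wat_hpx <- make_interaction_table(st, "water", "hpx")
  expect_lt(pick(wat_hpx, "3H-bond"), pick(wat_hpx, "pi-stack"))
  tol <- make_interaction_table(st, "toluene")
  expect_lt(pick(tol, "pi-stack"), 0)                # prefers to dissolve
  ## dG identity holds everywhere
  for (tab in list(vac, wat, wat_hpx, tol))
    expect_equal(tab$dg_cryst, tab$dg_vacuum - tab$dg_desolv,
                 tolerance = 1e-9)
})

test_that("identity guest perturbation leaves tables unchanged", {
  st <- beta_fixture()
  a <- make_interaction_table(st, "water")
  b <- make_interaction_table(st, "water", guest_perturbation("none"))
  expect_equal(a$dg_cryst, b$dg_cryst)
  expect_error(solvent_profile("synthetic"), "named offsets")
})

test_that("pairwise supercell energies are extensive", {
  st <- beta_fixture()
  model <- pairwise_energy_model()
  e1 <- lattice_energy_ss(supercell_energy(model, build_supercell(st, c(1, 1, 1))))
  e2 <- lattice_energy_ss(supercell_energy(model, build_supercell(st, c(2, 1, 1))))
  e3 <- lattice_energy_ss(supercell_energy(model, build_supercell(st, c(2, 2, 1))))
  expect_equal(e1, e2, tolerance = 1e-9)
  expect_equal(e1, e3, tolerance = 1e-9)
  zero <- pairwise_energy_model(depths = c("pi-stack" = 0, "3H-bond" = 0,
                                           "2H-bond" = 0, "pi-other" = 0,
                                           other = 0),
                                guest_penalty = c("pi-stack" = 0,
                                                  "3H-bond" = 0,
                                                  "2H-bond" = 0,
                                                  "pi-other" = 0, other = 0))
  expect_equal(lattice_energy_ss(supercell_energy(zero, build_supercell(st, c(1, 1, 1)))), 0)
})

test_that("injected per-guest penalties are recovered from lattice energies", {
  st <- beta_fixture()
  sc <- build_supercell(st, c(2, 2, 1))        # 16 sites
  model <- pairwise_energy_model()
  contacts <- supercell_contacts(sc, model$cutoff)
  h <- purine_template("hypoxanthine")
  ## injected penalty per guest molecule: sum over its contacts
  cls_counts <- table(c(contacts$class, contacts$class)) / sc$Z
  delta_true <- sum(model$guest_penalty[names(cls_counts)] * cls_counts)
  xg <- 0:10 / 16
  E <- vapply(0:10, function(ng) {
    ens <- enumerate_configurations(sc, h, ng, max_members = 4, seed = 2)
    min(vapply(ens$members, function(m)
      lattice_energy_ss(supercell_energy(model, m, contacts)), numeric(1)))
  }, numeric(1))
  slope <- coef(lm(E ~ xg))[2]
  expect_lt(abs(slope - delta_true) / delta_true, 0.05)
})

test_that("the xan-like guest doubles the hpx-like lattice-energy slope", {
  mh <- pairwise_energy_model(guest_kind = "hpx")
  mx <- pairwise_energy_model(guest_kind = "xan")
  expect_equal(unname(mx$guest_penalty / mh$guest_penalty)[-1], rep(2, 4))
  expect_equal(mx$phase_advantage, 2 * mh$phase_advantage)
})

test_that("guest-weakened 3H makes lattice energy increase with composition", {
  st <- beta_fixture()
  sc <- build_supercell(st, c(1, 1, 1))
  model <- pairwise_energy_model()
  contacts <- supercell_contacts(sc, model$cutoff)
  h <- purine_template("hypoxanthine")
  E <- vapply(0:4, function(ng) {
    ens <- enumerate_configurations(sc, h, ng, max_members = 2, seed = 1)
    min(vapply(ens$members, function(m)
      lattice_energy_ss(supercell_energy(model, m, contacts)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(E) > 0))
})
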