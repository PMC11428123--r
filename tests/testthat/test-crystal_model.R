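test_that("unit cell validates parameters and computes volume", {
  cell <- unit_cell(3.55, 9.7, 16.3, beta = 96)
  expect_equal(cell_volume(cell),
               3.55 * 9.7 * 16.3 * sin(96 * pi / 180), tolerance = 1e-12)
  expect_error(unit_cell(-1, 2, 3), "positive")
  expect_error(unit_cell(1, 2, 3, alpha = 0), "angles")
  expect_error(unit_cell(1, 2, 3, alpha = 181), "angles")
})

test_that("d-spacing follows the reciprocal metric", {
  cub <- unit_cell(10, 10, 10)
  expect_equal(d_spacing(cub, c(1, 0, 0)), 10)
  expect_equal(d_spacing(cub, c(2, 0, 0)), 5)
  ## independent reciprocal-basis construction for a monoclinic cell
  mc <- unit_cell(3.5, 9, 12, beta = 100)
  M <- cell_matrix(mc)
  V <- cell_volume(mc)
  astar <- .cross3(M[, 2], M[, 3]) / V
  bstar <- .cross3(M[, 3], M[, 1]) / V
  cstar <- .cross3(M[, 1], M[, 2]) / V
  for (hkl in list(c(1, 0, 0), c(0, 2, 1), c(1, -2, 3), c(2, 2, 2))) {
    g <- hkl[1] * astar + hkl[2] * bstar + hkl[3] * cstar
    expect_equal(d_spacing(mc, hkl), 1 / sqrt(sum(g^2)), tolerance = 1e-12)
  }
  expect_error(d_spacing(cub, c(0, 0, 0)), "nonzero")
  expect_error(miller_index(0, 0, 0), "not a valid plane")
})

test_that("d-spacing scales as d(n hkl) = d(hkl)/n", {
  mc <- unit_cell(4.2, 7.7, 11.3, alpha = 88, beta = 97, gamma = 91)
  for (hkl in list(c(1, 1, 0), c(1, -1, 2), c(0, 0, 1))) {
    d1 <- d_spacing(mc, hkl)
    for (n in 2:4) expect_equal(d_spacing(mc, n * hkl), d1 / n,
                                tolerance = 1e-12)
  }
})

test_that("symmetry operation strings parse and format round-trip", {
  for (s in c("x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z", "x,-y+1/2,z+1/2")) {
    op <- parse_symop(s)
    expect_equal(format_symop(op), s)
    op2 <- parse_symop(format_symop(op))
    expect_equal(op2$R, op$R)
    expect_equal(op2$t, op$t)
  }
  op <- parse_symop("-x, y + 1/2, -z+0.5")
  expect_equal(apply_symop(op, c(0.1, 0.2, 0.3)), c(-0.1, 0.7, 0.2))
  expect_error(parse_symop("x,y"), "expected 3")
  expect_error(parse_symop("x,y,q"), "cannot parse")
})

test_that("symmetry expansion yields Z molecules and is idempotent", {
  st <- beta_fixture()
  expect_equal(st$Z, 4L)
  ## re-expanding the full molecule list with the same ops reduces back
  st2 <- crystal_structure(st$cell, st$symops, st$molecules)
  expect_equal(st2$Z, st$Z)
  cents1 <- molecule_centroids(st)
  cents2 <- molecule_centroids(st2)
  key <- function(m) paste(sort(apply(round(m, 4) %% 1, 1, paste,
                                      collapse = ",")), collapse = ";")
  expect_equal(key(cents2), key(cents1))
})

test_that("supercell construction scales counts and volume", {
  st <- beta_fixture()
  sc <- build_supercell(st, c(3, 3, 1))
  expect_equal(sc$Z, 36L)
  expect_equal(cell_volume(sc$cell), 9 * cell_volume(st$cell),
               tolerance = 1e-9)
  s1 <- build_supercell(st, c(1, 1, 1))
  expect_equal(s1$molecules, st$molecules)
  expect_equal(length(s1$symops), length(st$symops))
  toy <- simple_p1_purine()
  a21 <- build_supercell(toy, c(2, 1, 1))
  a12 <- build_supercell(toy, c(1, 2, 1))
  expect_equal(a21$Z, a12$Z)
  expect_false(isTRUE(all.equal(a21$cell, a12$cell)))
  expect_error(build_supercell(st, c(0, 1, 1)), "positive")
})

test_that("CIF write/read round-trips the structure within 1e-6 Angstrom", {
  st <- beta_fixture()
  tmp <- tempfile(fileext = ".cif")
  write_cif(st, tmp)
  st2 <- read_cif(tmp)
  expect_equal(st2$Z, st$Z)
  allcart <- function(s) {
    m <- do.call(rbind, lapply(s$molecules, function(x) x$frac))
    m <- frac_to_cart(s$cell, m - floor(m))
    m[order(round(m[, 1], 4), round(m[, 2], 4), round(m[, 3], 4)), ]
  }
  expect_lt(max(abs(allcart(st) - allcart(st2))), 1e-6)
})

test_that("CIF reader assembles molecules and rejects bad input", {
  toy <- simple_p1_purine()
  tmp <- tempfile(fileext = ".cif")
  write_cif(toy, tmp)
  st <- read_cif(tmp)
  expect_equal(st$Z, 1L)                     # P1, one molecule
  expect_equal(nrow(st$molecules[[1]]$frac), 11L)
  fixture <- system.file("extdata", "beta-guanine-synthetic.cif",
                         package = "xtalgrow")
  expect_equal(read_cif(fixture)$Z, 4L)
  expect_error(read_cif(tempfile()), "no such file")
  ## partial occupancy is unsupported
  lines <- readLines(tmp)
  lines <- sub("1\\.0$", "0.5", lines)
  tmp2 <- tempfile(fileext = ".cif")
  writeLines(lines, tmp2)
  expect_error(read_cif(tmp2), "occupanc")
})

test_that("molecule templates share the purine scaffold", {
  g <- purine_template("guanine")
  h <- purine_template("hypoxanthine")
  x <- purine_template("xanthine")
  shared <- Reduce(intersect, list(names(g$scaffold), names(h$scaffold),
                                   names(x$scaffold)))
  expect_true(all(c("N1", "C2", "N3", "C4", "C5", "C6",
                    "N7", "C8", "N9", "O6") %in% shared))
  expect_gt(min(dist(g$xyz)), 0.5)
  expect_error(molecule_template("bad", "t", c("C", "C"),
                                 rbind(c(0, 0, 0), c(0.1, 0, 0))),
               "closer than 0.5")
})
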