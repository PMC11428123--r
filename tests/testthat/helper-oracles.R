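## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (plain double loops, explicit linear algebra).

## brute-force periodic neighbor enumeration: double loop over molecule
## pairs and a fixed block of lattice images
brute_force_neighbors <- function(structure, cutoff, img = 3) {
  M <- cell_matrix(structure$cell)
  carts <- lapply(seq_len(structure$Z), function(i) molecule_cart(structure, i))
  out <- NULL
  for (i in seq_len(structure$Z)) for (j in seq_len(structure$Z))
    for (oa in -img:img) for (ob in -img:img) for (oc in -img:img) {
      if (i == j && oa == 0 && ob == 0 && oc == 0) next
      shift <- as.numeric(M %*% c(oa, ob, oc))
      B <- sweep(carts[[j]], 2, shift, "+")
      dmin <- Inf
      for (p in seq_len(nrow(carts[[i]]))) {
        d <- sqrt(colSums((t(B) - carts[[i]][p, ])^2))
        dmin <- min(dmin, min(d))
      }
      if (dmin <= cutoff)
        out <- rbind(out, data.frame(i = i, j = j, oa = oa, ob = ob, oc = oc,
                                     dist = dmin))
    }
  out
}

contact_key <- function(df) {
  sort(sprintf("%d|%d|%d|%d|%d", df$i, df$j, df$oa, df$ob, df$oc))
}

## random small P1 toy cells for property tests
random_toy_structure <- function(seed, Zmax = 3) {
  set.seed(seed)
  cell <- unit_cell(runif(1, 6, 10), runif(1, 6, 10), runif(1, 6, 10),
                    runif(1, 80, 100), runif(1, 80, 100), runif(1, 80, 100))
  Z <- sample.int(Zmax, 1)
  mols <- lapply(seq_len(Z), function(k) {
    n <- sample(3:5, 1)
    xyz <- matrix(rnorm(3 * n, sd = 0.8), n, 3)
    ## enforce the 0.5-A minimum separation of molecule templates
    while (n > 1 && min(dist(xyz)) < 0.55)
      xyz <- matrix(rnorm(3 * n, sd = 0.8), n, 3)
    cent <- runif(3)
    list(species = paste0("sp", k), elements = rep("C", n),
         frac = sweep(cart_to_frac(cell, xyz), 2, cent, "+"))
  })
  crystal_structure(cell, symops_for("P1"), mols)
}

## exhaustive translation-deduplicated occupancy patterns (independent of
## the package's canonicalization)
brute_force_patterns <- function(repeats, Zp, k) {
  sites <- expand.grid(m = seq_len(Zp), oa = 0:(repeats[1] - 1),
                       ob = 0:(repeats[2] - 1), oc = 0:(repeats[3] - 1))
  N <- nrow(sites)
  id_of <- function(m, oa, ob, oc)
    which(sites$m == m & sites$oa == oa & sites$ob == ob & sites$oc == oc)
  seen <- character(0)
  combs <- utils::combn(N, k)
  for (ci in seq_len(ncol(combs))) {
    set <- combs[, ci]
    best <- NULL
    for (ta in 0:(repeats[1] - 1)) for (tb in 0:(repeats[2] - 1))
      for (tc in 0:(repeats[3] - 1)) {
        mapped <- vapply(set, function(s)
          id_of(sites$m[s], (sites$oa[s] + ta) %% repeats[1],
                (sites$ob[s] + tb) %% repeats[2],
                (sites$oc[s] + tc) %% repeats[3]), integer(1))
        key <- paste(sort(mapped), collapse = ",")
        if (is.null(best) || key < best) best <- key
      }
    seen <- union(seen, best)
  }
  length(seen)
}

## shared fixtures
beta_fixture <- function() synth_beta_guanine()

simple_p1_purine <- function(edge = 12) {
  cell <- unit_cell(edge, edge, edge)
  g <- purine_template("guanine")
  crystal_structure(cell, symops_for("P1"),
                    list(list(species = "guanine", elements = g$elements,
                              frac = cart_to_frac(cell, g$xyz),
                              scaffold = g$scaffold)))
}

.cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
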