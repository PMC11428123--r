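#' Identify facets of a grown crystal
#'
#' Spacing-based facet coloring: every surface site is assigned to the
#' candidate Miller-plane family whose supporting plane (the outermost
#' lattice plane of that family touching the crystal) it lies closest
#' beneath, with the depth measured in units of that family's d-spacing.
#' Ties (edges, where two supporting planes meet) go to the family with
#' the larger d-spacing. Relative areas are surface-site count fractions;
#' (hkl) and (-h-k-l) form one family.
#'
#' @param state a [run_growth()] result.
#' @param candidates integer matrix of candidate `hkl` rows; default all
#'   indices with `|h|, |k|, |l| <= 2` (up to sign and common factor).
#' @return data.frame of class `facet_list` with columns `h`, `k`, `l`,
#'   `area` (relative, sums to 1 over classified sites), `n_sites`.
#' @export
identify_facets <- function(state, candidates = NULL) {
  occ <- state$occ
  if (sum(occ > 0) < 10)
    stop("identify_facets: crystal too small to classify", call. = FALSE)
  if (is.null(candidates)) candidates <- .default_hkl_set()
  if (!nrow(candidates)) stop("identify_facets: empty candidate set", call. = FALSE)
  surf <- .surface_sites(state)
  if (length(surf) < 10)
    stop("identify_facets: crystal too small to classify", call. = FALSE)
  cellM <- cell_matrix(state$structure$cell)
  X <- state$site_frac[surf, , drop = FALSE] %*% t(cellM)
  B <- reciprocal_matrix(state$structure$cell)
  dsp <- apply(candidates, 1, function(hkl) d_spacing(state$structure$cell, hkl))
  ## process candidates from large to small d so ties keep the low index
  ord <- order(-dsp)
  candidates <- candidates[ord, , drop = FALSE]
  dsp <- dsp[ord]
  best_depth <- rep(Inf, length(surf))
  assign <- rep(NA_integer_, length(surf))
  for (ci in seq_len(nrow(candidates))) {
    nrm <- as.numeric(B %*% candidates[ci, ])
    nrm <- nrm / sqrt(sum(nrm^2))
    p <- as.numeric(X %*% nrm)
    depth <- pmin(max(p) - p, p - min(p)) / dsp[ci]
    upd <- depth < best_depth - 1e-9
    assign[upd] <- ci
    best_depth[upd] <- depth[upd]
  }
  tab <- table(assign[!is.na(assign)])
  out <- data.frame(h = candidates[as.integer(names(tab)), 1],
                    k = candidates[as.integer(names(tab)), 2],
                    l = candidates[as.integer(names(tab)), 3],
                    n_sites = as.integer(tab))
  out$area <- out$n_sites / sum(out$n_sites)
  out <- out[order(-out$area), ]
  rownames(out) <- NULL
  class(out) <- c("facet_list", "data.frame")
  out
}

.default_hkl_set <- function(maxi = 2) {
  g <- as.matrix(expand.grid(h = -maxi:maxi, k = -maxi:maxi, l = -maxi:maxi))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1, function(v) {
    d <- v[v != 0]
    if (d[1] < 0) return(FALSE)             # canonical sign
    g0 <- Reduce(function(a, b) .gcd(a, b), abs(d))
    g0 == 1
  })
  g[keep, , drop = FALSE]
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

## surface sites (occupied, with an empty in-lattice neighbor slot) plus
## their outward vectors: the summed Cartesian directions toward those
## empty slots
.surface_outward <- function(state) {
  occ <- state$occ
  Z <- state$structure$Z
  contacts <- state$contacts
  n <- length(occ)
  nocc <- integer(n); deg <- integer(n)
  out <- matrix(0, n, 3)
  dims <- state$dims
  la <- dims[1]; lb <- dims[2]; lc <- dims[3]
  idx0 <- seq_len(n) - 1L
  mol <- (idx0 %% Z) + 1L
  cidx <- idx0 %/% Z
  ia <- cidx %% la; ib <- (cidx %/% la) %% lb; ic <- cidx %/% (la * lb)
  M <- cell_matrix(state$structure$cell)
  for (r in seq_len(nrow(contacts))) {
    sel <- which(mol == contacts$i[r])
    ja <- ia[sel] + contacts$oa[r]; jb <- ib[sel] + contacts$ob[r]
    jc <- ic[sel] + contacts$oc[r]
    ok <- ja >= 0 & ja < la & jb >= 0 & jb < lb & jc >= 0 & jc < lc
    tgt <- contacts$j[r] + Z * (ja + la * (jb + lb * jc))
    deg[sel[ok]] <- deg[sel[ok]] + 1L
    occ_t <- occ[tgt[ok]] > 0
    nocc[sel[ok]] <- nocc[sel[ok]] + as.integer(occ_t)
    dir <- as.numeric(M %*% c(contacts$va[r], contacts$vb[r], contacts$vc[r]))
    dir <- dir / sqrt(sum(dir^2))
    emp <- sel[ok][!occ_t]
    if (length(emp)) out[emp, ] <- out[emp, ] + rep(dir, each = length(emp))
  }
  surf <- which(occ > 0 & nocc < deg)
  list(surf = surf, outward = out[surf, , drop = FALSE])
}

## surface sites: occupied with at least one empty in-lattice neighbor slot
.surface_sites <- function(state) {
  occ <- state$occ
  Z <- state$structure$Z
  contacts <- state$contacts
  n <- length(occ)
  nocc <- integer(n)
  deg <- integer(n)
  dims <- state$dims
  la <- dims[1]; lb <- dims[2]; lc <- dims[3]
  idx0 <- seq_len(n) - 1L
  mol <- (idx0 %% Z) + 1L
  cidx <- idx0 %/% Z
  ia <- cidx %% la; ib <- (cidx %/% la) %% lb; ic <- cidx %/% (la * lb)
  for (r in seq_len(nrow(contacts))) {
    sel <- which(mol == contacts$i[r])
    ja <- ia[sel] + contacts$oa[r]; jb <- ib[sel] + contacts$ob[r]
    jc <- ic[sel] + contacts$oc[r]
    ok <- ja >= 0 & ja < la & jb >= 0 & jb < lb & jc >= 0 & jc < lc
    tgt <- contacts$j[r] + Z * (ja + la * (jb + lb * jc))
    deg[sel[ok]] <- deg[sel[ok]] + 1L
    occ_t <- occ[tgt[ok]] > 0
    nocc[sel[ok]] <- nocc[sel[ok]] + as.integer(occ_t)
  }
  which(occ > 0 & nocc < deg)
}

## bucket-grid fixed-radius neighbor lists
.grid_neighbors <- function(X, r) {
  n <- nrow(X)
  key <- floor(sweep(X, 2, apply(X, 2, min)) / r)
  kid <- paste(key[, 1], key[, 2], key[, 3])
  buckets <- split(seq_len(n), kid)
  keymat <- unique(key)
  lookup <- buckets
  out <- vector("list", n)
  r2 <- r * r
  for (i in seq_len(n)) {
    cand <- integer()
    for (da in -1:1) for (db in -1:1) for (dc in -1:1) {
      kk <- paste(key[i, 1] + da, key[i, 2] + db, key[i, 3] + dc)
      b <- lookup[[kk]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    d2 <- rowSums(sweep(X[cand, , drop = FALSE], 2, X[i, ])^2)
    out[[i]] <- cand[d2 <= r2]
  }
  out
}

#' Morphology metrics of a grown crystal
#'
#' Extents are the spans of occupied-site centroids along the
#' crystallographic a, b, c directions (Angstrom, plus one effective site
#' diameter); the cross-section is the convex hull of the projection onto
#' the plane perpendicular to a (the stacking/growth axis), classified by
#' its dominant hull edges: 6 edges -> hexagonal, 4 edges -> rectangular
#' (aspect <= 2) or lath (aspect > 2), otherwise irregular.
#'
#' @param state a [run_growth()] result.
#' @param facets optionally include an [identify_facets()] call's result.
#' @return object of class `morphology_report`: list with `extents` (named,
#'   Angstrom), `aspect` (named ratios a/b, a/c, b/c), `cross_section`
#'   (class label), `cross_edges`, `n_molecules`, `facets`.
#' @export
morphology_metrics <- function(state, facets = NULL) {
  sel <- which(state$occ > 0)
  if (length(sel) <= 2)
    stop("morphology_metrics: crystal degenerate (<= 2 sites)", call. = FALSE)
  cellM <- cell_matrix(state$structure$cell)
  X <- state$site_frac[sel, , drop = FALSE] %*% t(cellM)
  axes <- apply(cellM, 2, function(v) v / sqrt(sum(v^2)))
  proj <- X %*% axes                       # projections onto a, b, c directions
  site_d <- min(state$contacts$dist)
  extents <- apply(proj, 2, function(p) diff(range(p))) + site_d
  names(extents) <- c("a", "b", "c")
  aspect <- c(ab = extents[[1]] / extents[[2]],
              ac = extents[[1]] / extents[[3]],
              bc = extents[[2]] / extents[[3]])
  cs <- .cross_section(X, axes[, 1])
  structure(list(extents = extents, aspect = aspect,
                 cross_section = cs$class, cross_edges = cs$n_edges,
                 cross_aspect = cs$aspect,
                 n_molecules = length(sel), facets = facets),
            class = "morphology_report")
}

## classify the polygon of the projection perpendicular to `axis`
.cross_section <- function(X, axis) {
  ## orthonormal basis of the perpendicular plane
  u <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- u - sum(u * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  P <- cbind(X %*% e1, X %*% e2)
  hull <- grDevices::chull(P)
  H <- P[hull, , drop = FALSE]
  nh <- nrow(H)
  if (nh < 3) return(list(class = "irregular", n_edges = nh, aspect = NA))
  ## cluster hull edges by direction (length-weighted greedy clustering),
  ## robust to the small corner edges a discrete lattice hull produces
  edges <- H[c(2:nh, 1), ] - H
  ang <- atan2(edges[, 2], edges[, 1])
  len <- sqrt(rowSums(edges^2))
  ord <- order(-len)
  ctr_ang <- numeric(0); ctr_len <- numeric(0)
  tol <- 18 * pi / 180
  for (i in ord) {
    if (length(ctr_ang)) {
      d <- abs(ctr_ang - ang[i]) %% (2 * pi)
      d <- pmin(d, 2 * pi - d)
      j <- which.min(d)
    }
    if (length(ctr_ang) && min(d) <= tol) {
      w <- len[i] / (ctr_len[j] + len[i])
      ## circular mean toward the new edge
      delta <- ((ang[i] - ctr_ang[j] + pi) %% (2 * pi)) - pi
      ctr_ang[j] <- ctr_ang[j] + w * delta
      ctr_len[j] <- ctr_len[j] + len[i]
    } else {
      ctr_ang <- c(ctr_ang, ang[i]); ctr_len <- c(ctr_len, len[i])
    }
  }
  per <- sum(len)
  n_dom <- sum(ctr_len >= 0.08 * per)
  ## in-plane aspect from principal extents
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc, nu = 0, nv = 2)
  ext <- apply(Pc %*% sv$v, 2, function(v) diff(range(v)))
  aspect <- max(ext) / max(min(ext), 1e-9)
  cls <- if (n_dom == 6) "hexagonal"
         else if (n_dom == 4 && aspect <= 2) "square/rectangular"
         else if (n_dom == 4) "lath"
         else "irregular"
  list(class = cls, n_edges = n_dom, aspect = aspect)
}

#' @export
print.morphology_report <- function(x, ...) {
  cat(sprintf("<morphology_report> %d molecules; extents a=%.1f b=%.1f c=%.1f A\n",
              x$n_molecules, x$extents["a"], x$extents["b"], x$extents["c"]))
  cat(sprintf("  aspect a/b=%.2f a/c=%.2f b/c=%.2f; cross-section: %s (%d edges)\n",
              x$aspect["ab"], x$aspect["ac"], x$aspect["bc"],
              x$cross_section, x$cross_edges))
  if (!is.null(x$facets)) {
    f <- utils::head(x$facets, 3)
    cat("  top facets:", paste(sprintf("(%d%d%d) %.0f%%", f$h, f$k, f$l,
                                       100 * f$area), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Morphology sweep over interaction-strength grids
#'
#' Re-runs the growth simulation on modified copies of a base interaction
#' table: the pi-stack crystallization energy scaled by each value of
#' `pi_scale`, and the 3H-bond energy set to `hb_ratio` times the 2H-bond
#' energy; reports per-grid-point medians over seeded replicates.
#'
#' @param table base `interaction_table` (labelled, e.g. from
#'   [make_interaction_table()]).
#' @param structure the matching [crystal_structure()].
#' @param pi_scale numeric vector of pi-stack scale factors.
#' @param hb_ratio numeric vector of 3H:2H energy ratios (NA keeps the base
#'   3H energy).
#' @param config a [growth_config()]; its seed starts the replicate seeds.
#' @param replicates number of seeds per grid point (>= 3).
#' @return data.frame of class `morphology_sweep`: one row per grid point
#'   with median extents, aspect ratios and the modal cross-section class.
#' @export
sweep_morphology <- function(table, structure, pi_scale = 1, hb_ratio = NA,
                             config = growth_config(preset = "desk"),
                             replicates = 5) {
  if (replicates < 3) stop("sweep_morphology: need >= 3 replicates", call. = FALSE)
  if (!length(pi_scale) || !length(hb_ratio))
    stop("sweep_morphology: empty grid", call. = FALSE)
  grid <- expand.grid(pi_scale = pi_scale, hb_ratio = hb_ratio)
  out <- NULL
  for (gi in seq_len(nrow(grid))) {
    tab <- table
    ip <- tab$label == "pi-stack"
    tab$dg_cryst[ip] <- tab$dg_cryst[ip] * grid$pi_scale[gi]
    if (!is.na(grid$hb_ratio[gi])) {
      i3 <- tab$label == "3H-bond"; i2 <- tab$label == "2H-bond"
      tab$dg_cryst[i3] <- grid$hb_ratio[gi] * tab$dg_cryst[i2][1]
    }
    mets <- lapply(seq_len(replicates), function(r) {
      cfg <- config
      cfg$seed <- config$seed + 1000 * gi + r
      st <- tryCatch(run_growth(tab, structure, cfg),
                     error = function(e) stop(sprintf(
                       "sweep_morphology: grid point (pi=%g, r=%g): %s",
                       grid$pi_scale[gi], grid$hb_ratio[gi],
                       conditionMessage(e)), call. = FALSE))
      morphology_metrics(st)
    })
    med <- function(f) stats::median(vapply(mets, f, numeric(1)))
    classes <- vapply(mets, function(m) m$cross_section, character(1))
    out <- rbind(out, data.frame(
      pi_scale = grid$pi_scale[gi], hb_ratio = grid$hb_ratio[gi],
      extent_a = med(function(m) m$extents[["a"]]),
      extent_b = med(function(m) m$extents[["b"]]),
      extent_c = med(function(m) m$extents[["c"]]),
      aspect_ab = med(function(m) m$aspect[["ab"]]),
      aspect_bc = med(function(m) m$aspect[["bc"]]),
      cross_section = names(sort(base::table(classes), decreasing = TRUE))[1],
      n_molecules = med(function(m) as.numeric(m$n_molecules))))
  }
  class(out) <- c("morphology_sweep", "data.frame")
  out
}
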