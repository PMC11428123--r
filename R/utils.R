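## Internal geometry helpers shared across modules.

## All pairwise distances between two Cartesian coordinate sets (rows).
.cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

.min_dist <- function(A, B) min(.cross_dist(A, B))

## Covalent radii (Angstrom) for bond detection; Cordero-style values.
.COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20)

.covalent_radius <- function(el) {
  r <- .COVALENT_RADII[el]
  r[is.na(r)] <- 0.75
  unname(r)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of point set `P` onto point set `Q` (rows correspond):
#' returns the proper rotation `R` and translation `t` minimising
#' the RMSD of `P %*% t(R) + t` to `Q`. This is the alignment engine behind
#' guest-for-host substitution ("maximum atom overlap").
#'
#' @param P,Q n x 3 matrices with corresponding rows, n >= 3.
#' @return list with `R` (3 x 3 rotation), `t` (length 3), `rmsd`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3 || nrow(P) < 3)
    stop("kabsch: P and Q must be matching n x 3 matrices, n >= 3", call. = FALSE)
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  t <- qc - as.numeric(R %*% pc)
  list(R = R, t = t, rmsd = rmsd)
}

## Perpendicular heights of the cell along the three axes (distance between
## opposite faces); used to size periodic image searches.
.cell_heights <- function(cell) {
  M <- cell_matrix(cell)
  Mi <- solve(M)
  vapply(1:3, function(k) 1 / sqrt(sum(Mi[k, ]^2)), numeric(1))
}

.wrap_frac <- function(x) x - floor(x)
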