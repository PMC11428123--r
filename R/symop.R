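#' Symmetry operations
#'
#' Affine operations in fractional coordinates, stored as a 3x3 rotation part
#' `R` and a translation `t`, so that x' = R x + t. Constructors accept the
#' CIF "x,y,z" string notation (e.g. `"-x, y+1/2, -z+1/2"`).
#'
#' @param xyz character string in CIF symmetry notation.
#' @return object of class `symop` (list with elements `R`, `t`).
#' @examples
#' op <- parse_symop("-x, y+1/2, -z+1/2")
#' apply_symop(op, c(0.1, 0.2, 0.3))
#' @export
parse_symop <- function(xyz) {
  parts <- strsplit(gsub("[[:space:]]", "", xyz), ",")[[1]]
  if (length(parts) != 3)
    stop(sprintf("parse_symop: expected 3 components in '%s'", xyz), call. = FALSE)
  R <- matrix(0, 3, 3)
  tr <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    expr <- gsub("-", "+-", expr, fixed = TRUE)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[nzchar(terms)]
    if (!length(terms))
      stop(sprintf("parse_symop: empty component in '%s'", xyz), call. = FALSE)
    for (term in terms) {
      sign <- 1
      if (startsWith(term, "-")) { sign <- -1; term <- substring(term, 2) }
      low <- tolower(term)
      if (low %in% c("x", "y", "z")) {
        R[i, match(low, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", term)) {
        f <- as.numeric(strsplit(term, "/", fixed = TRUE)[[1]])
        tr[i] <- tr[i] + sign * f[1] / f[2]
      } else if (grepl("^[0-9.]+$", term)) {
        tr[i] <- tr[i] + sign * as.numeric(term)
      } else if (grepl("^[0-9.]+[xyz]$", low) || grepl("^[0-9]+/[0-9]+[xyz]$", low)) {
        ax <- substring(low, nchar(low))
        coefstr <- substring(term, 1, nchar(term) - 1)
        coef <- if (grepl("/", coefstr)) {
          f <- as.numeric(strsplit(coefstr, "/", fixed = TRUE)[[1]]); f[1] / f[2]
        } else as.numeric(coefstr)
        R[i, match(ax, c("x", "y", "z"))] <- sign * coef
      } else {
        stop(sprintf("parse_symop: cannot parse term '%s' in '%s'", term, xyz),
             call. = FALSE)
      }
    }
  }
  structure(list(R = R, t = tr), class = "symop")
}

#' @rdname parse_symop
#' @param op a `symop`.
#' @export
format_symop <- function(op) {
  ax <- c("x", "y", "z")
  comps <- vapply(1:3, function(i) {
    s <- ""
    for (j in 1:3) {
      cij <- op$R[i, j]
      if (cij == 0) next
      piece <- if (abs(cij) == 1) ax[j] else paste0(format(abs(cij)), ax[j])
      s <- paste0(s, if (cij < 0) "-" else if (nzchar(s)) "+" else "", piece)
    }
    ti <- op$t[i] %% 1
    if (abs(ti) > 1e-9 && abs(ti - 1) > 1e-9) {
      fr <- .as_fraction(ti)
      s <- paste0(s, "+", fr)
    }
    if (!nzchar(s)) s <- "0"
    s
  }, character(1))
  paste(comps, collapse = ",")
}

.as_fraction <- function(x, denoms = c(2, 3, 4, 6, 12)) {
  for (d in denoms) {
    n <- round(x * d)
    if (abs(x - n / d) < 1e-9) return(sprintf("%d/%d", n, d))
  }
  format(x)
}

#' @rdname parse_symop
#' @param frac fractional coordinate vector (length 3) or n x 3 matrix.
#' @export
apply_symop <- function(op, frac) {
  if (is.matrix(frac)) {
    sweep(frac %*% t(op$R), 2, op$t, "+")
  } else {
    as.numeric(op$R %*% frac + op$t)
  }
}

.identity_symop <- function() structure(list(R = diag(3), t = numeric(3)), class = "symop")

.is_identity_symop <- function(op) {
  max(abs(op$R - diag(3))) < 1e-9 && max(abs(op$t %% 1)) < 1e-9
}

#' Standard space-group generator sets used by the synthetic structures
#'
#' @param symbol one of `"P1"`, `"P-1"`, `"P21/c"`.
#' @return list of `symop`.
#' @export
symops_for <- function(symbol) {
  xyz <- switch(symbol,
    "P1"    = c("x,y,z"),
    "P-1"   = c("x,y,z", "-x,-y,-z"),
    "P21/c" = c("x,y,z", "-x,y+1/2,-z+1/2", "-x,-y,-z", "x,-y+1/2,z+1/2"),
    stop(sprintf("symops_for: unknown symbol '%s'", symbol), call. = FALSE))
  lapply(xyz, parse_symop)
}
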