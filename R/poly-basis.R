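#' Orthogonal polynomial basis over assay temperature
#'
#' Builds a degree-`degree` orthogonal polynomial basis from an
#' observation-level temperature vector by the Forsythe three-term
#' recurrence on the discrete measure defined by the observations
#' (replicated temperatures carry their multiplicity as weight). Evaluated
#' on its construction vector the basis columns are centred, mutually
#' orthogonal, and have unit sum of squares — the convention of
#' `stats::poly()`, so orthogonal-scale coefficients are directly
#' comparable with standard software output.
#'
#' The recurrence constants (`alpha`, squared norms) are stored, making
#' evaluation at arbitrary new temperatures exact and independent of the
#' construction data.
#'
#' @param temps Numeric vector of temperatures (degC), one entry per
#'   observation (replicates included).
#' @param degree Polynomial degree (default 3).
#' @return Object of class `poly_basis` with elements `degree`, `alpha`
#'   (centering constants, length `degree`), `norm2` (squared norms of the
#'   unnormalized polynomials, length `degree + 2` with leading 1 and the
#'   degree-0 norm, as in `stats::poly`), and `temps` (construction vector).
#' @examples
#' b <- poly_basis(rep(c(10, 15, 20, 25, 28), each = 4), degree = 3)
#' M <- predict(b, b$temps)
#' round(crossprod(M), 12)  # identity
#' @export
poly_basis <- function(temps, degree = 3L) {
  stopifnot(is.numeric(temps), all(is.finite(temps)), degree >= 1)
  degree <- as.integer(degree)
  if (length(unique(temps)) < degree + 1L)
    stop_validation("need at least %d distinct temperatures for degree %d (got %d)",
                    degree + 1L, degree, length(unique(temps)))

  n <- length(temps)
  ## Forsythe recurrence: p_{j}(x) = (x - alpha_j) p_{j-1}(x) - beta_j p_{j-2}(x)
  ## with alpha_j = <x p_{j-1}, p_{j-1}> / ||p_{j-1}||^2,
  ##      beta_j  = ||p_{j-1}||^2 / ||p_{j-2}||^2,
  ## inner products summed over the observation vector.
  P <- matrix(0, n, degree + 1L)
  P[, 1] <- 1
  alpha <- numeric(degree)
  norm2 <- numeric(degree + 1L)   # ||p_j||^2, j = 0..degree
  norm2[1] <- n
  for (j in seq_len(degree)) {
    pj1 <- P[, j]
    alpha[j] <- sum(temps * pj1^2) / norm2[j]
    pj <- (temps - alpha[j]) * pj1
    if (j >= 2) pj <- pj - (norm2[j] / norm2[j - 1]) * P[, j - 1]
    P[, j + 1] <- pj
    norm2[j + 1] <- sum(pj^2)
    if (norm2[j + 1] < 1e-10 * norm2[j])
      stop_validation("temperature vector is rank deficient at degree %d", j)
  }

  structure(list(degree = degree,
                 alpha = alpha,
                 norm2 = c(1, norm2),    # stats::poly coefs convention
                 temps = as.numeric(temps)),
            class = "poly_basis")
}

#' Evaluate an orthogonal polynomial basis at new temperatures
#'
#' Applies the stored three-term recurrence, then normalizes each column by
#' the construction-time norm, so evaluating at the construction vector
#' reproduces the training design matrix exactly.
#'
#' @param object A [poly_basis()].
#' @param newdata Numeric vector of temperatures (degC).
#' @param ... Unused.
#' @return Numeric matrix, `length(newdata)` rows by `degree` columns
#'   (columns named `P1`, `P2`, ...). The constant column is not included.
#' @export
predict.poly_basis <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  stopifnot(all(is.finite(x)))
  d <- object$degree
  norm2 <- object$norm2[-1]       # ||p_j||^2, j = 0..degree
  P <- matrix(0, length(x), d + 1L)
  P[, 1] <- 1
  for (j in seq_len(d)) {
    pj <- (x - object$alpha[j]) * P[, j]
    if (j >= 2) pj <- pj - (norm2[j] / norm2[j - 1]) * P[, j - 1]
    P[, j + 1] <- pj
  }
  out <- sweep(P[, -1, drop = FALSE], 2, sqrt(norm2[-1]), "/")
  colnames(out) <- paste0("P", seq_len(d))
  out
}

#' @export
print.poly_basis <- function(x, ...) {
  cat(sprintf("Orthogonal polynomial basis, degree %d, built on %d observations (%d distinct temps)\n",
              x$degree, length(x$temps), length(unique(x$temps))))
  invisible(x)
}

## Monomial representation of the fitted curve: given a coefficient vector
## (intercept, c1..cd) on the orthogonal basis, return raw polynomial
## coefficients (a0..ad) with eta(T) = sum a_k T^k. Solved exactly through
## a small Vandermonde system at degree+1 nodes spread over the data range.
basis_to_monomial <- function(basis, coefs) {
  d <- basis$degree
  stopifnot(length(coefs) == d + 1L)
  nodes <- seq(min(basis$temps), max(basis$temps), length.out = d + 1L)
  V <- outer(nodes, 0:d, `^`)
  eta <- drop(cbind(1, predict(basis, nodes)) %*% coefs)
  drop(solve(V, eta))
}
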