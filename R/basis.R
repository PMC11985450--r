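# Orthogonal bases on equally spaced index grids.
#
# Deviation effects in the APC model are constrained to be orthogonal to the
# constant and linear functions of their own index (age, period, or cohort).
# We parametrize them through an orthonormal basis of the complement of
# span{1, x}, built by QR decomposition under the unweighted inner product on
# the grid labels.  The orthogonal quadratic q2 used to split each deviation
# vector into curvature and higher-order parts is x^2 Gram-Schmidted against
# {1, x} and scaled to unit Euclidean norm; its polynomial coefficients are
# kept so the curve can be continued beyond the grid.

# n x (n-2) matrix whose columns are orthonormal and orthogonal to 1 and v.
ortho_dev_basis <- function(v) {
  n <- length(v)
  if (n < 3L) stop_("need at least 3 levels to define deviations (got %d)", n)
  Q <- qr.Q(qr(cbind(1, v - mean(v))), complete = TRUE)
  Q[, 3:n, drop = FALSE]
}

# Orthogonalized quadratic on grid v: unit-norm vector plus the polynomial
# p(x) = k0 + k1*x + k2*x^2 that generates it at arbitrary x.
ortho_quad <- function(v) {
  n <- length(v)
  if (n < 3L) stop_("need at least 3 levels for a quadratic (got %d)", n)
  vc <- v - mean(v)
  y <- v^2
  b1 <- sum(vc * y) / sum(vc^2)          # projection on centered linear
  b0 <- mean(y) - b1 * 0                  # projection on constant (of residual)
  res <- y - mean(y) - b1 * vc
  nrm <- sqrt(sum(res^2))
  if (nrm < 1e-12) stop_("degenerate grid: quadratic not identifiable")
  # res = v^2 - mean(v^2) - b1*(v - mean(v)); expand in raw x
  k2 <- 1 / nrm
  k1 <- -b1 / nrm
  k0 <- (-mean(y) + b1 * mean(v)) / nrm
  list(values = res / nrm,
       poly = c(k0, k1, k2),
       eval = function(x) k0 + k1 * x + k2 * x^2,
       deriv = function(x) k1 + 2 * k2 * x)
}

# Piecewise-linear "hockey-stick" basis (x - tau_i)_+ for i = 0..k, where
# tau_0 = x_min so the first column is the global linear term.  No intercept.
pwl_basis <- function(x, knots) {
  stopifnot(length(knots) >= 1L)
  B <- vapply(knots, function(k) pmax(x - k, 0), numeric(length(x)))
  if (is.null(dim(B))) B <- matrix(B, nrow = length(x))
  colnames(B) <- paste0("hinge_", format(knots, trim = TRUE))
  B
}
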