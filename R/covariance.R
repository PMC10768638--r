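#' Covariance matrix of a pure GBS circuit
#'
#' Builds the `2N x 2N` real covariance matrix (xxpp quadrature ordering,
#' vacuum = `I/2` convention) of the pure Gaussian state produced by per-mode
#' squeezers followed by an interferometer: `sigma = S %*% t(S) / 2` with
#' `S = S_U %*% S_sq`. The squeezer symplectic is
#' `diag(e^{r_i}) ⊕ diag(e^{-r_i})` (x anti-squeezed, p squeezed), the sign
#' convention under which the circuit's sampling matrix is
#' `B = U diag(tanh r) t(U)` with positive Takagi values; the interferometer
#' symplectic is the orthogonal `rbind(cbind(X, -Y), cbind(Y, X))` for
#' `U = X + iY`.
#'
#' @param r numeric vector of squeezing parameters, all `>= 0`.
#' @param U `N x N` unitary matrix (same `N` as `r`).
#' @param tol unitarity tolerance for `U`.
#' @return `2N x 2N` real symmetric positive-definite matrix.
#' @export
covariance_from_circuit <- function(r, U, tol = 1e-10) {
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("covariance_from_circuit: squeezing parameters must be finite and >= 0")
  }
  U <- as.matrix(U)
  N <- length(r)
  if (nrow(U) != N || ncol(U) != N) {
    stop("covariance_from_circuit: r has length ", N, " but U is ",
         nrow(U), " x ", ncol(U))
  }
  if (!is_unitary(U, tol)) {
    stop("covariance_from_circuit: U is not unitary within tolerance ", tol)
  }
  S_sq <- diag(c(exp(r), exp(-r)), 2 * N)
  X <- Re(U)
  Y <- Im(U)
  S_U <- rbind(cbind(X, -Y), cbind(Y, X))
  S <- S_U %*% S_sq
  sigma <- S %*% t(S) / 2
  (sigma + t(sigma)) / 2
}

#' Validate a covariance matrix
#'
#' Checks symmetry, positive definiteness and the uncertainty relation
#' `sigma + i Omega / 2 >= 0` with the xxpp symplectic form
#' `Omega = rbind(cbind(0, I), cbind(-I, 0))`.
#'
#' @param sigma `2N x 2N` real matrix.
#' @param tol numerical slack on the eigenvalue checks.
#' @return invisibly `TRUE`; errors describe the violated invariant.
#' @export
validate_covariance <- function(sigma, tol = 1e-8) {
  sigma <- as.matrix(sigma)
  n2 <- nrow(sigma)
  if (n2 != ncol(sigma) || n2 %% 2L != 0L) {
    stop("covariance must be square with even dimension")
  }
  if (max(abs(sigma - t(sigma))) > tol) stop("covariance is not symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= -tol) stop("covariance is not positive definite")
  N <- n2 / 2L
  Om <- rbind(cbind(matrix(0, N, N), diag(1, N)),
              cbind(-diag(1, N), matrix(0, N, N)))
  H <- sigma + 1i * Om / 2
  hev <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(Re(hev)) < -tol) {
    stop("covariance violates the uncertainty relation sigma + i*Omega/2 >= 0")
  }
  invisible(TRUE)
}

#' Detection-pattern probability of a pure GBS circuit
#'
#' Implements the hafnian pattern-probability formula for a pure Gaussian
#' state: `Pr(s) = |Haf(B_s)|^2 / (n_1! ... n_N! sqrt(det(sigma + I/2)))`,
#' where `B_s` is the pattern-reduced sampling matrix. The vacuum pattern
#' gives `1 / sqrt(det(sigma + I/2))`; odd-photon patterns give exactly 0
#' (odd-dimension hafnian).
#'
#' @param B `N x N` sampling matrix (complex symmetric, Takagi spectrum in
#'   `[0, 1)`), from the same circuit as `sigma`.
#' @param sigma `2N x 2N` covariance matrix of the circuit.
#' @param s integer vector of per-mode photon counts.
#' @param tol slack on the internal-consistency check that the result lies in
#'   `[0, 1]`.
#' @return probability in `[0, 1]`.
#' @export
pattern_probability <- function(B, sigma, s, tol = 1e-9) {
  B <- as.matrix(B)
  N <- nrow(B)
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != 2 * N) {
    stop("pattern_probability: B is ", N, "-mode but sigma is ",
         nrow(sigma), " x ", ncol(sigma))
  }
  s <- check_pattern(s, N)
  norm <- sqrt(det(sigma + diag(1, 2 * N) / 2))
  Bs <- reduce_matrix(B, s)
  p <- Mod(hafnian(Bs))^2 / (prod(factorial(s)) * norm)
  if (p < -tol || p > 1 + tol) {
    stop("pattern_probability: result ", format(p),
         " outside [0, 1]; the B/sigma pair is inconsistent")
  }
  min(max(p, 0), 1)
}
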