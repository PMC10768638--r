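#' Construct a vertex-weighted graph
#'
#' The common currency of every pipeline in this package: a loopless,
#' undirected graph given by a symmetric 0/1 adjacency matrix with zero
#' diagonal, plus non-negative per-vertex weights `omega`. Weights live only
#' in `omega`, never on the diagonal of `A` (the diagonal cannot affect a
#' hafnian in any case); they enter the GBS encoding through the rescaling
#' matrix `Omega`.
#'
#' @param A square 0/1 matrix, symmetric, zero diagonal.
#' @param omega numeric vertex weights (default all 1), length `nrow(A)`.
#' @param labels optional character vertex labels.
#' @return object of class `weighted_graph` with fields `A`, `omega`,
#'   `labels`, `N`.
#' @export
weighted_graph <- function(A, omega = NULL, labels = NULL) {
  A <- as.matrix(A)
  N <- nrow(A)
  if (N != ncol(A)) stop("adjacency matrix must be square")
  if (N > 0 && max(abs(A - t(A))) > 1e-9) {
    stop("adjacency matrix must be symmetric")
  }
  if (N > 0 && any(abs(diag(A)) > 1e-9)) {
    stop("adjacency matrix must have zero diagonal (weights belong in omega)")
  }
  if (N > 0 && !all(abs(A) < 1e-9 | abs(A - 1) < 1e-9)) {
    stop("adjacency entries must be 0 or 1")
  }
  A <- round(A)
  storage.mode(A) <- "double"
  if (is.null(omega)) omega <- rep(1, N)
  omega <- as.numeric(omega)
  if (length(omega) != N) stop("omega must have one weight per vertex")
  if (any(!is.finite(omega)) || any(omega < 0)) {
    stop("vertex weights must be finite and >= 0")
  }
  if (!is.null(labels) && length(labels) != N) {
    stop("labels must have one entry per vertex")
  }
  structure(list(A = A, omega = omega, labels = labels, N = N),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("Weighted graph:", x$N, "vertices,", sum(x$A) / 2, "edges; weight range [",
      if (x$N) format(min(x$omega)) else "-", ",",
      if (x$N) format(max(x$omega)) else "-", "]\n")
  invisible(x)
}

# Stable content hash of a graph, recorded in encoded circuits for provenance.
graph_hash <- function(G) {
  rlang::hash(list(round(G$A), signif(G$omega, 12)))
}

#' Scaling parameters for graph encoding
#'
#' The rescaling `Omega_ii = c (1 + alpha * omega_i)` applied on both sides of
#' the weighted Laplacian. `c` sets the overall brightness (every Takagi value
#' scales as `c^2`); `alpha` controls how strongly vertex weights bias the
#' photon distribution toward heavy vertices.
#'
#' @param c global scale, `> 0`.
#' @param alpha weight gain, `>= 0`.
#' @return object of class `scaling_params`.
#' @export
scaling_params <- function(c, alpha) {
  if (!is.finite(c) || c <= 0) stop("scaling c must be > 0")
  if (!is.finite(alpha) || alpha < 0) stop("scaling alpha must be >= 0")
  structure(list(c = c, alpha = alpha), class = "scaling_params")
}

omega_diag <- function(G, p) {
  p$c * (1 + p$alpha * G$omega)
}

#' Rescaled weighted Laplacian of a graph
#'
#' Computes `A' = Omega (D - A) Omega` where `D` is the degree matrix
#' (`D_ii = sum_j A_ij`) and `Omega = diag(c (1 + alpha * omega_i))`. `D - A`
#' is positive semidefinite, so the result has a non-negative spectrum; for a
#' suitable `(c, alpha)` its Takagi values fall inside `[0, 1)` and it can
#' serve as a GBS sampling matrix.
#'
#' @param G a [weighted_graph()].
#' @param p a [scaling_params()].
#' @return `N x N` symmetric numeric matrix.
#' @export
laplacian_rescale <- function(G, p) {
  stopifnot(inherits(G, "weighted_graph"), inherits(p, "scaling_params"))
  om <- omega_diag(G, p)
  L <- diag(rowSums(G$A), G$N) - G$A
  out <- t(L * om) * om  # Omega %*% L %*% Omega for diagonal Omega
  (out + t(out)) / 2
}

#' Choose scaling parameters for a target maximum Takagi value
#'
#' Searches `(c, alpha)` so that the Takagi spectrum of the rescaled Laplacian
#' has maximum value exactly `lambda_max_target` while maximizing the circuit
#' mean photon number `sum(sinh(r_i)^2)`. Because every Takagi value scales as
#' `c^2` at fixed `alpha`, the optimal `c` at each `alpha` is the one that
#' saturates the target; the search therefore reduces to a deterministic
#' logarithmic grid over `alpha` with golden-section refinement.
#'
#' @param G a [weighted_graph()] with at least one edge.
#' @param lambda_max_target value in `(0, 1)`; default `tanh(1.8)`, i.e. a
#'   maximum squeezing parameter of 1.8.
#' @param alpha_grid candidate weight gains for the coarse grid.
#' @return a [scaling_params()] with attributes `mean_photons` and `lambda`
#'   (the achieved spectrum).
#' @export
choose_scaling <- function(G, lambda_max_target = tanh(1.8),
                           alpha_grid = c(0, 10^seq(-3, 3, length.out = 61))) {
  stopifnot(inherits(G, "weighted_graph"))
  if (!is.finite(lambda_max_target) ||
      lambda_max_target <= 0 || lambda_max_target >= 1) {
    stop("lambda_max_target must lie in (0, 1)")
  }
  base_spec <- function(alpha) {
    p <- scaling_params(1, alpha)
    svd(laplacian_rescale(G, p))$d
  }
  objective <- function(alpha) {
    lam1 <- base_spec(alpha)
    if (max(lam1) <= 0) return(list(val = -Inf, c = NA_real_))
    c2 <- lambda_max_target / max(lam1)
    lam <- c2 * lam1
    list(val = sum(sinh(atanh(pmin(lam, 1 - 1e-12)))^2), c = sqrt(c2),
         lambda = lam)
  }
  if (max(svd(laplacian_rescale(G, scaling_params(1, 0)))$d) <= 0) {
    stop("encoding infeasible: the graph Laplacian is identically zero")
  }
  vals <- vapply(alpha_grid, function(a) objective(a)$val, numeric(1))
  best <- which.max(vals)
  # golden-section refinement on log(1 + alpha) around the best grid point
  lo <- alpha_grid[max(best - 1L, 1L)]
  hi <- alpha_grid[min(best + 1L, length(alpha_grid))]
  f <- function(a) objective(a)$val
  g <- (sqrt(5) - 1) / 2
  a <- log1p(lo); b <- log1p(hi)
  x1 <- b - g * (b - a); x2 <- a + g * (b - a)
  f1 <- f(expm1(x1)); f2 <- f(expm1(x2))
  for (it in seq_len(60)) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + g * (b - a); f2 <- f(expm1(x2))
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - g * (b - a); f1 <- f(expm1(x1))
    }
  }
  alpha <- expm1((a + b) / 2)
  cand <- c(alpha, alpha_grid[best])
  alpha <- cand[which.max(vapply(cand, f, numeric(1)))]
  res <- objective(alpha)
  p <- scaling_params(res$c, alpha)
  attr(p, "mean_photons") <- res$val
  attr(p, "lambda") <- res$lambda
  p
}

#' Scaling with a fixed weight gain
#'
#' Companion to [choose_scaling()] for weighted-clique experiments: holds the
#' weight gain `alpha` fixed and solves for the global scale `c` that puts
#' the largest Takagi value exactly at `lambda_max_target` (every Takagi
#' value scales as `c^2`). A strictly positive `alpha` is what couples the
#' vertex weights to the sampler — with `alpha = 0` the matrix `Omega` is a
#' multiple of the identity and detection patterns carry no weight
#' information at all, only subgraph density.
#'
#' @param G a [weighted_graph()].
#' @param alpha weight gain (default 1, commensurate with weights of order
#'   1).
#' @param lambda_max_target target maximum Takagi value, in `(0, 1)`.
#' @return a [scaling_params()].
#' @export
scaling_for_weight_gain <- function(G, alpha = 1,
                                    lambda_max_target = tanh(1.8)) {
  stopifnot(inherits(G, "weighted_graph"))
  if (lambda_max_target <= 0 || lambda_max_target >= 1) {
    stop("lambda_max_target must lie in (0, 1)")
  }
  lam1 <- svd(laplacian_rescale(G, scaling_params(1, alpha)))$d
  if (max(lam1) <= 0) {
    stop("encoding infeasible: the graph Laplacian is identically zero")
  }
  scaling_params(sqrt(lambda_max_target / max(lam1)), alpha)
}

#' Construct a GBS circuit from explicit parameters
#'
#' Low-level constructor for a circuit that does not come from a graph (e.g.
#' a hand-built squeezer/interferometer program). [encode_graph()] is the
#' high-level route.
#'
#' @param U unitary matrix.
#' @param r squeezing parameters (`>= 0`, `tanh(r) < 1`), same length as
#'   `ncol(U)`.
#' @param scaling optional [scaling_params()] provenance.
#' @return an `encoded_circuit`.
#' @export
encoded_circuit <- function(U, r, scaling = NULL) {
  U <- as.matrix(U) + 0i
  r <- as.numeric(r)
  if (!is_unitary(U)) stop("U is not unitary")
  if (length(r) != nrow(U)) stop("r and U disagree on the mode count")
  if (any(r < 0) || any(!is.finite(r))) stop("r must be finite and >= 0")
  structure(list(U = U, r = r, scaling = scaling,
                 graph_hash = rlang::hash(list(signif(Re(U), 12),
                                               signif(Im(U), 12),
                                               signif(r, 12))),
                 N = nrow(U)),
            class = "encoded_circuit")
}

#' Encode a weighted graph as a GBS circuit
#'
#' Applies [laplacian_rescale()] then [takagi_decompose()]: the Takagi
#' vectors give the interferometer unitary `U` and the Takagi values give the
#' squeezing parameters `r_i = atanh(lambda_i)`. The circuit reconstructs its
#' sampling matrix as `B = U diag(tanh r) t(U)`.
#'
#' @param G a [weighted_graph()].
#' @param p a [scaling_params()]; if `NULL`, chosen by [choose_scaling()].
#' @param margin safety margin: every Takagi value must be `< 1 - margin`.
#' @return object of class `encoded_circuit`: `U`, `r`, `scaling`,
#'   `graph_hash`, `N`.
#' @export
encode_graph <- function(G, p = NULL, margin = 0.01) {
  stopifnot(inherits(G, "weighted_graph"))
  if (is.null(p)) p <- choose_scaling(G)
  B <- laplacian_rescale(G, p)
  td <- takagi_decompose(B)
  if (any(td$lambda >= 1 - margin)) {
    stop("spectrum error: Takagi value ", format(max(td$lambda)),
         " exceeds 1 - margin = ", 1 - margin,
         "; reduce the scaling constant c")
  }
  r <- squeezing_from_takagi(td$lambda)
  structure(list(U = td$U, r = r, scaling = p, graph_hash = graph_hash(G),
                 N = G$N),
            class = "encoded_circuit")
}

#' @export
print.encoded_circuit <- function(x, ...) {
  cat("Encoded GBS circuit:", x$N, "modes; r_max =", format(max(x$r)),
      "; mean photons =", format(sum(sinh(x$r)^2)), "\n")
  invisible(x)
}

#' Sampling matrix of an encoded circuit
#'
#' @param circuit an [encode_graph()] result.
#' @return `B = U diag(tanh r) t(U)` (real part returned when the imaginary
#'   remainder is at rounding level, as for real symmetric inputs).
#' @export
circuit_sampling_matrix <- function(circuit) {
  stopifnot(inherits(circuit, "encoded_circuit"))
  B <- circuit$U %*% diag(tanh(circuit$r), circuit$N) %*% t(circuit$U)
  B <- (B + t(B)) / 2
  if (max(abs(Im(B))) < 1e-10) B <- Re(B)
  B
}

#' Collision-free hafnian/weight identity
#'
#' For a collision-free pattern `s` on `k` detected modes, the degree matrix
#' cannot contribute to the reduced hafnian (diagonal entries never enter a
#' matching), so `Haf(A'_s) = (-1)^(k/2) det(Omega_s) Haf(A_s)`. The sign
#' `(-1)^(k/2)` comes from the `-A` off-diagonal of the Laplacian; it is
#' immaterial to the `|Haf|^2` sampling probabilities, which is why the
#' identity is usually quoted without it. Returns both sides (with the sign
#' included in `rhs`) so their equality can be checked to machine precision.
#'
#' @param G a [weighted_graph()].
#' @param p a [scaling_params()].
#' @param s collision-free detection pattern (0/1 vector) with an even number
#'   of photons.
#' @return list with `lhs = Haf(A'_s)` and
#'   `rhs = (-1)^(k/2) * det(Omega_s) * Haf(A_s)`.
#' @export
hafnian_weight_identity_check <- function(G, p, s) {
  stopifnot(inherits(G, "weighted_graph"))
  s <- check_pattern(s, G$N)
  if (any(s > 1L)) stop("identity check requires a collision-free pattern")
  k <- sum(s)
  if (k %% 2L != 0L) stop("identity check requires an even photon number")
  idx <- which(s == 1L)
  Ap <- laplacian_rescale(G, p)
  lhs <- hafnian(Ap[idx, idx, drop = FALSE])
  om <- omega_diag(G, p)[idx]
  rhs <- (-1)^(k / 2) * prod(om) * hafnian(G$A[idx, idx, drop = FALSE])
  list(lhs = lhs, rhs = rhs)
}
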