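#' Hafnian of a complex symmetric matrix
#'
#' The hafnian of a symmetric `2m x 2m` matrix `M` is the sum over all perfect
#' matchings of the index set `{1, ..., 2m}` of the product of the matched
#' entries. For the 0/1 adjacency matrix of a graph it counts perfect
#' matchings; in Gaussian boson sampling it gives detection-pattern amplitudes.
#' Diagonal entries never contribute (matchings have no self-loops).
#'
#' Exact recursive matching enumeration, adequate for desk-scale matrices
#' (dimension up to 26, i.e. up to 13 photon pairs; cost grows as the double
#' factorial of the dimension). By convention the hafnian of an odd-dimension
#' matrix is 0 (no perfect matching exists) and the empty `0 x 0` matrix has
#' hafnian 1 (empty product).
#'
#' @param M square numeric or complex matrix, symmetric to within `tol`.
#' @param tol symmetry tolerance on `max(abs(M - t(M)))`.
#' @return a length-1 complex (or numeric, if `M` is numeric) value.
#' @examples
#' hafnian(matrix(0, 0, 0))          # 1: empty product
#' hafnian(matrix(c(0, 1, 1, 0), 2)) # 1: single matching
#' hafnian(matrix(1, 4, 4))          # 3: the three perfect matchings of K4
#' @export
hafnian <- function(M, tol = 1e-10) {
  M <- as.matrix(M)
  n <- nrow(M)
  if (n != ncol(M)) {
    stop("hafnian: matrix must be square, got ", n, " x ", ncol(M))
  }
  if (n == 0L) {
    return(if (is.complex(M)) 1 + 0i else 1)
  }
  if (max(abs(M - t(M))) > tol) {
    stop("hafnian: matrix is not symmetric within tolerance ", tol)
  }
  if (n %% 2L == 1L) {
    return(if (is.complex(M)) 0 + 0i else 0)
  }
  if (n > 26L) {
    stop("hafnian: dimension ", n, " exceeds the desk-scale guard (26)")
  }
  haf_rec(M, seq_len(n))
}

# Recursive enumeration: match the first live index with each partner in turn.
haf_rec <- function(M, idx) {
  k <- length(idx)
  if (k == 0L) {
    return(1)
  }
  i <- idx[1L]
  rest <- idx[-1L]
  acc <- 0
  for (p in seq_along(rest)) {
    mij <- M[i, rest[p]]
    if (mij != 0) {
      acc <- acc + mij * haf_rec(M, rest[-p])
    }
  }
  acc
}

#' Reduce a sampling matrix by a detection pattern
#'
#' Builds the submatrix `B_s` entering the pattern-probability formula: mode
#' `i` contributes `n_i` copies of its row and column, where `n_i` is the
#' photon count of the pattern. For a collision-free pattern this is the plain
#' induced submatrix on the detected modes.
#'
#' @param B square matrix (the sampling matrix).
#' @param s integer vector of per-mode photon counts, length `nrow(B)`.
#' @return the `k x k` reduced matrix where `k = sum(s)` (a `0 x 0` matrix for
#'   the vacuum pattern).
#' @export
reduce_matrix <- function(B, s) {
  B <- as.matrix(B)
  s <- check_pattern(s, nrow(B))
  idx <- rep(seq_along(s), times = s)
  B[idx, idx, drop = FALSE]
}

# Validate a detection pattern against a mode count.
check_pattern <- function(s, N) {
  s <- as.integer(round(s))
  if (length(s) != N) {
    stop("detection pattern has length ", length(s), " but the circuit has ",
         N, " modes")
  }
  if (any(s < 0L)) stop("detection pattern has negative photon counts")
  s
}

# All perfect matchings of {1..k} (k even) as a list of 2-column pair matrices.
# Used by the vectorized many-subset hafnian below.
perfect_matchings <- function(k) {
  if (k %% 2L != 0L) stop("perfect_matchings: k must be even")
  if (k == 0L) return(list(matrix(integer(0), 0, 2)))
  rec <- function(idx) {
    if (length(idx) == 0L) {
      return(list(matrix(integer(0), 0, 2)))
    }
    i <- idx[1L]
    rest <- idx[-1L]
    out <- list()
    for (p in seq_along(rest)) {
      for (m in rec(rest[-p])) {
        out[[length(out) + 1L]] <- rbind(c(i, rest[p]), m)
      }
    }
    out
  }
  rec(seq_len(k))
}

# Hafnians of many induced submatrices of B at once.
# subsets: k x M integer matrix, each column a set of k distinct mode indices.
# Returns a length-M vector. Vectorized over subsets: for each perfect
# matching of {1..k} the matched entries are gathered for all subsets in one
# indexing operation.
hafnians_of_subsets <- function(B, subsets) {
  k <- nrow(subsets)
  M <- ncol(subsets)
  if (M == 0L) return(if (is.complex(B)) complex(0) else numeric(0))
  if (k %% 2L != 0L) {
    return(rep(if (is.complex(B)) 0 + 0i else 0, M))
  }
  if (k == 0L) return(rep(if (is.complex(B)) 1 + 0i else 1, M))
  matchings <- perfect_matchings(k)
  acc <- rep(if (is.complex(B)) 0 + 0i else 0, M)
  for (m in matchings) {
    term <- rep(if (is.complex(B)) 1 + 0i else 1, M)
    for (r in seq_len(nrow(m))) {
      term <- term * B[cbind(subsets[m[r, 1L], ], subsets[m[r, 2L], ])]
    }
    acc <- acc + term
  }
  acc
}
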