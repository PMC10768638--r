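# Independent oracles used across the test suite. These deliberately avoid
# the package's own algorithms: matchings are counted by permutation
# enumeration, cliques by subset enumeration, nested RNA folds by interval
# dynamic programming.

# Number of perfect matchings of a graph (adjacency 0/1), by brute force over
# all vertex permutations paired consecutively. Feasible for n <= 8.
oracle_matching_count <- function(A) {
  n <- nrow(A)
  if (n %% 2L == 1L) return(0)
  if (n == 0L) return(1)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  count <- 0
  for (p in perms(seq_len(n))) {
    ok <- TRUE
    for (q in seq_len(n / 2)) {
      if (A[p[2 * q - 1L], p[2 * q]] == 0) { ok <- FALSE; break }
    }
    if (ok) count <- count + 1
  }
  # each matching counted 2^m * m! times (pair order and within-pair order)
  m <- n / 2
  count / (2^m * factorial(m))
}

# Maximum weighted clique by exhaustive subset enumeration (N <= 16).
oracle_max_clique_subsets <- function(A, omega) {
  N <- nrow(A)
  best_w <- 0
  best_v <- integer(0)
  for (mask in 0:(2^N - 1)) {
    v <- which(bitwAnd(mask, bitwShiftL(1L, 0:(N - 1L))) > 0L)
    k <- length(v)
    if (k > 1L && sum(A[v, v]) != k * (k - 1L)) next
    w <- sum(omega[v])
    if (w > best_w + 1e-12) {
      best_w <- w
      best_v <- v
    }
  }
  list(vertices = best_v, weight = best_w)
}

# Maximum total stem length over nested (pseudoknot-free) stem selections,
# by interval dynamic programming over a fixed stem list.
oracle_nested_stem_dp <- function(stems, L) {
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i >= j) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- f(i + 1L, j)
    rows <- which(stems$i == i & stems$j <= j)
    for (r in rows) {
      Ls <- stems$length[r]
      q <- stems$j[r]
      cand <- Ls + f(i + Ls, q - Ls) + f(q + 1L, j)
      if (cand > best) best <- cand
    }
    memo[[key]] <- best
    best
  }
  f(1L, L)
}

# Random complex symmetric matrix with spectral radius below `rmax`.
random_sampling_matrix <- function(n, rmax = 0.9) {
  Z <- matrix(complex(real = stats::rnorm(n * n),
                      imaginary = stats::rnorm(n * n)), n)
  B <- (Z + t(Z)) / 2
  B * (rmax / max(svd(B)$d))
}
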