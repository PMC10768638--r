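test_that("hafnian handles the base cases and conventions", {
  expect_equal(hafnian(matrix(0, 0, 0)), 1)
  expect_equal(hafnian(matrix(c(0, 1, 1, 0), 2)), 1)
  expect_equal(hafnian(matrix(1, 4, 4)), 3)
  # odd dimension: no perfect matching, 0 by convention
  expect_equal(hafnian(matrix(0, 3, 3)), 0)
  expect_error(hafnian(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(hafnian(matrix(1, 2, 3)), "square")
})

test_that("hafnian of an adjacency matrix counts perfect matchings", {
  set.seed(41)
  for (n in c(4, 6, 8)) {
    for (rep in 1:5) {
      A <- matrix(0, n, n)
      up <- which(upper.tri(A))
      A[up] <- rbinom(length(up), 1, 0.5)
      A <- A + t(A)
      expect_equal(hafnian(A), oracle_matching_count(A))
    }
  }
  # complete graph closed form: (2m-1)!! matchings
  K10 <- matrix(1, 10, 10) - diag(10)
  expect_equal(hafnian(K10), 9 * 7 * 5 * 3 * 1)
})

test_that("diagonal perturbations never change a hafnian", {
  set.seed(42)
  for (rep in 1:5) {
    B <- random_sampling_matrix(6)
    D <- diag(complex(real = rnorm(6), imaginary = rnorm(6)), 6)
    expect_equal(hafnian(B + D), hafnian(B), tolerance = 1e-10)
  }
})

test_that("reduce_matrix repeats rows/columns by photon count", {
  B <- matrix(c(1, 2, 3, 2, 4, 5, 3, 5, 6), 3)
  expect_equal(reduce_matrix(B, c(0, 1, 1)), B[2:3, 2:3])
  expect_equal(dim(reduce_matrix(B, c(0, 0, 0))), c(0L, 0L))
  t0 <- 0.4
  expect_equal(reduce_matrix(matrix(t0, 1, 1), 2L), matrix(t0, 2, 2))
  expect_error(reduce_matrix(B, c(1, 0)), "modes")
})

test_that("vectorized subset hafnians agree with the scalar routine", {
  set.seed(43)
  B <- random_sampling_matrix(8)
  for (k in c(2, 4, 6)) {
    subsets <- enumerate_patterns(8, k)
    hv <- gbsgraph:::hafnians_of_subsets(B, subsets)
    pick <- sample(ncol(subsets), 5)
    for (j in pick) {
      idx <- subsets[, j]
      expect_equal(hv[j], hafnian(B[idx, idx]), tolerance = 1e-10)
    }
  }
})

test_that("takagi decomposition reconstructs and orders the spectrum", {
  expect_equal(takagi_decompose(diag(c(0.5, 0.2)))$lambda, c(0.5, 0.2))
  set.seed(44)
  for (n in c(2, 3, 5, 7)) {
    B <- random_sampling_matrix(n, rmax = 2)
    td <- takagi_decompose(B)
    expect_true(is_unitary(td$U, 1e-8))
    expect_true(all(td$lambda >= 0))
    expect_true(all(diff(td$lambda) <= 1e-10))
    expect_lt(max(abs(B - td$U %*% diag(td$lambda, n) %*% t(td$U))), 1e-8)
  }
  expect_error(takagi_decompose(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("takagi handles degenerate and rank-deficient spectra", {
  # B = [[0, t], [t, 0]] has the doubly degenerate value t
  td <- takagi_decompose(matrix(c(0, 0.7, 0.7, 0), 2))
  expect_equal(td$lambda, c(0.7, 0.7), tolerance = 1e-10)
  expect_lt(max(abs(matrix(c(0, 0.7, 0.7, 0), 2) -
                      td$U %*% diag(td$lambda) %*% t(td$U))), 1e-8)
  # rank-1 real matrix with a large null space
  B <- matrix(0, 5, 5); B[1, 2] <- B[2, 1] <- 0.3
  td <- takagi_decompose(B)
  expect_true(is_unitary(td$U, 1e-8))
  expect_equal(sort(td$lambda), c(0, 0, 0, 0.3, 0.3), tolerance = 1e-10)
  expect_lt(max(abs(B - td$U %*% diag(td$lambda) %*% t(td$U))), 1e-8)
})

test_that("squeezing parameters invert tanh with the documented guards", {
  expect_equal(squeezing_from_takagi(0), 0)
  expect_equal(squeezing_from_takagi(tanh(2.23)), 2.23)
  expect_equal(squeezing_from_takagi(tanh(1.8)), 1.8)
  expect_error(squeezing_from_takagi(1), ">= 1")
  expect_error(squeezing_from_takagi(-0.1), "negative")
})

test_that("covariance construction matches the pure-state closed forms", {
  # vacuum
  expect_equal(covariance_from_circuit(0, matrix(1 + 0i, 1, 1)),
               diag(0.5, 2))
  # single-mode purity: sqrt(det(sigma + I/2)) = cosh(r)
  for (r in c(0.3, 1.1, 2.23)) {
    sig <- covariance_from_circuit(r, matrix(1 + 0i, 1, 1))
    expect_equal(sqrt(det(sig + diag(0.5, 2))), cosh(r), tolerance = 1e-8)
    expect_silent(validate_covariance(sig))
  }
  # two equal squeezers + 50:50: product of cosh
  U <- matrix(c(1, 1, 1, -1), 2) / sqrt(2)
  sig <- covariance_from_circuit(c(0.8, 0.8), U)
  expect_equal(sqrt(det(sig + diag(0.5, 4))), cosh(0.8)^2, tolerance = 1e-8)
  expect_error(covariance_from_circuit(c(0.1, 0.2), matrix(1 + 0i, 1, 1)),
               "length")
})

test_that("pattern probabilities match squeezed-vacuum and TMSV closed forms", {
  # r = 0: vacuum pattern has probability 1
  sig0 <- covariance_from_circuit(c(0, 0), diag(1 + 0i, 2))
  expect_equal(pattern_probability(matrix(0, 2, 2), sig0, c(0, 0)), 1)
  # two-mode squeezed vacuum via B = [[0, t], [t, 0]]
  r <- 0.9; t0 <- tanh(r)
  B <- matrix(c(0, t0, t0, 0), 2)
  td <- takagi_decompose(B)
  rr <- squeezing_from_takagi(td$lambda)
  sig <- covariance_from_circuit(rr, td$U)
  expect_equal(pattern_probability(B, sig, c(1, 1)), t0^2 / cosh(r)^2,
               tolerance = 1e-10)
  # single mode, two photons in one mode
  sig1 <- covariance_from_circuit(r, matrix(1 + 0i, 1, 1))
  expect_equal(pattern_probability(matrix(t0, 1, 1), sig1, 2L),
               t0^2 / (2 * cosh(r)), tolerance = 1e-10)
  # inconsistent B/sigma pair is detected
  expect_error(pattern_probability(matrix(5, 1, 1), sig1, 2L), "inconsistent")
})

test_that("circuit encoding is self-consistent through the Takagi invariant", {
  set.seed(45)
  lam <- sort(runif(5, 0, 0.9), decreasing = TRUE)
  U <- haar_unitary(5, seed = 8)
  B <- U %*% diag(lam) %*% t(U)
  td <- takagi_decompose(B)
  expect_equal(td$lambda, lam, tolerance = 1e-8)
  r <- squeezing_from_takagi(td$lambda)
  B2 <- td$U %*% diag(tanh(r)) %*% t(td$U)
  expect_lt(max(abs(B - B2)), 1e-8)
})

test_that("clements compilation round-trips unitaries", {
  # identity compiles to all-zero rotations
  p <- clements_compile(diag(1 + 0i, 4))
  expect_equal(length(p$layers), 6L)
  expect_true(all(vapply(p$layers, function(l) abs(l$theta), numeric(1)) <
                    1e-12))
  expect_lt(max(abs(clements_recompose(p) - diag(1, 4))), 1e-10)
  # N = 2: recovers a single T block up to output phases
  th <- 0.7; ph <- 1.2
  T2 <- rbind(c(exp(1i * ph) * cos(th), -sin(th)),
              c(exp(1i * ph) * sin(th), cos(th)))
  p <- clements_compile(T2)
  expect_equal(length(p$layers), 1L)
  expect_equal(p$layers[[1]]$theta, th, tolerance = 1e-10)
  expect_lt(max(abs(clements_recompose(p) - T2)), 1e-10)
  expect_error(clements_compile(matrix(c(1, 1, 0, 1), 2)), "unitary")
})

test_that("clements round-trip error stays below 1e-8 across random unitaries", {
  seeds <- 1:8
  for (n in 2:8) {
    for (s in seeds) {
      U <- haar_unitary(n, seed = 100 * n + s)
      p <- clements_compile(U)
      expect_equal(length(p$layers), n * (n - 1) / 2)
      expect_lt(max(abs(clements_recompose(p) - U)), 1e-8)
    }
  }
})

test_that("collision-free probability mass is monotone in the cutoff and <= 1", {
  fx <- planted_clique_graph(N = 6, k_planted = 3, seed = 21)
  circ <- encode_graph(fx$graph,
                       choose_scaling(fx$graph, lambda_max_target = 0.6))
  masses <- vapply(c(0, 2, 4, 6), function(k) {
    exact_distribution(circ, k_max = k)$mass
  }, numeric(1))
  expect_true(all(diff(masses) >= -1e-12))
  expect_true(all(masses <= 1 + 1e-12))
})
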