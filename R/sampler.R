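#' Enumerate collision-free detection patterns
#'
#' All ways to detect `k` photons in `N` modes with at most one photon per
#' mode, in lexicographic order of the detected-mode indices (the ordering
#' used to index pattern axes in distribution plots).
#'
#' @param N mode count.
#' @param k photon number, `0 <= k <= N`.
#' @return `k x choose(N, k)` integer matrix; each column lists the detected
#'   modes of one pattern.
#' @examples
#' ncol(enumerate_patterns(32, 2)) # 496
#' @export
enumerate_patterns <- function(N, k) {
  N <- as.integer(N); k <- as.integer(k)
  if (k < 0L || k > N) stop("photon number k must satisfy 0 <= k <= N")
  if (k == 0L) return(matrix(integer(0), 0L, 1L))
  m <- utils::combn(N, k)
  storage.mode(m) <- "integer"
  m
}

#' Exact collision-free pattern distribution of an encoded circuit
#'
#' Evaluates the hafnian probability formula for every collision-free pattern
#' with at most `k_max` photons. Odd photon numbers are enumerated and carry
#' exactly zero probability (a pure Gaussian state emits photons in pairs).
#' The distribution records both the raw probabilities (which sum to the
#' truncated-subspace mass, `<= 1`) and the renormalization constant of the
#' truncated subspace.
#'
#' @param circuit an [encode_graph()] result (or any object with unitary `U`
#'   and squeezing `r`).
#' @param k_max photon-number cutoff (even values contribute; default 8).
#' @param k_guard resource guard: `k_max` beyond this errors out (default 10).
#' @param max_patterns resource guard on the total number of enumerated
#'   patterns.
#' @return object of class `pattern_distribution`: `N`, `ks`, `blocks` (per
#'   photon number: detected-mode matrix `subsets` and raw probability vector
#'   `prob`), `mass` (truncated-subspace probability mass), `norm_const`
#'   (`sqrt(det(sigma + I/2)) = prod(cosh(r))`).
#' @export
exact_distribution <- function(circuit, k_max = 8, k_guard = 10,
                               max_patterns = 2e6) {
  stopifnot(inherits(circuit, "encoded_circuit"))
  k_max <- as.integer(k_max)
  if (k_max < 0L) stop("k_max must be >= 0")
  if (k_max > k_guard) {
    stop("resource guard: k_max = ", k_max, " exceeds the desk-scale guard (",
         k_guard, "); raise k_guard explicitly if you mean it")
  }
  N <- circuit$N
  ks <- 0:min(k_max, N)
  total <- sum(choose(N, ks))
  if (total > max_patterns) {
    stop("resource guard: ", format(total, big.mark = ","),
         " patterns would be enumerated (max_patterns = ",
         format(max_patterns, big.mark = ","), ")")
  }
  B <- circuit_sampling_matrix(circuit)
  norm_const <- prod(cosh(circuit$r))
  blocks <- list()
  for (k in ks) {
    subsets <- enumerate_patterns(N, k)
    if (k %% 2L == 1L) {
      prob <- rep(0, ncol(subsets))
    } else {
      haf <- hafnians_of_subsets(B, subsets)
      prob <- Mod(haf)^2 / norm_const
    }
    blocks[[as.character(k)]] <- list(k = k, subsets = subsets, prob = prob)
  }
  mass <- sum(vapply(blocks, function(b) sum(b$prob), numeric(1)))
  structure(list(N = N, ks = ks, blocks = blocks, mass = mass,
                 norm_const = norm_const),
            class = "pattern_distribution")
}

#' @export
print.pattern_distribution <- function(x, ...) {
  cat("Collision-free pattern distribution:", x$N, "modes, k in {",
      paste(x$ks, collapse = ", "), "}; truncated mass",
      format(x$mass, digits = 6), "\n")
  invisible(x)
}

#' Condition a pattern distribution on a photon number
#'
#' Restricts to the patterns with exactly `k` photons and renormalizes. Used
#' by the clique pipelines, which consume fixed-photon-number samples (the
#' truncation bias of the full distribution cancels within a block).
#'
#' @param dist a [exact_distribution()] result.
#' @param k photon number present in `dist`.
#' @return a `pattern_distribution` with a single block whose probabilities
#'   sum to 1.
#' @export
condition_on_photons <- function(dist, k) {
  stopifnot(inherits(dist, "pattern_distribution"))
  b <- dist$blocks[[as.character(k)]]
  if (is.null(b)) stop("photon number ", k, " not present in the distribution")
  mass <- sum(b$prob)
  if (mass <= 0) stop("photon number ", k, " has zero probability mass")
  b$prob <- b$prob / mass
  structure(list(N = dist$N, ks = k, blocks = setNames(list(b), k),
                 mass = 1, norm_const = dist$norm_const),
            class = "pattern_distribution")
}

# Flatten a distribution's blocks into (modes list, prob vector).
flatten_distribution <- function(dist) {
  modes <- list()
  prob <- numeric(0)
  for (b in dist$blocks) {
    if (ncol(b$subsets) == 0L) next
    modes <- c(modes, lapply(seq_len(ncol(b$subsets)),
                             function(j) b$subsets[, j]))
    prob <- c(prob, b$prob)
  }
  list(modes = modes, prob = prob)
}

#' Sample detection patterns from an encoded circuit
#'
#' Exact sampling by inverse CDF over the truncated collision-free
#' distribution, renormalized within the truncated subspace, followed by
#' optional uniform photon loss: with transmission `eta < 1` each detected
#' photon is independently kept with probability `eta` (uniform output loss
#' commutes through the interferometer and acts as binomial thinning), so odd
#' photon totals become possible just as in a lossy experiment.
#'
#' @param circuit an [encode_graph()] result.
#' @param n number of samples.
#' @param seed integer RNG seed recorded in the batch.
#' @param k_max photon-number cutoff for the distribution (ignored when
#'   `dist` is supplied).
#' @param eta transmission in `(0, 1]`.
#' @param dist optional precomputed [exact_distribution()] (possibly
#'   conditioned) to sample from; saves recomputation across replicates.
#' @return object of class `sample_batch`: `patterns` (list of detected-mode
#'   integer vectors), `N`, `seed`, `eta`, `circuit_hash`.
#' @export
gbs_sample <- function(circuit, n, seed, k_max = 8, eta = 1, dist = NULL) {
  stopifnot(inherits(circuit, "encoded_circuit"))
  if (n < 1) stop("n must be >= 1")
  if (!is.finite(eta) || eta <= 0 || eta > 1) {
    stop("transmission eta must lie in (0, 1]")
  }
  if (is.null(dist)) dist <- exact_distribution(circuit, k_max = k_max)
  flat <- flatten_distribution(dist)
  with_seed(seed, {
    idx <- sample.int(length(flat$prob), size = n, replace = TRUE,
                      prob = flat$prob)
    patterns <- lapply(idx, function(i) flat$modes[[i]])
    if (eta < 1) {
      patterns <- lapply(patterns, function(m) {
        if (length(m) == 0L) return(m)
        m[stats::runif(length(m)) < eta]
      })
    }
    structure(list(patterns = patterns, N = dist$N, seed = seed, eta = eta,
                   circuit_hash = circuit$graph_hash),
              class = "sample_batch")
  })
}

#' @export
print.sample_batch <- function(x, ...) {
  k <- lengths(x$patterns)
  cat("Sample batch:", length(x$patterns), "patterns on", x$N,
      "modes (seed", x$seed, ", eta", x$eta, "); photon counts ",
      paste(names(table(k)), table(k), sep = "x", collapse = ", "), "\n")
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Total variation distance between two pattern distributions
#'
#' `0.5 * sum(|p - q|)` over a shared pattern support, computed on the
#' renormalized (within-truncation) probabilities.
#'
#' @param P,Q [exact_distribution()] results with identical mode count and
#'   photon-number blocks.
#' @return value in `[0, 1]`.
#' @export
total_variation_distance <- function(P, Q) {
  stopifnot(inherits(P, "pattern_distribution"),
            inherits(Q, "pattern_distribution"))
  if (P$N != Q$N || !identical(P$ks, Q$ks)) {
    stop("distributions have mismatched support")
  }
  tv <- 0
  for (k in as.character(P$ks)) {
    bp <- P$blocks[[k]]; bq <- Q$blocks[[k]]
    if (!identical(dim(bp$subsets), dim(bq$subsets))) {
      stop("distributions have mismatched support at k = ", k)
    }
    tv <- tv + sum(abs(bp$prob / P$mass - bq$prob / Q$mass))
  }
  tv / 2
}

#' Total transmission budget of a looped interferometer
#'
#' Multiplies the per-stage efficiencies of a time-bin GBS machine with the
#' loop transmission raised to the number of round trips:
#' `loop_transmission^loop_count * prod(stage_efficiencies)`.
#'
#' @param stage_efficiencies numeric vector of one-off efficiencies in
#'   `(0, 1]` (source coupling, filters, demultiplexer, detectors, ...).
#' @param loop_transmission per-round-trip transmission in `(0, 1]`.
#' @param loop_count number of round trips, `>= 0`.
#' @return total transmission in `(0, 1]`.
#' @examples
#' # a 60-mode budget: 61 loops at 0.90 plus five fixed stages
#' loss_budget(c(0.9, 0.944, 0.93, 0.973, 0.95), 0.90, 61)
#' @export
loss_budget <- function(stage_efficiencies, loop_transmission, loop_count) {
  stage_efficiencies <- as.numeric(stage_efficiencies)
  if (length(stage_efficiencies) &&
      (any(stage_efficiencies <= 0) || any(stage_efficiencies > 1))) {
    stop("stage efficiencies must lie in (0, 1]")
  }
  if (loop_transmission <= 0 || loop_transmission > 1) {
    stop("loop transmission must lie in (0, 1]")
  }
  if (loop_count < 0) stop("loop_count must be >= 0")
  loop_transmission^loop_count * prod(stage_efficiencies)
}
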