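#' Vertex subset detected by a collision-free pattern
#'
#' @param G a [weighted_graph()].
#' @param s either a 0/1 count vector of length `N` or an integer vector of
#'   detected mode indices (as stored in a [gbs_sample()] batch).
#' @return sorted integer vector of vertex indices.
#' @export
subgraph_from_pattern <- function(G, s) {
  stopifnot(inherits(G, "weighted_graph"))
  if (length(s) == G$N && all(s %in% c(0, 1))) {
    v <- which(s == 1)
  } else {
    v <- as.integer(s)
    if (any(duplicated(v))) stop("pattern has photon collisions")
    if (length(v) && (min(v) < 1L || max(v) > G$N)) {
      stop("pattern refers to modes outside 1..", G$N)
    }
  }
  sort(v)
}

is_clique <- function(G, v) {
  k <- length(v)
  if (k <= 1L) return(TRUE)
  sub <- G$A[v, v, drop = FALSE]
  sum(sub) == k * (k - 1)
}

clique_weight <- function(G, v) sum(G$omega[v])

#' Greedy shrinking of a vertex set to a clique
#'
#' While the induced subgraph is not complete, removes the vertex with the
#' minimum degree within the induced subgraph, breaking ties by minimum
#' weight and then uniformly at random (seeded). The empty set is a clique,
#' so the procedure always terminates.
#'
#' @param G a [weighted_graph()].
#' @param V vertex subset (integer indices).
#' @param seed RNG seed for the random tie-break.
#' @return integer vector: a clique contained in `V`.
#' @export
greedy_shrink <- function(G, V, seed = 1L) {
  stopifnot(inherits(G, "weighted_graph"))
  V <- sort(unique(as.integer(V)))
  with_seed(seed, {
    while (!is_clique(G, V)) {
      deg <- rowSums(G$A[V, V, drop = FALSE])
      cand <- V[deg == min(deg)]
      if (length(cand) > 1L) {
        w <- G$omega[cand]
        cand <- cand[w == min(w)]
      }
      drop <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
      V <- setdiff(V, drop)
    }
    V
  })
}

#' Local-search expansion of a clique
#'
#' Per iteration the set of vertices adjacent to every current member is
#' computed; if non-empty, the heaviest such vertex joins (ties broken at
#' random, seeded). When no vertex can be added, an optional swap move
#' removes one member and adds two new vertices, accepted only if it
#' increases the clique weight. The clique weight never decreases and the
#' fixed point is a maximal clique.
#'
#' @param G a [weighted_graph()].
#' @param C a clique of `G` (integer vertex indices).
#' @param iterations maximum number of moves.
#' @param seed RNG seed for tie-breaks.
#' @param swap enable the 1-out/2-in swap move (default `TRUE`).
#' @return integer vector: a maximal clique with weight `>=` the input's.
#' @export
local_search <- function(G, C, iterations = 30L, seed = 1L, swap = TRUE) {
  stopifnot(inherits(G, "weighted_graph"))
  C <- sort(unique(as.integer(C)))
  if (!is_clique(G, C)) stop("local_search requires a clique as input")
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      common <- common_neighbors(G, C)
      if (length(common) > 0L) {
        w <- G$omega[common]
        best <- common[w == max(w)]
        add <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
        C <- sort(c(C, add))
        next
      }
      if (!swap || length(C) == 0L) break
      move <- find_swap(G, C)
      if (is.null(move)) break
      C <- sort(c(setdiff(C, move$out), move$ins))
    }
    C
  })
}

common_neighbors <- function(G, C) {
  if (length(C) == 0L) return(seq_len(G$N))
  cnt <- colSums(G$A[C, , drop = FALSE])
  setdiff(which(cnt == length(C)), C)
}

# Best weight-improving 1-out/2-in swap, or NULL if none exists.
find_swap <- function(G, C) {
  best <- NULL
  best_gain <- 0
  for (out in C) {
    rest <- setdiff(C, out)
    cand <- common_neighbors(G, rest)
    cand <- setdiff(cand, out)
    if (length(cand) < 2L) next
    # pairs of candidates that are themselves adjacent
    sub <- G$A[cand, cand, drop = FALSE]
    pr <- which(upper.tri(sub) & sub == 1, arr.ind = TRUE)
    if (nrow(pr) == 0L) next
    gains <- G$omega[cand[pr[, 1L]]] + G$omega[cand[pr[, 2L]]] - G$omega[out]
    g <- max(gains)
    if (g > best_gain + 1e-12) {
      b <- which.max(gains)
      best <- list(out = out, ins = cand[pr[b, ]])
      best_gain <- g
    }
  }
  best
}

#' Exact maximum weighted clique
#'
#' Branch-and-bound over vertices ordered by descending weight, pruning any
#' branch whose current weight plus the total weight of the remaining
#' candidates cannot beat the incumbent. Deterministic; ties are resolved
#' toward the lexicographically smallest vertex set. Guarded to `N <= 40`
#' (desk scale).
#'
#' @param G a [weighted_graph()].
#' @param guard maximum allowed vertex count.
#' @return list with `vertices` (sorted integer vector), `weight`, `size`.
#' @export
max_weighted_clique_exact <- function(G, guard = 40L) {
  stopifnot(inherits(G, "weighted_graph"))
  if (G$N > guard) {
    stop("resource guard: exact solver limited to ", guard, " vertices")
  }
  ord <- order(G$omega, seq_len(G$N), decreasing = c(TRUE, FALSE),
               method = "radix")
  best <- list(vertices = integer(0), weight = 0)
  A <- G$A
  omega <- G$omega
  expand <- function(current, cw, cand) {
    if (length(cand) == 0L) {
      if (cw > best$weight + 1e-12 ||
          (abs(cw - best$weight) <= 1e-12 &&
           lex_less(current, best$vertices))) {
        best <<- list(vertices = sort(current), weight = cw)
      }
      return(invisible(NULL))
    }
    for (i in seq_along(cand)) {
      rest <- cand[i:length(cand)]
      if (cw + sum(omega[rest]) < best$weight - 1e-12) break
      v <- cand[i]
      newcand <- rest[-1L][A[v, rest[-1L]] == 1]
      expand(c(current, v), cw + omega[v], newcand)
    }
    # also consider stopping here (current may itself be maximal)
    if (cw > best$weight + 1e-12) {
      best <<- list(vertices = sort(current), weight = cw)
    }
    invisible(NULL)
  }
  expand(integer(0), 0, ord)
  list(vertices = best$vertices, weight = best$weight,
       size = length(best$vertices))
}

lex_less <- function(a, b) {
  a <- sort(a); b <- sort(b)
  n <- min(length(a), length(b))
  if (n > 0L) {
    d <- which(a[seq_len(n)] != b[seq_len(n)])
    if (length(d)) return(a[d[1L]] < b[d[1L]])
  }
  length(a) < length(b)
}

#' Run the sample-to-clique postprocessing pipeline
#'
#' For each sampled pattern: detected modes -> [greedy_shrink()] ->
#' [local_search()]. Cliques are tallied across samples; the success
#' probability is the fraction of postprocessed samples equal to the exact
#' maximum weighted clique. When several batches are supplied they are
#' treated as independent experimental replicates and per-replicate success
#' probabilities are reported alongside the pooled value.
#'
#' @param G a [weighted_graph()].
#' @param batch a [gbs_sample()] batch, or a list of batches (replicates).
#' @param n_post local-search iterations per sample (default 30).
#' @param seed RNG seed for the postprocessing tie-breaks.
#' @param swap passed to [local_search()].
#' @return object of class `clique_stats`: `table` (data frame with clique
#'   members, weight, size, count, probability), `success_probability`,
#'   `replicate_success`, `n_samples`, `max_clique`.
#' @export
run_clique_pipeline <- function(G, batch, n_post = 30L, seed = 1L,
                                swap = TRUE) {
  stopifnot(inherits(G, "weighted_graph"))
  batches <- if (inherits(batch, "sample_batch")) list(batch) else batch
  if (length(batches) == 0L ||
      !all(vapply(batches, inherits, logical(1), "sample_batch"))) {
    stop("batch must be a sample_batch or a non-empty list of them")
  }
  if (sum(vapply(batches, function(b) length(b$patterns), integer(1))) == 0L) {
    stop("empty batch")
  }
  target <- max_weighted_clique_exact(G)
  key_target <- paste(target$vertices, collapse = "|")
  tally <- new.env(parent = emptyenv())
  rep_succ <- numeric(length(batches))
  n_total <- 0L
  sub_seed <- seed
  for (bi in seq_along(batches)) {
    hits <- 0L
    for (p in batches[[bi]]$patterns) {
      sub_seed <- sub_seed + 1L
      v <- subgraph_from_pattern(G, p)
      cl <- greedy_shrink(G, v, seed = sub_seed)
      cl <- local_search(G, cl, iterations = n_post, seed = sub_seed,
                         swap = swap)
      key <- paste(cl, collapse = "|")
      cur <- if (!is.null(tally[[key]])) tally[[key]] else 0L
      tally[[key]] <- cur + 1L
      if (key == key_target) hits <- hits + 1L
      n_total <- n_total + 1L
    }
    rep_succ[bi] <- hits / max(length(batches[[bi]]$patterns), 1L)
  }
  keys <- ls(tally)
  counts <- vapply(keys, function(k) tally[[k]], integer(1))
  members <- lapply(strsplit(keys, "\\|"), function(x) as.integer(x[nzchar(x)]))
  tab <- data.frame(
    members = keys,
    weight = vapply(members, function(v) clique_weight(G, v), numeric(1)),
    size = lengths(members),
    count = as.integer(counts),
    probability = counts / n_total,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$probability, -tab$weight), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 success_probability = sum(counts[keys == key_target]) / n_total,
                 replicate_success = rep_succ,
                 n_samples = n_total,
                 max_clique = target),
            class = "clique_stats")
}

#' @export
print.clique_stats <- function(x, ...) {
  cat("Clique statistics over", x$n_samples, "postprocessed samples (",
      length(x$replicate_success), "replicate(s) )\n")
  cat("  max weighted clique: {", paste(x$max_clique$vertices, collapse = ", "),
      "} weight", format(x$max_clique$weight), "\n")
  cat("  success probability:", format(x$success_probability, digits = 4), "\n")
  invisible(x)
}

#' Uniform classical sampling baseline
#'
#' Draws vertex subsets uniformly at random with subset sizes matched to a
#' given photon-number histogram, for head-to-head comparison with GBS
#' sampling under identical postprocessing.
#'
#' @param G a [weighted_graph()].
#' @param k_distribution photon-number histogram: a named vector mapping
#'   photon number to probability (or counts; normalized internally).
#' @param n number of subsets to draw.
#' @param seed RNG seed.
#' @return a `sample_batch` of uniformly drawn subsets.
#' @export
uniform_baseline <- function(G, k_distribution, n, seed = 1L) {
  stopifnot(inherits(G, "weighted_graph"))
  ks <- as.integer(names(k_distribution))
  if (any(is.na(ks))) stop("k_distribution must be named by photon number")
  if (any(ks > G$N)) stop("photon number exceeds the vertex count")
  w <- as.numeric(k_distribution)
  if (any(w < 0) || sum(w) <= 0) stop("invalid k_distribution weights")
  with_seed(seed, {
    kk <- ks[sample.int(length(ks), n, replace = TRUE, prob = w)]
    patterns <- lapply(kk, function(k) sort(sample.int(G$N, k)))
    structure(list(patterns = patterns, N = G$N, seed = seed, eta = 1,
                   circuit_hash = "uniform-baseline"),
              class = "sample_batch")
  })
}
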