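#' Random weighted graph with a planted clique
#'
#' Emulates the structure of the artificially constructed benchmark graphs
#' used to demonstrate clique finding by sampling: an Erdos-Renyi background
#' on `N` vertices, a planted `k_planted`-clique, base vertex weights drawn
#' uniformly from `[0.5, 1]`, and the planted vertices' weights multiplied by
#' `weight_boost` so the planted clique is the weight target. The planted set
#' is returned as ground truth (whether it is in fact the maximum weighted
#' clique should be confirmed with [max_weighted_clique_exact()]; for large
#' boosts it always is).
#'
#' @param N vertex count (default 32).
#' @param k_planted planted clique size (default 6).
#' @param edge_p background edge probability (default 0.5).
#' @param weight_boost multiplier on planted-vertex weights (default 2).
#' @param seed RNG seed; identical seeds give identical graphs.
#' @return list with `graph` (a [weighted_graph()]) and `planted` (sorted
#'   vertex indices).
#' @export
planted_clique_graph <- function(N = 32L, k_planted = 6L, edge_p = 0.5,
                                 weight_boost = 2, seed = 1L) {
  if (k_planted > N) stop("k_planted must be <= N")
  if (edge_p < 0 || edge_p >= 1) stop("edge_p must lie in [0, 1)")
  if (weight_boost < 1) stop("weight_boost must be >= 1")
  with_seed(seed, {
    A <- matrix(0, N, N)
    up <- which(upper.tri(A))
    A[up] <- as.numeric(stats::runif(length(up)) < edge_p)
    A <- A + t(A)
    planted <- sort(sample.int(N, k_planted))
    A[planted, planted] <- 1
    diag(A) <- 0
    omega <- stats::runif(N, 0.5, 1)
    omega[planted] <- omega[planted] * weight_boost
    list(graph = weighted_graph(A, omega), planted = planted)
  })
}

#' Haar-random unitary matrix
#'
#' QR of a complex Ginibre matrix with the standard phase fix (diagonal of
#' `R` made real positive), giving the Haar measure on `U(N)`.
#'
#' @param N dimension.
#' @param seed RNG seed.
#' @return `N x N` complex unitary.
#' @export
haar_unitary <- function(N, seed = 1L) {
  with_seed(seed, {
    Z <- matrix(complex(real = stats::rnorm(N * N),
                        imaginary = stats::rnorm(N * N)), N) / sqrt(2)
    qq <- qr(Z)
    Q <- qr.Q(qq)
    d <- diag(qr.R(qq))
    Q %*% diag(d / abs(d), N)
  })
}

#' Synthetic rigid protein-ligand pharmacophore complex
#'
#' Generates a protein pharmacophore point cloud and a ligand that is a rigid
#' transform (random rotation + translation) of a subset of it, plus decoy
#' ligand points. The true contacts pair each transformed point with its
#' protein original using hydrogen-bond kinds (potential 1.0); decoys are
#' aromatic (potential 0.6). With coordinate noise below about half the
#' flexibility constant, the true contact set is a clique of the resulting
#' binding interaction graph and, having the largest total potential, its
#' maximum weighted clique.
#'
#' @param n_true_contacts number of true protein-ligand contacts (>= 1).
#' @param n_decoys number of decoy ligand points.
#' @param noise_A isotropic Gaussian positional noise (Angstrom) added to the
#'   transformed ligand points.
#' @param seed RNG seed.
#' @param box_A protein points are drawn uniformly in a cube of this side.
#' @return list with `protein`, `ligand` (pharmacophore tables) and
#'   `true_contacts` (data frame of protein_id/ligand_id pairs).
#' @export
rigid_complex <- function(n_true_contacts = 6L, n_decoys = 4L, noise_A = 0,
                          seed = 1L, box_A = 15) {
  if (n_true_contacts < 1L) stop("need at least one true contact")
  if (noise_A < 0) stop("noise_A must be >= 0")
  with_seed(seed, {
    n_p <- n_true_contacts + 2L  # extra protein points with no partner
    P <- matrix(stats::runif(3 * n_p, 0, box_A), ncol = 3)
    pk <- rep(c("HD", "HA"), length.out = n_p)
    protein <- data.frame(
      id = paste0("P", seq_len(n_p)), kind = pk,
      x = P[, 1], y = P[, 2], z = P[, 3], side = "protein",
      stringsAsFactors = FALSE
    )
    # random rotation via QR of a Gaussian matrix
    M <- matrix(stats::rnorm(9), 3)
    Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    shift <- stats::runif(3, -20, 20)
    Ltrue <- P[seq_len(n_true_contacts), , drop = FALSE] %*% t(Q)
    Ltrue <- Ltrue + matrix(shift, n_true_contacts, 3, byrow = TRUE)
    Ltrue <- Ltrue + matrix(stats::rnorm(3 * n_true_contacts, 0, noise_A),
                            ncol = 3)
    lig_kind <- ifelse(pk[seq_len(n_true_contacts)] == "HD", "HA", "HD")
    Ldec <- matrix(stats::runif(3 * n_decoys, 0, box_A), ncol = 3) +
      matrix(shift, max(n_decoys, 1L), 3, byrow = TRUE)[seq_len(n_decoys), ,
                                                        drop = FALSE]
    ligand <- data.frame(
      id = paste0("l", seq_len(n_true_contacts + n_decoys)),
      kind = c(lig_kind, rep("AR", n_decoys)),
      x = c(Ltrue[, 1], Ldec[, 1]),
      y = c(Ltrue[, 2], Ldec[, 2]),
      z = c(Ltrue[, 3], Ldec[, 3]),
      side = "ligand", stringsAsFactors = FALSE
    )
    list(protein = protein, ligand = ligand,
         true_contacts = data.frame(
           protein_id = protein$id[seq_len(n_true_contacts)],
           ligand_id = ligand$id[seq_len(n_true_contacts)],
           stringsAsFactors = FALSE))
  })
}

#' Designed RNA sequence with a known optimal fold
#'
#' Builds a sequence containing a set of nested stems with the requested
#' lengths (G/C arms separated by A spacers, closed by an A hairpin loop) and
#' verifies, through the package's own stem-graph pipeline, that the designed
#' structure is the unique maximum-weight fold. If a random arm choice
#' creates a spurious co-optimal fold the design is retried with a new
#' deterministic sub-seed.
#'
#' @param stem_lengths integer vector, outermost stem first; all lengths must
#'   be >= 3 so the default pipeline parameters can recover them.
#' @param seed RNG seed.
#' @param max_tries design retries before giving up.
#' @return list with `seq` (an [rna_sequence()]) and `reference` (two-column
#'   pair matrix of the designed structure).
#' @export
designed_rna <- function(stem_lengths, seed = 1L, max_tries = 50L) {
  stem_lengths <- as.integer(stem_lengths)
  if (length(stem_lengths) == 0L) stop("stem_lengths must be non-empty")
  if (any(stem_lengths < 3L)) {
    stop("stem lengths must be >= 3 (the pipeline's default minimum stem)")
  }
  for (try in seq_len(max_tries)) {
    cand <- with_seed(seed + 1000L * (try - 1L), {
      arms <- lapply(stem_lengths, function(L) {
        sample(c("G", "C"), L, replace = TRUE)
      })
      spacer <- c("A", "A")
      loop <- c("A", "A", "A", "A")
      left <- list()
      for (a in arms) left <- c(left, list(a, spacer))
      left[[length(left)]] <- NULL  # no spacer before the loop
      comp <- c(G = "C", C = "G")
      right <- list()
      for (a in rev(arms)) {
        right <- c(right, list(rev(unname(comp[a])), spacer))
      }
      right[[length(right)]] <- NULL
      bases <- c(unlist(left), loop, unlist(right))
      # designed pair coordinates
      pairs <- NULL
      pos <- 1L
      Ltot <- length(bases)
      lefts <- integer(0)
      for (ai in seq_along(arms)) {
        L <- stem_lengths[ai]
        lefts <- c(lefts, pos)
        pos <- pos + L + 2L
      }
      pos_r <- Ltot
      for (ai in seq_along(arms)) {
        L <- stem_lengths[ai]
        i0 <- lefts[ai]
        pairs <- rbind(pairs, cbind(i = i0 + seq_len(L) - 1L,
                                    j = pos_r - seq_len(L) + 1L))
        pos_r <- pos_r - L - 2L
      }
      list(seq = rna_sequence(paste(bases, collapse = ""),
                              id = sprintf("designed-%d", seed)),
           reference = pairs[order(pairs[, 1L]), , drop = FALSE])
    })
    if (design_is_unique_optimum(cand)) return(cand)
  }
  stop("design error: could not realize a unique optimal fold for lengths ",
       paste(stem_lengths, collapse = ","))
}

# Contract check: the WFSG's maximum-weight cliques map to exactly the
# designed structure.
design_is_unique_optimum <- function(cand) {
  wf <- build_wfsg(cand$seq, min_stem = 3L)
  if (wf$graph$N == 0L) return(FALSE)
  cl <- all_max_weight_cliques(wf$graph)
  if (length(cl) != 1L) return(FALSE)
  st <- clique_to_structure(cl[[1L]], wf$legend)
  setequal(pair_keys(st), pair_keys(cand$reference))
}
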