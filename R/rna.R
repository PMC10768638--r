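#' RNA sequence object
#'
#' @param bases character string over `A, C, G, U` (lower case accepted; `T`
#'   is mapped to `U` with a warning).
#' @param id sequence identifier (e.g. an accession number).
#' @return object of class `rna_sequence`: `id`, `bases` (character vector),
#'   `length`.
#' @export
rna_sequence <- function(bases, id = "seq") {
  b <- strsplit(toupper(gsub("\\s", "", bases)), "")[[1]]
  if (any(b == "T")) {
    warning("T mapped to U in sequence ", id)
    b[b == "T"] <- "U"
  }
  bad <- setdiff(unique(b), c("A", "C", "G", "U"))
  if (length(bad)) {
    stop("invalid base(s) in sequence ", id, ": ", paste(bad, collapse = ", "))
  }
  if (length(b) < 1L) stop("sequence must have length >= 1")
  structure(list(id = id, bases = b, length = length(b)),
            class = "rna_sequence")
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat("RNA sequence", x$id, "(", x$length, "nt )\n")
  invisible(x)
}

# Complementarity predicate for a pairing rule.
pairing_ok <- function(a, b, pairing = c("wobble", "wc")) {
  pairing <- match.arg(pairing)
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  if (pairing == "wc") return(wc)
  wc | (a == "G" & b == "U") | (a == "U" & b == "G")
}

#' Enumerate candidate stems of an RNA sequence
#'
#' A stem is a maximal run of consecutive complementary base pairs
#' `(i+t, j-t)`, `t = 0, ..., L-1`. Runs extend inward only while the hairpin
#' loop constraint `j' - i' - 1 >= min_loop` holds and are reported when
#' `L >= min_stem`. Ordered by `(i, j, L)`.
#'
#' @param seq an [rna_sequence()].
#' @param min_stem minimum stem length (default 3 base pairs).
#' @param min_loop minimum unpaired loop size enclosed by the innermost pair
#'   (default 3 nt).
#' @param pairing `"wobble"` (Watson-Crick plus G-U, default) or `"wc"`.
#' @return data frame with columns `i`, `j` (outermost pair, 1-based) and
#'   `length`.
#' @export
enumerate_stems <- function(seq, min_stem = 3L, min_loop = 3L,
                            pairing = c("wobble", "wc")) {
  stopifnot(inherits(seq, "rna_sequence"))
  pairing <- match.arg(pairing)
  if (min_stem < 1L) stop("min_stem must be >= 1")
  if (min_loop < 0L) stop("min_loop must be >= 0")
  b <- seq$bases
  L <- seq$length
  out <- list()
  # pairs (i, j) with i + j = s lie on one anti-diagonal; runs of consecutive
  # complementary pairs along it are the stems
  for (s in 3:(2 * L - 1)) {
    i0 <- max(1L, s - L)
    imax <- floor((s - 1) / 2)
    if (imax < i0) next
    ii <- i0:imax
    jj <- s - ii
    ok <- pairing_ok(b[ii], b[jj], pairing) & (jj - ii - 1L >= min_loop)
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      len <- r$lengths[q]
      if (len >= min_stem) {
        out[[length(out) + 1L]] <- c(i = ii[starts[q]], j = jj[starts[q]],
                                     length = len)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(i = integer(0), j = integer(0), length = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  df <- df[order(df$i, df$j, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

stem_pairs <- function(stem) {
  t <- seq_len(stem$length) - 1L
  cbind(i = stem$i + t, j = stem$j - t)
}

#' Can two stems co-exist in one secondary structure?
#'
#' False when the stems share a base, and (unless pseudoknots are allowed)
#' when any two of their base pairs cross (`i1 < i2 < j1 < j2`).
#'
#' @param s1,s2 single rows of an [enumerate_stems()] table.
#' @param allow_pseudoknots permit crossing stems (default `FALSE`).
#' @return logical.
#' @export
coexist <- function(s1, s2, allow_pseudoknots = FALSE) {
  p1 <- stem_pairs(s1)
  p2 <- stem_pairs(s2)
  if (length(intersect(c(p1), c(p2))) > 0L) return(FALSE)
  if (!allow_pseudoknots) {
    for (r in seq_len(nrow(p1))) {
      a <- p1[r, 1L]; bb <- p1[r, 2L]
      cross <- (a < p2[, 1L] & p2[, 1L] < bb & bb < p2[, 2L]) |
        (p2[, 1L] < a & a < p2[, 2L] & p2[, 2L] < bb)
      if (any(cross)) return(FALSE)
    }
  }
  TRUE
}

#' Build the weighted full stem graph (WFSG) of an RNA sequence
#'
#' Vertices are candidate stems weighted by their length; edges join stems
#' that can co-exist in one fold. The maximum weighted clique of the WFSG is
#' the stem set with the largest total paired length, i.e. the predicted
#' secondary structure.
#'
#' @param seq an [rna_sequence()].
#' @param min_stem,min_loop,pairing passed to [enumerate_stems()].
#' @param allow_pseudoknots passed to [coexist()].
#' @return list with `graph` (a [weighted_graph()], `omega` = stem lengths)
#'   and `legend` (the stem table, row `i` describing vertex `i`).
#' @export
build_wfsg <- function(seq, min_stem = 3L, min_loop = 3L,
                       pairing = c("wobble", "wc"),
                       allow_pseudoknots = FALSE) {
  pairing <- match.arg(pairing)
  stems <- enumerate_stems(seq, min_stem, min_loop, pairing)
  n <- nrow(stems)
  if (n == 0L) {
    warning("no stems: the stem graph is empty")
    return(list(graph = weighted_graph(matrix(0, 0, 0), numeric(0)),
                legend = stems))
  }
  A <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (coexist(stems[i, ], stems[j, ], allow_pseudoknots)) {
          A[i, j] <- A[j, i] <- 1
        }
      }
    }
  }
  labels <- paste0("stem(", stems$i, ",", stems$j, ")x", stems$length)
  list(graph = weighted_graph(A, stems$length, labels = labels),
       legend = stems)
}

#' Secondary structure from a stem clique
#'
#' Takes the union of the base pairs of the member stems. Cliques of a
#' pseudoknot-free WFSG always yield a valid nested structure; overlapping
#' pairs would indicate a broken co-existence graph and raise an error.
#'
#' @param clique integer vertex indices (or a [max_weighted_clique_exact()]
#'   result).
#' @param legend the stem table from [build_wfsg()].
#' @return two-column integer matrix of base pairs `(i, j)`, `i < j`, sorted
#'   by `i`.
#' @export
clique_to_structure <- function(clique, legend) {
  v <- if (is.list(clique)) clique$vertices else as.integer(clique)
  if (length(v) == 0L) return(cbind(i = integer(0), j = integer(0)))
  pairs <- do.call(rbind, lapply(v, function(k) stem_pairs(legend[k, ])))
  if (anyDuplicated(c(pairs))) {
    stop("internal invariant violated: clique stems share bases")
  }
  pairs[order(pairs[, 1L]), , drop = FALSE]
}

#' Matthews correlation coefficient for base-pair prediction
#'
#' Scores a predicted structure against a reference over the universe of all
#' `L(L-1)/2` unordered index pairs: `TP` = shared pairs, `FP` = predicted
#' only, `FN` = reference only, `TN` = the rest. Returns 0 when any
#' denominator factor vanishes (the usual convention).
#'
#' @param predicted,reference two-column matrices of base pairs.
#' @param L sequence length (must cover the largest index used).
#' @return value in `[-1, 1]`.
#' @export
mcc <- function(predicted, reference, L) {
  pk <- pair_keys(predicted)
  rk <- pair_keys(reference)
  idx <- c(predicted, reference)
  if (length(idx) && max(idx) > L) stop("L is smaller than the largest index")
  TP <- length(intersect(pk, rk))
  FP <- length(setdiff(pk, rk))
  FN <- length(setdiff(rk, pk))
  TN <- L * (L - 1) / 2 - TP - FP - FN
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / den
}

pair_keys <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0L) return(character(0))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  lo <- pmin(pairs[, 1L], pairs[, 2L])
  hi <- pmax(pairs[, 1L], pairs[, 2L])
  paste(lo, hi, sep = "-")
}

#' Predict RNA secondary structure through the stem-graph clique pipeline
#'
#' End-to-end convenience wrapper: build the WFSG, find all maximum weighted
#' cliques exactly, convert each to a structure and (optionally) score
#' against a reference. The paper-style readout reports every co-optimal
#' clique plus the best MCC.
#'
#' @param seq an [rna_sequence()].
#' @param reference optional reference structure (two-column pair matrix).
#' @param ... passed to [build_wfsg()].
#' @return list with `wfsg`, `cliques` (list of vertex sets), `structures`
#'   (list of pair matrices), and, if a reference was given, `mcc` (vector)
#'   and `best_mcc`.
#' @export
predict_rna_structure <- function(seq, reference = NULL, ...) {
  wf <- build_wfsg(seq, ...)
  if (wf$graph$N == 0L) {
    structs <- list(cbind(i = integer(0), j = integer(0)))
    cliques <- list(integer(0))
  } else {
    cliques <- all_max_weight_cliques(wf$graph)
    structs <- lapply(cliques, clique_to_structure, legend = wf$legend)
  }
  out <- list(wfsg = wf, cliques = cliques, structures = structs)
  if (!is.null(reference)) {
    out$mcc <- vapply(structs, mcc, numeric(1), reference = reference,
                      L = seq$length)
    out$best_mcc <- max(out$mcc)
  }
  out
}

#' All maximum-weight cliques of a small graph
#'
#' Exact enumeration of every clique attaining the maximum weight (ties are
#' scientifically meaningful here: co-optimal stem cliques are alternative
#' folds). Branch-and-bound seeded by [max_weighted_clique_exact()].
#'
#' @param G a [weighted_graph()].
#' @param tol weight tie tolerance.
#' @return list of sorted integer vertex vectors.
#' @export
all_max_weight_cliques <- function(G, tol = 1e-9) {
  best <- max_weighted_clique_exact(G)
  found <- list()
  expand <- function(current, cw, cand) {
    if (abs(cw - best$weight) <= tol &&
        length(common_neighbors(G, current)) == 0L) {
      found <<- c(found, list(sort(current)))
    }
    if (length(cand) == 0L) return(invisible(NULL))
    for (i in seq_along(cand)) {
      rest <- cand[i:length(cand)]
      if (cw + sum(G$omega[rest]) < best$weight - tol) break
      v <- cand[i]
      newcand <- rest[-1L][G$A[v, rest[-1L]] == 1]
      expand(c(current, v), cw + G$omega[v], newcand)
    }
    invisible(NULL)
  }
  ord <- order(G$omega, seq_len(G$N), decreasing = c(TRUE, FALSE),
               method = "radix")
  expand(integer(0), 0, ord)
  unique(found)
}

#' Dot-bracket notation for a nested structure
#'
#' @param pairs two-column pair matrix (must be pseudoknot-free).
#' @param L sequence length.
#' @return character string of `(`, `)`, `.`.
#' @export
structure_to_dotbracket <- function(pairs, L) {
  s <- rep(".", L)
  if (length(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    for (r in seq_len(nrow(pairs))) {
      a <- min(pairs[r, ]); b <- max(pairs[r, ])
      for (r2 in seq_len(nrow(pairs))) {
        a2 <- min(pairs[r2, ]); b2 <- max(pairs[r2, ])
        if (a < a2 && a2 < b && b < b2) {
          stop("structure contains a pseudoknot; dot-bracket unsupported")
        }
      }
      s[a] <- "("; s[b] <- ")"
    }
  }
  paste(s, collapse = "")
}
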