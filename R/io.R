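#' Read a vertex-weighted graph from an adjacency-matrix text file
#'
#' Accepts the adjacency dialect used throughout the toolkit: a square
#' numeric matrix, whitespace- or comma-delimited, optionally preceded by a
#' single-integer header line giving the dimension; `#` comment lines are
#' skipped. Vertex weights may be stored on the diagonal (they are extracted
#' and the diagonal zeroed, with a warning) or supplied in a sidecar file of
#' one weight per line via `weights`.
#'
#' @param path adjacency file.
#' @param weights optional path of a sidecar vertex-weight file (one numeric
#'   per line, or a single CSV column).
#' @param tol symmetry tolerance; asymmetric matrices are rejected with the
#'   offending entry's position.
#' @return a [weighted_graph()].
#' @export
read_adjacency <- function(path, weights = NULL, tol = 1e-9) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop(path, ": empty adjacency file")
  header_n <- NA_integer_
  first <- strsplit(lines[1], "[,[:space:]]+")[[1]]
  first <- first[nzchar(first)]
  if (length(first) == 1L && length(lines) > 1L &&
      !is.na(suppressWarnings(as.integer(first))) &&
      as.numeric(first) == round(as.numeric(first)) &&
      as.integer(first) == length(lines) - 1L) {
    header_n <- as.integer(first)
    lines <- lines[-1]
  }
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(lines[i], "[,[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v))) {
      stop(path, ": line ", i + ifelse(is.na(header_n), 0L, 1L),
           ": non-numeric entry")
    }
    v
  })
  N <- length(rows)
  if (any(lengths(rows) != N)) {
    stop(path, ": matrix is not square (", N, " rows, row lengths ",
         paste(unique(lengths(rows)), collapse = "/"), ")")
  }
  if (!is.na(header_n) && header_n != N) {
    stop(path, ": header says ", header_n, " but found ", N, " rows")
  }
  A <- do.call(rbind, rows)
  asym <- abs(A - t(A))
  if (N > 0 && max(asym) > tol) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(path, ": matrix asymmetric at (", w[1], ",", w[2], "): ",
         A[w[1], w[2]], " vs ", A[w[2], w[1]])
  }
  omega <- NULL
  if (!is.null(weights)) {
    if (!file.exists(weights)) stop("weight file not found: ", weights)
    wl <- readLines(weights, warn = FALSE)
    wl <- trimws(wl)
    wl <- wl[nzchar(wl) & !startsWith(wl, "#")]
    omega <- suppressWarnings(as.numeric(wl))
    if (any(is.na(omega))) stop(weights, ": non-numeric weight entry")
    if (length(omega) != N) {
      stop(weights, ": ", length(omega), " weights for ", N, " vertices")
    }
  }
  if (any(abs(diag(A)) > tol)) {
    if (!is.null(omega)) {
      stop(path, ": weights found both on the diagonal and in a sidecar file")
    }
    warning(path, ": vertex weights taken from the diagonal; diagonal zeroed")
    omega <- diag(A)
    diag(A) <- 0
  }
  weighted_graph(A, omega)
}

#' Write a vertex-weighted graph as an adjacency-matrix text file
#'
#' @param G a [weighted_graph()].
#' @param path output file.
#' @param weights_on_diagonal store `omega` on the diagonal (the compact
#'   dialect, default) instead of a sidecar file.
#' @param weights_path sidecar weight file to write when
#'   `weights_on_diagonal = FALSE`.
#' @return invisibly `path`.
#' @export
write_adjacency <- function(G, path, weights_on_diagonal = TRUE,
                            weights_path = NULL) {
  stopifnot(inherits(G, "weighted_graph"))
  A <- G$A
  if (weights_on_diagonal) {
    diag(A) <- G$omega
  } else if (!is.null(weights_path)) {
    writeLines(format(G$omega, digits = 15, trim = TRUE, scientific = FALSE),
               weights_path)
  }
  writeLines(apply(A, 1, function(r) {
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = " ")
  }), path)
  invisible(path)
}

#' Read RNA sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readBStringSet`; sequences are upper-cased
#' and DNA-style `T` is mapped to `U` with a warning.
#'
#' @param path FASTA file.
#' @return list of [rna_sequence()] objects, named by FASTA id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(ss), function(i) {
    id <- strsplit(names(ss)[i], "[[:space:]]")[[1]][1]
    rna_sequence(as.character(ss[[i]]), id = id)
  })
  names(out) <- vapply(out, function(s) s$id, character(1))
  out
}

#' Read pharmacophore points from CSV
#'
#' Expects the columns `id, kind, x, y, z, side` (Angstrom coordinates).
#'
#' @param path CSV file.
#' @return validated [pharmacophore_points()] data frame.
#' @export
read_pharmacophores <- function(path) {
  if (!file.exists(path)) stop("pharmacophore file not found: ", path)
  pharmacophore_points(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a reference secondary structure
#'
#' Two dialects: dot-bracket (the first non-comment line made of `(`, `)`,
#' `.` characters; an optional preceding sequence line is skipped) and
#' whitespace/comma-separated pair lists (`i j` per line, 1-based; CT-style
#' lines `i base j` with `j = 0` for unpaired are also understood).
#'
#' @param path structure file.
#' @return two-column integer matrix of base pairs.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, ">")]
  if (length(lines) == 0L) stop(path, ": empty structure file")
  db <- grep("^[().]+$", lines, value = TRUE)
  if (length(db) > 0L) {
    return(dotbracket_to_pairs(db[1]))
  }
  pairs <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "[,[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    v <- suppressWarnings(as.numeric(tok))
    num <- v[!is.na(v)]
    if (length(num) < 2L) stop(path, ": line ", i, ": cannot parse pair")
    a <- num[1]
    b <- num[length(num)]  # CT rows carry the partner in the last column
    if (b == 0) next
    if (a < b) pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  if (length(pairs) == 0L) return(cbind(i = integer(0), j = integer(0)))
  m <- do.call(rbind, pairs)
  m <- unique(m)
  colnames(m) <- c("i", "j")
  m[order(m[, 1]), , drop = FALSE]
}

dotbracket_to_pairs <- function(s) {
  ch <- strsplit(s, "")[[1]]
  stack <- integer(0)
  pairs <- list()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  if (length(pairs) == 0L) return(cbind(i = integer(0), j = integer(0)))
  m <- do.call(rbind, pairs)
  colnames(m) <- c("i", "j")
  m[order(m[, 1]), , drop = FALSE]
}

#' Serialize a sample batch
#'
#' Line-oriented record format: a JSON header line (seed, eta, mode count,
#' circuit hash) followed by one pattern per line as comma-separated detected
#' mode indices (empty line body for the vacuum pattern).
#'
#' @param batch a [gbs_sample()] batch.
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_sample_batch <- function(batch, path) {
  stopifnot(inherits(batch, "sample_batch"))
  header <- jsonlite::toJSON(
    list(N = batch$N, seed = batch$seed, eta = batch$eta,
         circuit_hash = batch$circuit_hash),
    auto_unbox = TRUE)
  body <- vapply(batch$patterns, paste, character(1), collapse = ",")
  writeLines(c(paste0("#", header), body), path)
  invisible(path)
}

#' @rdname write_sample_batch
#' @param path file written by [write_sample_batch()].
#' @export
read_sample_batch <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1], "#")) {
    stop(path, ": missing sample-batch header")
  }
  header <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  patterns <- lapply(lines[-1], function(l) {
    if (!nzchar(l)) return(integer(0))
    as.integer(strsplit(l, ",")[[1]])
  })
  structure(list(patterns = patterns, N = header$N, seed = header$seed,
                 eta = header$eta, circuit_hash = header$circuit_hash),
            class = "sample_batch")
}

#' Export clique statistics
#'
#' CSV table (members joined by `|`, weight, size, count, probability) plus a
#' JSON summary with the success probability and per-replicate values.
#'
#' @param stats a [run_clique_pipeline()] result.
#' @param csv_path,json_path output files (either may be `NULL`).
#' @return invisibly `NULL`.
#' @export
write_clique_stats <- function(stats, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(stats, "clique_stats"))
  if (!is.null(csv_path)) {
    utils::write.csv(stats$table, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(success_probability = stats$success_probability,
           replicate_success = stats$replicate_success,
           n_samples = stats$n_samples,
           max_clique = stats$max_clique),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
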