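#' Pharmacophore point table
#'
#' Validates a table of pharmacophore points: abstracted interaction features
#' (hydrogen-bond acceptor `HA`, donor `HD`, negative charge `NC`, aromatic
#' ring `AR`; the vocabulary is extensible) with 3-D coordinates in Angstrom
#' and a side (`protein` or `ligand`). By the field's convention protein
#' points are labelled in capitals and ligand points in lower case; kinds are
#' stored upper-case internally.
#'
#' @param df data frame with columns `id`, `kind`, `x`, `y`, `z`, `side`.
#' @param vocabulary allowed kinds (upper-case).
#' @return the validated data frame (kinds upper-cased).
#' @export
pharmacophore_points <- function(df, vocabulary = c("HA", "HD", "NC", "AR")) {
  need <- c("id", "kind", "x", "y", "z", "side")
  if (!all(need %in% names(df))) {
    stop("pharmacophore table must have columns ", paste(need, collapse = ", "))
  }
  df$kind <- toupper(as.character(df$kind))
  bad <- setdiff(unique(df$kind), vocabulary)
  if (length(bad)) {
    stop("unknown pharmacophore kind(s): ", paste(bad, collapse = ", "))
  }
  df$side <- tolower(as.character(df$side))
  if (!all(df$side %in% c("protein", "ligand"))) {
    stop("side must be 'protein' or 'ligand'")
  }
  for (cc in c("x", "y", "z")) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (any(!is.finite(df[[cc]]))) stop("non-finite coordinate in column ", cc)
  }
  df$id <- as.character(df$id)
  df
}

#' Default contact-potential table
#'
#' An editable knowledge-based default: hydrogen bonds (donor-acceptor in
#' either orientation) 1.0, charge-charge 0.8, aromatic-aromatic 0.6. Rows
#' absent from the table produce no contact vertex. Replace with a calibrated
#' table for real docking work.
#'
#' @return data frame with columns `protein_kind`, `ligand_kind`, `weight`.
#' @export
default_potential_table <- function() {
  data.frame(
    protein_kind = c("HD", "HA", "NC", "AR"),
    ligand_kind  = c("HA", "HD", "NC", "AR"),
    weight       = c(1.0, 1.0, 0.8, 0.6),
    stringsAsFactors = FALSE
  )
}

#' Flexibility rule for contact compatibility
#'
#' `tau` (flexibility constant) and `epsilon` (interaction distance), both in
#' Angstrom, define the geometric-compatibility band `tau + 2*epsilon`. In
#' `per_kind` mode both may be tables keyed by pharmacophore kind; the values
#' for a contact pair are resolved from the four kinds involved and combined
#' with `combine` (default `max`; `mean` and `min` are the alternatives).
#'
#' @param tau numeric constant or named vector by kind.
#' @param epsilon numeric constant or named vector by kind.
#' @param combine combination rule for per-kind mode.
#' @return object of class `flexibility_rule`.
#' @export
flexibility_rule <- function(tau = 1.0, epsilon = 0.5,
                             combine = c("max", "mean", "min")) {
  combine <- match.arg(combine)
  if (any(unlist(tau) < 0) || any(unlist(epsilon) < 0)) {
    stop("tau and epsilon must be >= 0")
  }
  mode <- if (length(tau) > 1L || length(epsilon) > 1L) "per_kind" else "constant"
  structure(list(mode = mode, tau = tau, epsilon = epsilon, combine = combine),
            class = "flexibility_rule")
}

resolve_flex <- function(rule, kinds) {
  pick <- function(tab) {
    if (length(tab) == 1L && is.null(names(tab))) return(rep(tab, length(kinds)))
    v <- tab[kinds]
    if (any(is.na(v))) stop("flexibility table missing kind(s): ",
                            paste(kinds[is.na(v)], collapse = ", "))
    v
  }
  comb <- switch(rule$combine, max = max, mean = mean, min = min)
  list(tau = comb(pick(rule$tau)), epsilon = comb(pick(rule$epsilon)))
}

#' Enumerate protein-ligand contacts
#'
#' One contact per (protein point, ligand point) pair whose kind pair appears
#' in the potential table; the contact weight is that table entry. Contacts
#' are ordered by (protein id, ligand id).
#'
#' @param protein,ligand [pharmacophore_points()] tables (the `side` column
#'   is checked).
#' @param potential_table data frame like [default_potential_table()].
#' @return data frame with columns `protein_id`, `ligand_id`, `protein_kind`,
#'   `ligand_kind`, `weight` and coordinate columns `px, py, pz, lx, ly, lz`.
#' @export
enumerate_contacts <- function(protein, ligand,
                               potential_table = default_potential_table()) {
  protein <- pharmacophore_points(protein)
  ligand <- pharmacophore_points(ligand)
  if (!all(protein$side == "protein")) stop("protein table has ligand points")
  if (!all(ligand$side == "ligand")) stop("ligand table has protein points")
  key <- paste(potential_table$protein_kind, potential_table$ligand_kind)
  out <- list()
  for (i in order(protein$id)) {
    for (j in order(ligand$id)) {
      m <- match(paste(protein$kind[i], toupper(ligand$kind[j])), key)
      if (is.na(m)) next
      out[[length(out) + 1L]] <- data.frame(
        protein_id = protein$id[i], ligand_id = ligand$id[j],
        protein_kind = protein$kind[i], ligand_kind = ligand$kind[j],
        weight = potential_table$weight[m],
        px = protein$x[i], py = protein$y[i], pz = protein$z[i],
        lx = ligand$x[j], ly = ligand$y[j], lz = ligand$z[j],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(protein_id = character(0), ligand_id = character(0),
                      protein_kind = character(0), ligand_kind = character(0),
                      weight = numeric(0), px = numeric(0), py = numeric(0),
                      pz = numeric(0), lx = numeric(0), ly = numeric(0),
                      lz = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Geometric compatibility of two contacts
#'
#' Two contacts are compatible (joined by an edge of the binding interaction
#' graph) when they share no pharmacophore point on either side and the
#' distance between their ligand points differs from the distance between
#' their protein points by at most `tau' + 2 epsilon'` (inclusive boundary),
#' with `tau'`, `epsilon'` resolved from the flexibility rule.
#'
#' @param c1,c2 single rows of an [enumerate_contacts()] table.
#' @param rule a [flexibility_rule()].
#' @return logical.
#' @export
compatible_edge <- function(c1, c2, rule = flexibility_rule()) {
  if (c1$protein_id == c2$protein_id || c1$ligand_id == c2$ligand_id) {
    return(FALSE)
  }
  dP <- sqrt((c1$px - c2$px)^2 + (c1$py - c2$py)^2 + (c1$pz - c2$pz)^2)
  dL <- sqrt((c1$lx - c2$lx)^2 + (c1$ly - c2$ly)^2 + (c1$lz - c2$lz)^2)
  fl <- resolve_flex(rule, c(c1$protein_kind, toupper(c1$ligand_kind),
                             c2$protein_kind, toupper(c2$ligand_kind)))
  abs(dL - dP) <= fl$tau + 2 * fl$epsilon
}

#' Build a binding interaction graph (BIG)
#'
#' Vertices are candidate protein-ligand contacts weighted by their
#' interaction potential; edges join geometrically compatible contacts. The
#' maximum weighted clique of a BIG is the predicted binding pose.
#'
#' @param protein,ligand pharmacophore tables.
#' @param potential_table contact potentials, see [default_potential_table()].
#' @param rule a [flexibility_rule()].
#' @return list with `graph` (a [weighted_graph()]) and `legend` (the contact
#'   table, row `i` describing vertex `i`).
#' @export
build_big <- function(protein, ligand,
                      potential_table = default_potential_table(),
                      rule = flexibility_rule()) {
  contacts <- enumerate_contacts(protein, ligand, potential_table)
  n <- nrow(contacts)
  if (n == 0L) {
    warning("no contacts: the binding interaction graph is empty")
    return(list(graph = weighted_graph(matrix(0, 0, 0), numeric(0)),
                legend = contacts))
  }
  A <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (compatible_edge(contacts[i, ], contacts[j, ], rule)) {
          A[i, j] <- A[j, i] <- 1
        }
      }
    }
  }
  labels <- paste0("(", contacts$protein_kind, ":", contacts$protein_id,
                   " - ", tolower(contacts$ligand_kind), ":",
                   contacts$ligand_id, ")")
  list(graph = weighted_graph(A, contacts$weight, labels = labels),
       legend = contacts)
}

#' Read a docking pose off a clique
#'
#' Maps the vertices of a clique in a binding interaction graph back to
#' protein-ligand pharmacophore pairings.
#'
#' @param clique integer vertex indices (or the list returned by
#'   [max_weighted_clique_exact()]).
#' @param legend the contact table from [build_big()].
#' @return data frame with `protein_id`, `ligand_id`, `weight` and a
#'   human-readable `label` per pairing.
#' @export
clique_to_pose <- function(clique, legend) {
  v <- if (is.list(clique)) clique$vertices else as.integer(clique)
  if (length(v) == 0L) {
    return(data.frame(protein_id = character(0), ligand_id = character(0),
                      weight = numeric(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  if (min(v) < 1L || max(v) > nrow(legend)) {
    stop("clique vertex outside the legend")
  }
  data.frame(
    protein_id = legend$protein_id[v],
    ligand_id = legend$ligand_id[v],
    weight = legend$weight[v],
    label = paste0("(", legend$protein_kind[v], legend$protein_id[v], " - ",
                   tolower(legend$ligand_kind[v]), legend$ligand_id[v], ")"),
    stringsAsFactors = FALSE
  )
}
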