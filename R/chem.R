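# Single-bond covalent radii in Angstrom (Cordero et al. 2008 consensus
# values; high-spin radii for first-row transition metals).
COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  NA. = 1.66, MG = 1.41, AL = 1.21, SI = 1.11, P = 1.07, S = 1.05,
  CL = 1.02, K = 2.03, CA = 1.76, MN = 1.61, FE = 1.52, CO = 1.50,
  NI = 1.24, CU = 1.32, ZN = 1.22, BR = 1.20, I = 1.39, SE = 1.20
)

#' Covalent radius of an element
#' @param elem character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom; unknown elements fall back
#'   to 0.77 with a warning.
#' @export
covalent_radius <- function(elem) {
  key <- toupper(elem)
  key[key == "NA"] <- "NA."
  r <- COVALENT_RADII[key]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(elem[is.na(r)]),
                                         collapse = ", "),
            "; using fallback covalent radius 0.77 Angstrom")
    r[is.na(r)] <- 0.77
  }
  unname(r)
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their frame-1 distance is at most the sum of
#' their covalent radii plus `slack`.  Hydrogen is special-cased:
#' hydrogen-hydrogen pairs are never bonded, and each hydrogen keeps only
#' the bond to its nearest heavy atom.
#'
#' @param ens a [conformer_ensemble()].
#' @param atom_subset indices of atoms to consider (default: all).
#' @param slack distance tolerance added to the radii sum, Angstrom.
#' @return An object of class `BondGraph`: list with `nodes` (atom
#'   indices) and `edges` (data.frame `i`, `j`, `length`), where `i < j`
#'   are global atom indices.
#' @export
infer_bonds <- function(ens, atom_subset = NULL, slack = 0.45) {
  stopifnot(inherits(ens, "ConformerEnsemble"))
  if (is.null(atom_subset)) atom_subset <- seq_len(nrow(ens$atoms))
  if (!length(atom_subset)) config_error("empty atom subset")
  x <- frame_coords(ens, 1L)[atom_subset, , drop = FALSE]
  elem <- ens$atoms$elem[atom_subset]
  rad <- covalent_radius(elem)
  n <- length(atom_subset)
  edges <- NULL
  if (n > 1L) {
    d <- as.matrix(stats::dist(x))
    cut <- outer(rad, rad, "+") + slack
    hit <- d <= cut & upper.tri(d)
    hit[elem == "H", elem == "H"] <- FALSE
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(i = atom_subset[idx[, 1]],
                          j = atom_subset[idx[, 2]],
                          length = d[idx])
      # each hydrogen bonds to its nearest heavy atom only
      for (h in which(elem == "H")) {
        gh <- atom_subset[h]
        inv <- which(edges$i == gh | edges$j == gh)
        if (length(inv) > 1L)
          edges <- edges[-setdiff(inv, inv[which.min(edges$length[inv])]), ]
      }
      swap <- edges$i > edges$j
      tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]
      edges$j[swap] <- tmp
      edges <- edges[order(edges$i, edges$j), ]
      rownames(edges) <- NULL
    }
  }
  if (is.null(edges))
    edges <- data.frame(i = integer(), j = integer(), length = numeric())
  structure(list(nodes = atom_subset, edges = edges), class = "BondGraph")
}

#' @export
print.BondGraph <- function(x, ...) {
  cat(sprintf("BondGraph: %d atoms, %d bonds\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Atoms bonded to a given atom
#' @param graph a [infer_bonds()] bond graph.
#' @param i global atom index.
#' @return Integer vector of bonded atom indices.
#' @export
bond_neighbors <- function(graph, i) {
  e <- graph$edges
  sort(c(e$j[e$i == i], e$i[e$j == i]))
}

# Bond-separation (graph distance) between two atoms, Inf if disconnected.
bond_separation <- function(graph, from, to) {
  if (from == to) return(0L)
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = graph$nodes))
  d <- igraph::distances(g, v = as.character(from), to = as.character(to))
  as.vector(d)
}

# Enumerate simple rings (size 3..max_size).  Each ring is reported once,
# anchored at its smallest member.  Fine for substrate-sized graphs.
find_rings <- function(graph, max_size = 6L) {
  adj <- lapply(graph$nodes, function(v) bond_neighbors(graph, v))
  names(adj) <- as.character(graph$nodes)
  rings <- list()
  walk <- function(path, start) {
    v <- path[length(path)]
    for (w in adj[[as.character(v)]]) {
      if (w == start && length(path) >= 3L) {
        # canonical: anchored at min, second-smallest neighbour direction
        if (path[2L] < path[length(path)])
          rings[[length(rings) + 1L]] <<- path
      } else if (w > start && !(w %in% path) && length(path) < max_size) {
        walk(c(path, w), start)
      }
    }
  }
  for (v in sort(graph$nodes)) walk(v, v)
  rings
}

# Max deviation of points from their least-squares plane.
plane_deviation <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  max(abs(xc %*% sv$v[, 3]))
}
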