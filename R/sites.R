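#' Classify candidate aliphatic C-H sites of a substrate
#'
#' Scans the substrate carbons and keeps those plausibly bearing an
#' abstractable sp3 hydrogen: 1-3 heavy neighbours, not a carbonyl carbon
#' (no C-O bond shorter than 1.30 Angstrom), and not part of a planar
#' ring whose members all have three bonds (the aromatic proxy; maximum
#' deviation from the ring least-squares plane below 0.1 Angstrom).
#' Heavy-neighbour counts 1/2/3 map to site classes CH3/CH2/CH.
#'
#' Deposited atom names rarely carry a paper's site numbering, so site
#' labels come from the `labels` map; unlabelled carbons keep their atom
#' name as label unless `labeled_only = TRUE`.
#'
#' @param graph bond graph from [infer_bonds()] covering the substrate.
#' @param ens the [conformer_ensemble()] the graph refers to.
#' @param substrate_atoms indices of the substrate atoms.
#' @param labels optional named character vector mapping atom names to
#'   site labels (e.g. `c("C7" = "C-7")`).
#' @param labeled_only drop carbons without an entry in `labels`.
#' @param substrate_id optional compound identifier stored in the map.
#' @return An object of class `SubstrateSiteMap`: list with
#'   `substrate_id` and `sites`, a named list of sites, each holding
#'   `label`, `carbon_index`, `site_class`, `heavy_neighbors`,
#'   `hydrogen_indices` (explicit hydrogens, possibly empty) and
#'   `methyl_ref` (torsion reference for CH3 hydrogen placement).
#' @export
classify_carbon_sites <- function(graph, ens, substrate_atoms,
                                  labels = NULL, labeled_only = FALSE,
                                  substrate_id = NULL) {
  stopifnot(inherits(graph, "BondGraph"),
            inherits(ens, "ConformerEnsemble"))
  a <- ens$atoms
  x <- frame_coords(ens, 1L)
  if (!all(substrate_atoms %in% graph$nodes))
    config_error("bond graph does not cover all substrate atoms")

  # ring members failing the aromatic proxy
  aromatic <- integer()
  for (ring in find_rings(graph)) {
    degs <- vapply(ring, function(v) length(bond_neighbors(graph, v)),
                   integer(1))
    if (all(degs == 3L) && plane_deviation(x[ring, , drop = FALSE]) < 0.1)
      aromatic <- union(aromatic, ring)
  }

  sites <- list()
  for (ci in substrate_atoms[a$elem[substrate_atoms] == "C"]) {
    nb <- bond_neighbors(graph, ci)
    heavy <- nb[a$elem[nb] != "H"]
    nh <- length(heavy)
    if (nh < 1L || nh > 3L) next
    if (ci %in% aromatic) next
    # carbonyl exclusion: any short C-O bond
    e <- graph$edges
    o_len <- c(e$length[e$i == ci & a$elem[e$j] == "O"],
               e$length[e$j == ci & a$elem[e$i] == "O"])
    if (any(o_len < 1.30)) next
    name <- a$name[ci]
    lab <- if (!is.null(labels) && name %in% names(labels))
      unname(labels[name]) else name
    if (labeled_only && (is.null(labels) || !(name %in% names(labels))))
      next
    hyd <- nb[a$elem[nb] == "H"]
    ref <- NA_integer_
    if (nh == 1L) {
      cand <- setdiff(bond_neighbors(graph, heavy), ci)
      cand <- cand[a$elem[cand] != "H"]
      if (length(cand)) ref <- min(cand)
    }
    sites[[lab]] <- list(label = lab, carbon_index = ci,
                         site_class = c("CH3", "CH2", "CH")[nh],
                         heavy_neighbors = heavy,
                         hydrogen_indices = hyd,
                         methyl_ref = ref)
  }
  if (anyDuplicated(names(sites)))
    config_error("duplicate site labels in classification")
  structure(list(substrate_id = substrate_id, sites = sites),
            class = "SubstrateSiteMap")
}

#' @export
print.SubstrateSiteMap <- function(x, ...) {
  cat(sprintf("SubstrateSiteMap%s: %d site(s)\n",
              if (!is.null(x$substrate_id))
                paste0(" [substrate ", x$substrate_id, "]") else "",
              length(x$sites)))
  for (s in x$sites)
    cat(sprintf("  %-6s %s atom %d (%d explicit H)\n", s$label,
                s$site_class, s$carbon_index, length(s$hydrogen_indices)))
  invisible(x)
}

#' Site labels of a site map
#' @param sites a [classify_carbon_sites()] map.
#' @return character vector of labels.
#' @export
site_labels <- function(sites) {
  stopifnot(inherits(sites, "SubstrateSiteMap"))
  vapply(sites$sites, `[[`, character(1), "label")
}

#' Shipped site-label vocabularies for the pathway substrates
#'
#' Returns the default atom-name to site-label maps for the
#' diketopiperazine intermediates (substrates 1-3) as generated by
#' [build_dkp()].  Stored as YAML under `inst/extdata/site_labels.yaml`
#' so users can adapt the file for deposited structures whose atom names
#' differ.
#'
#' @param substrate_id 1, 2 or 3; `NULL` returns the full list.
#' @return Named character vector (or list of them).
#' @export
default_site_labels <- function(substrate_id = NULL) {
  path <- system.file("extdata", "site_labels.yaml", package = "nacsel")
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg, function(m) unlist(m))
  if (is.null(substrate_id)) return(out)
  key <- paste0("substrate_", substrate_id)
  if (!key %in% names(out))
    config_error(sprintf("no shipped site labels for substrate '%s'",
                         substrate_id))
  out[[key]]
}
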