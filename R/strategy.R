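#' Detect a directing-group hydrogen bond near the reacting carbon
#'
#' A substrate hydroxyl can act as a directing group: anchored by a
#' hydrogen bond to a polar enzyme atom, it holds a neighbouring C-H
#' over the ferryl oxygen.  Evidence requires (a) a substrate hydroxyl
#' oxygen within `max_bond_separation` covalent bonds of the reacting
#' carbon (default 2, the vicinal-hydroxyl relationship) and (b) that
#' oxygen within `cutoff` of a protein-side O or N.  Detection is
#' heavy-atom distance only - crystal models carry no polar hydrogens -
#' with the conventional 3.5 Angstrom cutoff.
#'
#' Hydroxyl oxygens are recognised as substrate oxygens bonded to exactly
#' one heavy atom through a bond of at least 1.30 Angstrom (shorter C-O
#' bonds are carbonyls).
#'
#' @param ens a [conformer_ensemble()]; frame `frame` is analysed.
#' @param graph bond graph covering the substrate atoms.
#' @param sites substrate site map ([classify_carbon_sites()]).
#' @param reacting_site site label of the observed hydroxylation site.
#' @param enzyme_polar_atoms indices of candidate enzyme-side partners;
#'   defaults to all O/N atoms of polymer records.
#' @param cutoff heavy-atom hydrogen-bond distance cutoff, Angstrom.
#' @param max_bond_separation maximum covalent-bond distance between the
#'   hydroxyl oxygen and the reacting carbon.
#' @param frame frame index.
#' @return Object of class `HBondEvidence`: list with `present`,
#'   `pairs` (data.frame `substrate_o`, `partner`, `distance`) and
#'   `directing_hydroxyl_site_distance_bonds`.
#' @export
detect_directing_contact <- function(ens, graph, sites, reacting_site,
                                     enzyme_polar_atoms = NULL,
                                     cutoff = 3.5,
                                     max_bond_separation = 2L,
                                     frame = 1L) {
  stopifnot(inherits(ens, "ConformerEnsemble"),
            inherits(graph, "BondGraph"),
            inherits(sites, "SubstrateSiteMap"))
  if (!reacting_site %in% site_labels(sites))
    config_error(sprintf("reacting site '%s' not in site map",
                         reacting_site))
  a <- ens$atoms
  x <- frame_coords(ens, frame)
  if (is.null(enzyme_polar_atoms))
    enzyme_polar_atoms <- which(a$kind == "polymer" & a$elem %in% c("O", "N"))
  rc <- sites$sites[[reacting_site]]$carbon_index

  # substrate hydroxyl oxygens within the bond-separation budget
  sub_o <- intersect(graph$nodes, which(a$elem == "O"))
  hydroxyl <- sub_o[vapply(sub_o, function(o) {
    nb <- bond_neighbors(graph, o)
    heavy <- nb[a$elem[nb] != "H"]
    if (length(heavy) != 1L) return(FALSE)
    e <- graph$edges
    len <- c(e$length[e$i == o & e$j == heavy],
             e$length[e$j == o & e$i == heavy])
    len[1] >= 1.30
  }, logical(1))]

  pairs <- NULL
  sep_used <- NA_integer_
  for (o in hydroxyl) {
    sep <- bond_separation(graph, o, rc)
    if (!is.finite(sep) || sep > max_bond_separation) next
    if (length(enzyme_polar_atoms)) {
      d <- sqrt(rowSums((x[enzyme_polar_atoms, , drop = FALSE] -
                           matrix(x[o, ], length(enzyme_polar_atoms), 3,
                                  byrow = TRUE))^2))
      hit <- which(d <= cutoff)
      if (length(hit)) {
        pairs <- rbind(pairs, data.frame(substrate_o = o,
                                         partner = enzyme_polar_atoms[hit],
                                         distance = d[hit]))
        sep_used <- as.integer(sep)
      }
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(substrate_o = integer(), partner = integer(),
                        distance = numeric())
  structure(list(present = nrow(pairs) > 0L, pairs = pairs,
                 directing_hydroxyl_site_distance_bonds = sep_used,
                 cutoff = cutoff),
            class = "HBondEvidence")
}

#' @export
print.HBondEvidence <- function(x, ...) {
  cat(sprintf("Directing-group evidence: %s (%d pair(s), cutoff %g A)\n",
              if (x$present) "present" else "absent", nrow(x$pairs),
              x$cutoff))
  invisible(x)
}

#' Classify the enzyme's C-H site-selectivity strategy
#'
#' Three mutually exclusive calls:
#'
#' * `substrate_control` - the observed site is the inherently most
#'   reactive one; the enzyme merely exploits innate reactivity.
#' * `directing_group_control` - observed differs from inherent and a
#'   substrate hydroxyl adjacent to the reacting carbon hydrogen-bonds
#'   to the enzyme, re-orienting the substrate.
#' * `steric_control` - observed differs from inherent with no directing
#'   contact; the pocket shape overrides innate reactivity.
#'
#' @param inherent result of [inherent_site()], or a bare site label.
#' @param observed observed hydroxylation site label (experimental, or
#'   the top-ranked site from [predict_sites()]).
#' @param evidence a [detect_directing_contact()] result, or `NULL`
#'   (treated as no evidence).
#' @param enzyme optional enzyme name for the narrative.
#' @param observed_source provenance of `observed` recorded in the
#'   narrative (e.g. `"experiment"` or `"nac_prediction"`).
#' @return Object of class `StrategyCall`: list with `strategy`,
#'   `inherent_site`, `observed_site`, `evidence` and `narrative`.
#' @export
classify_strategy <- function(inherent, observed, evidence = NULL,
                              enzyme = NULL,
                              observed_source = "experiment") {
  if (is.list(inherent)) {
    if (isTRUE(inherent$tie))
      compute_error(paste0(
        "classification refused: inherent reactivity is tied between ",
        paste(inherent$site_label, collapse = ", "),
        "; resolve the tie (add barrier entries) before classifying"))
    inh_label <- inherent$site_label
    inh_barrier <- inherent$barrier
  } else {
    inh_label <- inherent
    inh_barrier <- NA_real_
  }
  if (!nzchar(inh_label) || !nzchar(observed))
    config_error("both inherent and observed site labels are required")
  ev_present <- !is.null(evidence) && isTRUE(evidence$present)
  strategy <- if (observed == inh_label) "substrate_control"
  else if (ev_present) "directing_group_control"
  else "steric_control"
  who <- if (is.null(enzyme)) "the enzyme" else enzyme
  narrative <- sprintf(paste0(
    "%s hydroxylates %s (source: %s); the inherently most reactive site is %s%s. ",
    "Directing-group contact: %s. Call: %s."),
    who, observed, observed_source, inh_label,
    if (is.na(inh_barrier)) "" else
      sprintf(" (barrier %.1f kcal/mol)", inh_barrier),
    if (ev_present) sprintf("present (%d hydrogen-bond pair(s))",
                            nrow(evidence$pairs)) else "absent",
    strategy)
  structure(list(strategy = strategy, inherent_site = inh_label,
                 inherent_barrier = inh_barrier, observed_site = observed,
                 evidence = evidence, narrative = narrative),
            class = "StrategyCall")
}

#' @export
print.StrategyCall <- function(x, ...) {
  cat("StrategyCall:", x$strategy, "\n  ", x$narrative, "\n", sep = "")
  invisible(x)
}
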