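#' Near-attack-conformation criterion
#'
#' A substrate pose is counted as an active (near-attack) conformation
#' for a site when the ferryl oxygen-to-hydrogen distance is at most
#' `d_max` and the O-H-C angle (vertex at the hydrogen) lies within
#' `theta_center +/- theta_tol`.  Defaults are the operative values for
#' aKGD hydrogen abstraction: 2.8 Angstrom and 170 +/- 15 degrees.  All
#' boundaries are inclusive, and the angle window is capped at 180
#' degrees (the geometric maximum).
#'
#' @param d_max maximum O...H distance, Angstrom.
#' @param theta_center,theta_tol centre and half-width of the O-H-C
#'   angle window, degrees.
#' @return A list of class `nac_criteria`.
#' @export
nac_criteria <- function(d_max = 2.8, theta_center = 170, theta_tol = 15) {
  if (!is.finite(d_max) || d_max <= 0)
    config_error("d_max must be positive")
  if (!is.finite(theta_center) || theta_center <= 0 || theta_center > 180)
    config_error("theta_center must be in (0, 180]")
  if (!is.finite(theta_tol) || theta_tol < 0)
    config_error("theta_tol must be non-negative")
  structure(list(d_max = d_max, theta_center = theta_center,
                 theta_tol = theta_tol), class = "nac_criteria")
}

#' @export
print.nac_criteria <- function(x, ...) {
  cat(sprintf("NAC criteria: d(O-H) <= %g Angstrom, theta(O-H-C) in %g +/- %g deg\n",
              x$d_max, x$theta_center, x$theta_tol))
  invisible(x)
}

#' Abstraction geometry of one O/H/C triple
#'
#' @param O,H,C numeric 3-vectors (Angstrom): ferryl oxygen, substrate
#'   hydrogen, substrate carbon.
#' @return List with `d_OH` (Angstrom) and `theta_OHC` (degrees, vertex
#'   at H).
#' @examples
#' oh_geometry(c(0, 0, 3), c(0, 0, 1), c(0, 0, 0))  # d 2, theta 180
#' @export
oh_geometry <- function(O, H, C) {
  a <- O - H; b <- C - H
  na <- vnorm(a); nb <- vnorm(b)
  if (na < 1e-9 || nb < 1e-9)
    compute_error("coincident points in oh_geometry")
  ct <- sum(a * b) / (na * nb)
  ct <- min(1, max(-1, ct))
  list(d_OH = na, theta_OHC = acos(ct) * 180 / pi)
}

#' Does a geometry record satisfy the NAC criterion?
#'
#' @param rec list with `d_OH` and `theta_OHC` (as [oh_geometry()]), or a
#'   numeric distance when `theta` is given separately.
#' @param crit a [nac_criteria()].
#' @param theta angle in degrees when `rec` is a bare distance.
#' @return logical.
#' @export
is_active <- function(rec, crit = nac_criteria(), theta = NULL) {
  if (is.numeric(rec) && !is.null(theta))
    rec <- list(d_OH = rec, theta_OHC = theta)
  lo <- crit$theta_center - crit$theta_tol
  hi <- min(crit$theta_center + crit$theta_tol, 180)
  rec$d_OH <= crit$d_max & rec$theta_OHC >= lo & rec$theta_OHC <= hi
}

#' Count near-attack conformations per site over an ensemble
#'
#' For every frame and candidate site, the site is active in that frame
#' if ANY of its hydrogens satisfies the criterion against the ferryl
#' oxygen (a methyl reacts through whichever hydrogen it presents).
#' Hydrogens explicit in the model are used verbatim; otherwise they are
#' placed at ideal geometry by [place_site_hydrogens()].
#'
#' @param ens a [conformer_ensemble()].
#' @param sites a [classify_carbon_sites()] site map.
#' @param oxo_index atom index of the ferryl oxygen (see
#'   [identify_oxo()]), or an explicit proxy for resting-state models.
#' @param crit a [nac_criteria()].
#' @param rotamers methyl rotor orientations scored per CH3 site (the
#'   best-scoring hydrogen wins; 1 = single staggered rotor).
#' @param keep_records retain the per-frame, per-hydrogen geometry table.
#' @return An object of class `NACSummary`: list with `n_frames`,
#'   `per_site` (data.frame `site`, `n_active`, `fraction`,
#'   `mean_d_active` - the mean over active frames of the minimal
#'   qualifying O...H distance, NA when a site is never active),
#'   `criteria`, and optionally `records`.
#' @export
tally_ensemble <- function(ens, sites, oxo_index, crit = nac_criteria(),
                           rotamers = 1L, keep_records = FALSE) {
  stopifnot(inherits(ens, "ConformerEnsemble"),
            inherits(sites, "SubstrateSiteMap"),
            inherits(crit, "nac_criteria"))
  if (ens$n_frames < 1L) config_error("empty ensemble")
  if (ens$atoms$elem[oxo_index] != "O")
    config_error(sprintf("oxo_index %d is element %s, not oxygen",
                         oxo_index, ens$atoms$elem[oxo_index]))
  if (!length(sites$sites))
    config_error("site map holds no candidate sites")

  labs <- site_labels(sites)
  nf <- ens$n_frames
  n_active <- setNames(integer(length(labs)), labs)
  d_sum <- setNames(numeric(length(labs)), labs)
  records <- if (keep_records) vector("list", nf * length(labs)) else NULL
  ri <- 0L
  for (f in seq_len(nf)) {
    x <- ens$frames[[f]]
    O <- x[oxo_index, ]
    for (s in sites$sites) {
      H <- place_site_hydrogens(s, x, rotamers = rotamers)
      C <- x[s$carbon_index, ]
      dv <- sqrt(rowSums(sweep(H, 2, O)^2))
      b <- sweep(H, 2, C) * -1            # H -> C
      a <- sweep(H, 2, O) * -1            # H -> O
      ct <- rowSums(a * b) / (dv * sqrt(rowSums(b^2)))
      th <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
      ok <- is_active(dv, crit, theta = th)
      if (any(ok)) {
        n_active[s$label] <- n_active[s$label] + 1L
        d_sum[s$label] <- d_sum[s$label] + min(dv[ok])
      }
      if (keep_records) {
        ri <- ri + 1L
        records[[ri]] <- data.frame(
          frame = f, site = s$label, hydrogen = seq_along(dv),
          d_OH = dv, theta_OHC = th, active = ok)
      }
    }
  }
  per_site <- data.frame(
    site = labs,
    n_active = as.integer(n_active),
    fraction = as.numeric(n_active) / nf,
    mean_d_active = ifelse(n_active > 0, d_sum / pmax(n_active, 1L), NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(n_frames = nf, per_site = per_site, criteria = crit)
  if (keep_records) out$records <- do.call(rbind, records[seq_len(ri)])
  structure(out, class = "NACSummary")
}

#' @export
print.NACSummary <- function(x, ...) {
  cat(sprintf("NAC tally over %d frame(s)\n", x$n_frames))
  print(x$per_site, row.names = FALSE)
  invisible(x)
}

#' Rank predicted hydroxylation sites from a NAC tally
#'
#' Sites with at least one active conformation, sorted by descending
#' count; ties broken by ascending mean qualifying O...H distance, then
#' lexicographic label.  An empty data frame means no site ever reached
#' a near-attack pose.
#'
#' @param summary a [tally_ensemble()] result.
#' @return data.frame `site`, `n_active`, `fraction`, `mean_d_active`.
#' @export
predict_sites <- function(summary) {
  stopifnot(inherits(summary, "NACSummary"))
  ps <- summary$per_site[summary$per_site$n_active > 0, , drop = FALSE]
  if (!nrow(ps)) return(ps)
  ps <- ps[order(-ps$n_active, ps$mean_d_active, ps$site), , drop = FALSE]
  rownames(ps) <- NULL
  ps
}
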