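# Internal-coordinate (NeRF) placement: position a new atom bonded to c,
# with angle x-c-b and dihedral x-c-b-a, lengths in Angstrom, angles in
# degrees.
place_internal <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  c + (-bond * cos(ang)) * bc +
    (bond * sin(ang) * cos(tor)) * m +
    (bond * sin(ang) * sin(tor)) * n
}

# Rotation taking unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  w <- vcross(u, v)
  s <- vnorm(w); cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unitv(vcross(u, p))
    return(rotation_axis(ax, pi))
  }
  rotation_axis(w / s, atan2(s, cth))
}

# Rotation about a unit axis by angle (radians).
rotation_axis <- function(ax, th) {
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation matrix from a (not necessarily unit) quaternion.
quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# tiny accumulator for synthetic structures
.new_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$name <- character(); b$elem <- character(); b$resname <- character()
  b$resid <- integer(); b$kind <- character(); b$xyz <- list()
  b
}
.add_atom <- function(b, name, elem, resname, resid, pos, kind = "hetero") {
  b$name <- c(b$name, name); b$elem <- c(b$elem, elem)
  b$resname <- c(b$resname, resname); b$resid <- c(b$resid, resid)
  b$kind <- c(b$kind, kind); b$xyz[[length(b$xyz) + 1L]] <- pos
  length(b$name)
}
.builder_ensemble <- function(b, chain = "A") {
  atoms <- data.frame(serial = seq_along(b$name), name = b$name,
                      elem = b$elem, resname = b$resname, resid = b$resid,
                      chain = chain, kind = b$kind,
                      stringsAsFactors = FALSE)
  conformer_ensemble(atoms, list(do.call(rbind, b$xyz)))
}

#' Build a truncated Fe(IV)-oxo active-site model (theozyme)
#'
#' An idealised first-shell model of an aKGD iron centre: octahedral
#' Fe(IV) with the oxo oxygen on +z, two methylimidazole nitrogen donors
#' (histidine mimics) on +/-x, two acetate oxygen donors (aspartate and
#' succinate mimics) on +/-y, and one water oxygen trans to the oxo.
#' Iron sits at the origin.  The default ferryl bond length of 1.62
#' Angstrom is a conventional spectroscopic value and is configurable.
#'
#' @param fe_oxo_length Fe=O bond length, Angstrom.
#' @return A single-frame [conformer_ensemble()] on which
#'   [identify_oxo()] succeeds.
#' @export
build_theozyme <- function(fe_oxo_length = 1.62) {
  if (!is.finite(fe_oxo_length) || fe_oxo_length <= 0)
    config_error("fe_oxo_length must be positive")
  b <- .new_builder()
  .add_atom(b, "FE", "FE", "FE", 1L, c(0, 0, 0))
  .add_atom(b, "O1", "O", "OXO", 2L, c(0, 0, fe_oxo_length))

  # methylimidazoles: planar 5-ring, coordinating N toward Fe on +/-x
  ring_side <- 1.37
  rc <- ring_side / (2 * sin(pi / 5))
  mim <- function(sgn, resid) {
    ctr <- c(sgn * (2.1 + rc), 0, 0)
    elems <- c("N", "C", "N", "C", "C")
    names <- c("N1", "C2", "N3", "C4", "C5")
    for (k in 0:4) {
      th <- pi + k * 2 * pi / 5
      pos <- ctr + rc * c(sgn * cos(th), sin(th), 0)
      .add_atom(b, names[k + 1], elems[k + 1], "MIM", resid, pos)
    }
    th <- pi + 2 * 2 * pi / 5            # methyl on N3, radially outward
    pos <- ctr + (rc + 1.47) * c(sgn * cos(th), sin(th), 0)
    .add_atom(b, "C6", "C", "MIM", resid, pos)
  }
  mim(+1, 3L); mim(-1, 4L)

  # acetates: coordinating carboxylate O toward Fe on +/-y
  act <- function(sgn, resid) {
    fe <- c(0, 0, 0)
    o1 <- c(0, sgn * 2.0, 0)
    cc <- o1 + 1.26 * c(0, sgn * 0.90, 0.436)
    o2 <- place_internal(fe, o1, cc, 1.26, 125, 0)
    me <- place_internal(fe, o1, cc, 1.50, 117, 180)
    .add_atom(b, "O1", "O", "ACT", resid, o1)
    .add_atom(b, "C1", "C", "ACT", resid, cc)
    .add_atom(b, "O2", "O", "ACT", resid, o2)
    .add_atom(b, "C2", "C", "ACT", resid, me)
  }
  act(+1, 5L); act(-1, 6L)

  # water trans to the oxo
  .add_atom(b, "O", "O", "HOH", 7L, c(0, 0, -2.1), kind = "water")
  .add_atom(b, "H1", "H", "HOH", 7L, c(0.76, 0, -2.69), kind = "water")
  .add_atom(b, "H2", "H", "HOH", 7L, c(-0.76, 0, -2.69), kind = "water")
  .builder_ensemble(b)
}

#' Build an idealised diketopiperazine pathway substrate
#'
#' Constructs a single-frame model of one of the three cyclodipeptide
#' intermediates: a planar 2,5-diketopiperazine (DKP) ring with an
#' isoleucine-like arm (C-5, its methyl C-5a, the C-6 methylene and the
#' terminal C-7 methyl) and a leucine-like arm (the C-1' methylene, the
#' tertiary C-2' and its methyls, one of which is labelled C-3').
#' Substrate 2 additionally carries the 7-OH hydroxyl; substrate 3
#' carries both 7-OH and 2'-OH.  Candidate sites per substrate follow
#' the pathway vocabulary: 1 -> C-7, C-2', C-5a, C-6; 2 -> C-2', C-3',
#' C-5; 3 -> C-3', C-5, C-6.
#'
#' @param substrate_id 1, 2 or 3.
#' @return List with `ensemble` (single-frame [conformer_ensemble()])
#'   and `sites` (the labelled [classify_carbon_sites()] map).
#' @export
build_dkp <- function(substrate_id = 1L) {
  if (!substrate_id %in% 1:3)
    config_error(sprintf("unknown substrate id '%s' (expected 1, 2 or 3)",
                         substrate_id))
  b <- .new_builder()
  r <- 1.45
  hex <- function(deg) r * c(cos(deg * pi / 180), sin(deg * pi / 180), 0)
  rn1 <- hex(90);  rc2 <- hex(30);   rc3 <- hex(-30)
  rn4 <- hex(-90); rc5 <- hex(-150); rc6 <- hex(150)
  .add_atom(b, "N1", "N", "DKP", 1L, rn1)
  .add_atom(b, "C2", "C", "DKP", 1L, rc2)
  .add_atom(b, "O2", "O", "DKP", 1L, rc2 * (1 + 1.23 / r))
  .add_atom(b, "C3", "C", "DKP", 1L, rc3)
  .add_atom(b, "N4", "N", "DKP", 1L, rn4)
  .add_atom(b, "C5R", "C", "DKP", 1L, rc5)
  .add_atom(b, "O5", "O", "DKP", 1L, rc5 * (1 + 1.23 / r))
  .add_atom(b, "C6R", "C", "DKP", 1L, rc6)

  up <- c(0, 0, 1.2)
  # leucine-like arm on the C3 alpha carbon
  c1p <- rc3 + 1.52 * unitv(unitv(rc3) + up)
  c2p <- place_internal(rn4, rc3, c1p, 1.52, 112, 100)
  c3p <- place_internal(rc3, c1p, c2p, 1.52, 111, 60)
  c3x <- place_internal(rc3, c1p, c2p, 1.52, 111, 180)
  .add_atom(b, "C1'", "C", "DKP", 1L, c1p)
  .add_atom(b, "C2'", "C", "DKP", 1L, c2p)
  .add_atom(b, "C3'", "C", "DKP", 1L, c3p)
  .add_atom(b, "C3X", "C", "DKP", 1L, c3x)
  if (substrate_id == 3L)
    .add_atom(b, "O2'", "O", "DKP", 1L,
              place_internal(rc3, c1p, c2p, 1.43, 109, 300))

  # isoleucine-like arm on the C6 alpha carbon
  c5 <- rc6 + 1.52 * unitv(unitv(rc6) + up)
  c5a <- place_internal(rn1, rc6, c5, 1.52, 111, 60)
  c6 <- place_internal(rn1, rc6, c5, 1.52, 111, 180)
  c7 <- place_internal(rc6, c5, c6, 1.52, 112, 180)
  .add_atom(b, "C5", "C", "DKP", 1L, c5)
  .add_atom(b, "C5A", "C", "DKP", 1L, c5a)
  .add_atom(b, "C6", "C", "DKP", 1L, c6)
  .add_atom(b, "C7", "C", "DKP", 1L, c7)
  if (substrate_id >= 2L)
    .add_atom(b, "O7", "O", "DKP", 1L,
              place_internal(c5, c6, c7, 1.43, 109, 180))

  ens <- .builder_ensemble(b, chain = "S")
  graph <- infer_bonds(ens)
  sites <- classify_carbon_sites(
    graph, ens, seq_len(nrow(ens$atoms)),
    labels = default_site_labels(substrate_id),
    labeled_only = TRUE, substrate_id = substrate_id)
  list(ensemble = ens, sites = sites, graph = graph)
}

# shift all atom indices of a site map by a constant offset
.shift_sites <- function(sites, off) {
  sites$sites <- lapply(sites$sites, function(s) {
    s$carbon_index <- s$carbon_index + off
    s$heavy_neighbors <- s$heavy_neighbors + off
    if (length(s$hydrogen_indices))
      s$hydrogen_indices <- s$hydrogen_indices + off
    if (!is.na(s$methyl_ref)) s$methyl_ref <- s$methyl_ref + off
    s
  })
  sites
}

#' Generate a conformer ensemble with planted NAC ground truth
#'
#' Combines a theozyme and a substrate into one topology and emits `n`
#' frames in which the substrate is rigidly re-posed.  With probability
#' `f_active` (seeded RNG) a frame is constructed so that the target
#' site's leading hydrogen satisfies the NAC criterion with margin
#' (O...H distance uniform in 2.0-2.7 Angstrom, O-H-C angle uniform in
#' 160-180 degrees) while every other site's hydrogens stay at least
#' `clearance` from the oxo; otherwise the substrate is posed with all
#' site hydrogens beyond `inactive_min`.  Planting is geometric - the
#' pose is constructed, not rejection-sampled - so the per-frame ground
#' truth in the ledger is exact, and identical seeds give bitwise
#' identical coordinates.
#'
#' @param theozyme a [build_theozyme()] ensemble.
#' @param substrate a [build_dkp()] result (or any list with `ensemble`
#'   and `sites`).
#' @param target_site site label to plant active conformations for.
#' @param f_active fraction of frames planted active, in `[0, 1]`.
#' @param n number of frames.
#' @param seed integer RNG seed.
#' @param clearance minimum oxo distance for off-target site hydrogens
#'   in active frames, Angstrom.
#' @param inactive_min minimum oxo distance for all site hydrogens in
#'   inactive frames, Angstrom.
#' @param steric_min minimum substrate-theozyme interatomic distance,
#'   Angstrom.
#' @return List with `ensemble` (the combined multi-frame ensemble),
#'   `sites` (site map re-indexed into the combined topology),
#'   `oxo_index`, and `ledger` (class `PlantLedger`: `target_site`,
#'   per-frame logical `plan`, `planted_count`, `seed`).
#' @export
sample_nac_ensemble <- function(theozyme, substrate, target_site,
                                f_active, n, seed = 1L,
                                clearance = 3.5, inactive_min = 3.2,
                                steric_min = 2.0) {
  stopifnot(inherits(theozyme, "ConformerEnsemble"))
  if (f_active < 0 || f_active > 1)
    config_error("f_active must be in [0, 1]")
  if (n < 1L) config_error("need at least one frame")
  sub_ens <- substrate$ensemble
  sub_sites <- substrate$sites
  if (!target_site %in% site_labels(sub_sites))
    config_error(sprintf("target site '%s' not in substrate site map",
                         target_site))
  nth <- nrow(theozyme$atoms)
  oxo <- identify_oxo(theozyme)
  O <- frame_coords(theozyme, 1L)[oxo, ]
  theo_xyz <- frame_coords(theozyme, 1L)

  sub_atoms <- sub_ens$atoms
  sub_atoms$serial <- sub_atoms$serial + nth
  sub_atoms$resid <- sub_atoms$resid + max(theozyme$atoms$resid)
  atoms <- rbind(theozyme$atoms, sub_atoms)
  sites <- .shift_sites(sub_sites, nth)

  S0 <- frame_coords(sub_ens, 1L)
  loc <- sub_sites$sites[[target_site]]
  H0 <- place_site_hydrogens(loc, S0)
  c0 <- S0[loc$carbon_index, ]
  u_locs <- lapply(seq_len(nrow(H0)), function(r) unitv(H0[r, ] - c0))
  others <- sub_sites$sites[site_labels(sub_sites) != target_site]
  centroid <- colMeans(S0)

  site_h_min_dist <- function(X, site_list) {
    if (!length(site_list)) return(Inf)
    min(vapply(site_list, function(s) {
      H <- place_site_hydrogens(s, X)
      min(sqrt(rowSums(sweep(H, 2, O)^2)))
    }, numeric(1)))
  }
  pose_ok <- function(X) {
    min(as.vector(proxy_dist(X, theo_xyz))) >= steric_min
  }
  proxy_dist <- function(A, B) {
    # all-pairs distances via the cross-term expansion
    a2 <- rowSums(A^2); b2 <- rowSums(B^2)
    d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
    sqrt(pmax(d2, 0))
  }

  set.seed(as.integer(seed))
  plan <- logical(n)
  frames <- vector("list", n)
  for (f in seq_len(n)) {
    active <- runif(1) < f_active
    plan[f] <- active
    if (active) {
      dstar <- runif(1, 2.0, 2.7)
      tstar <- runif(1, 160, 180)
      Ht <- O + c(0, 0, dstar)
      aa <- c(0, 0, -1)                         # H -> O direction
      placed <- FALSE
      for (u_loc in u_locs) {
        for (psi in seq(0, 345, by = 15) * pi / 180) {
          ep <- c(cos(psi), sin(psi), 0)
          w <- cos(tstar * pi / 180) * aa + sin(tstar * pi / 180) * ep
          Ct <- Ht + CH_BOND * w
          u_t <- unitv(Ht - Ct)
          R0 <- rotation_between(u_loc, u_t)
          for (chi in seq(0, 345, by = 15) * pi / 180) {
            R <- rotation_axis(u_t, chi) %*% R0
            X <- t(R %*% t(sweep(S0, 2, c0))) +
              matrix(Ct, nrow(S0), 3, byrow = TRUE)
            if (site_h_min_dist(X, others) >= clearance && pose_ok(X)) {
              frames[[f]] <- rbind(theo_xyz, X)
              placed <- TRUE
              break
            }
          }
          if (placed) break
        }
        if (placed) break
      }
      if (!placed)
        compute_error(sprintf(
          "geometric construction infeasible for site '%s' in frame %d: no clash-free active pose",
          target_site, f))
    } else {
      placed <- FALSE
      for (try in 1:100) {
        rd <- unitv(rnorm(3))
        D <- runif(1, 8, 11)
        R <- quat_rotation(rnorm(4))
        X <- t(R %*% t(sweep(S0, 2, centroid))) +
          matrix(O + D * rd, nrow(S0), 3, byrow = TRUE)
        if (site_h_min_dist(X, sub_sites$sites) > inactive_min &&
            pose_ok(X)) {
          frames[[f]] <- rbind(theo_xyz, X)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        compute_error(sprintf(
          "geometric construction infeasible: no clash-free inactive pose for frame %d", f))
    }
  }
  ens <- conformer_ensemble(atoms, frames)
  ledger <- structure(list(target_site = target_site, plan = plan,
                           planted_count = sum(plan), seed = seed),
                      class = "PlantLedger")
  list(ensemble = ens, sites = sites, oxo_index = oxo, ledger = ledger)
}

#' @export
print.PlantLedger <- function(x, ...) {
  cat(sprintf("PlantLedger: %d/%d frames planted active at %s (seed %d)\n",
              x$planted_count, length(x$plan), x$target_site, x$seed))
  invisible(x)
}

#' Write a plant ledger as JSON
#' @param ledger a `PlantLedger` from [sample_nac_ensemble()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "PlantLedger"))
  jsonlite::write_json(unclass(ledger), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
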