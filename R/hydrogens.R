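# 3-vector helpers
vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) compute_error("zero-length vector in geometry construction")
  v / n
}
vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

CH_BOND <- 1.09                       # ideal aliphatic C-H length, Angstrom
TET_ANGLE <- acos(-1 / 3)             # 109.4712 degrees in radians

#' Place ideal-geometry hydrogens on an sp3 carbon site
#'
#' Crystal models deposit no aliphatic hydrogens, but the NAC criterion
#' is evaluated at the hydrogen.  Hydrogens are therefore constructed
#' deterministically at ideal sp3 geometry (C-H 1.09 Angstrom):
#'
#' * CH (3 heavy neighbours): one H along the negated, normalised sum of
#'   the unit vectors to the neighbours.
#' * CH2 (2 heavy): two H in the plane through the external bisector
#'   perpendicular to the heavy-C-heavy plane, H-C-H = 109.47 degrees.
#' * CH3 (1 heavy): three H tetrahedral to the C-neighbour axis,
#'   staggered relative to the site's `methyl_ref` atom (the lowest-index
#'   heavy atom bonded to the neighbour).  `rotamers > 1` additionally
#'   returns copies of the three H rotated about the axis in steps of
#'   `120 / rotamers` degrees, so a caller can score several rotor
#'   orientations and keep the best.
#'
#' If the site already has explicit hydrogens in the model they are
#' returned verbatim and no placement happens.
#'
#' @param site one site entry of a [classify_carbon_sites()] map.
#' @param coords frame coordinates (atoms x 3 matrix).
#' @param rotamers number of methyl rotor orientations to generate.
#' @return Numeric matrix of hydrogen positions (rows x 3).
#' @export
place_site_hydrogens <- function(site, coords, rotamers = 1L) {
  if (length(site$hydrogen_indices) > 0L)
    return(coords[site$hydrogen_indices, , drop = FALSE])
  c0 <- coords[site$carbon_index, ]
  nb <- site$heavy_neighbors
  u <- lapply(nb, function(i) unitv(coords[i, ] - c0))
  nh <- length(nb)
  if (nh == 3L) {
    s <- u[[1]] + u[[2]] + u[[3]]
    if (vnorm(s) < sin(pi / 180))      # neighbours (nearly) coplanar/collinear
      compute_error("degenerate CH neighbour geometry")
    h <- c0 + CH_BOND * unitv(-s)
    return(matrix(h, 1, 3))
  }
  if (nh == 2L) {
    cosang <- sum(u[[1]] * u[[2]])
    if (cosang < cos(pi - pi / 180) || cosang > cos(pi / 180))
      compute_error("degenerate CH2 neighbour geometry (collinear)")
    b <- unitv(-(u[[1]] + u[[2]]))
    n <- unitv(vcross(u[[1]], u[[2]]))
    half <- TET_ANGLE / 2
    h1 <- c0 + CH_BOND * (cos(half) * b + sin(half) * n)
    h2 <- c0 + CH_BOND * (cos(half) * b - sin(half) * n)
    return(rbind(h1, h2))
  }
  if (nh == 1L) {
    axis <- u[[1]]                     # C -> neighbour
    # torsion reference: projection of neighbour -> ref onto the plane
    # perpendicular to the axis; falls back to a fixed lab vector
    e1 <- NULL
    if (!is.na(site$methyl_ref)) {
      r <- coords[site$methyl_ref, ] - coords[nb[1], ]
      rp <- r - sum(r * axis) * axis
      if (vnorm(rp) > 1e-6) e1 <- unitv(rp)
    }
    if (is.null(e1)) {
      probe <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- unitv(probe - sum(probe * axis) * axis)
    }
    e2 <- vcross(axis, e1)
    base <- c(60, 180, 300) * pi / 180  # staggered torsions w.r.t. ref
    spins <- (seq_len(rotamers) - 1L) * (120 / rotamers) * pi / 180
    out <- NULL
    for (sp in spins) {
      for (phi in base + sp) {
        dir <- cos(TET_ANGLE) * axis +
          sin(TET_ANGLE) * (cos(phi) * e1 + sin(phi) * e2)
        out <- rbind(out, c0 + CH_BOND * dir)
      }
    }
    return(out)
  }
  compute_error("site has no heavy neighbours; cannot orient hydrogens")
}
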