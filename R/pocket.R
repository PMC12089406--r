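# Van der Waals radii, Angstrom (Bondi 1964; 2.0 for metals/unknowns).
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
               P = 1.80, S = 1.80, CL = 1.75, BR = 1.85, I = 1.98,
               FE = 2.00, ZN = 2.00, MG = 1.73, SE = 1.90)

vdw_radius <- function(elem) {
  r <- VDW_RADII[toupper(elem)]
  r[is.na(r)] <- 2.0
  unname(r)
}

# the 26 lattice directions (all sign/axis combinations except the origin)
LATTICE_DIRS <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
LATTICE_DIRS <- LATTICE_DIRS[rowSums(abs(LATTICE_DIRS)) > 0, ]

#' Grid-based buried pocket volume
#'
#' A POCASA-style descriptor of steric permissiveness of an active-site
#' cavity.  Grid points within `shell_radius` of `center` count toward
#' the volume when they (a) lie outside every atom's van der Waals
#' sphere inflated by `probe` and (b) are buried: marching outward along
#' a lattice direction (26 neighbours) hits an atom within
#' `shell_radius` for at least `buriedness_k` of the 26 directions.
#' Volume is `count * grid_spacing^3`.  The estimate is approximate -
#' rank ordering and magnitude are meaningful, exact agreement with any
#' particular cavity server is not - and it is deterministic: the grid
#' is anchored at `center`, so the result is exactly
#' translation-invariant and approximately rotation-invariant.
#'
#' @param coords atoms x 3 matrix, Angstrom (e.g. [frame_coords()]).
#' @param elements element symbols per atom (for van der Waals radii).
#' @param center 3-vector, cavity probe centre (e.g. the iron position).
#' @param shell_radius search radius around `center`, Angstrom.
#' @param grid_spacing grid step, Angstrom (at most 1.0).
#' @param probe probe radius, Angstrom.
#' @param buriedness_k minimum number of blocked lattice directions
#'   (out of 26) for a point to count as buried.
#' @return Cavity volume in cubic Angstrom.
#' @export
pocket_volume <- function(coords, elements, center, shell_radius = 8,
                          grid_spacing = 0.5, probe = 1.4,
                          buriedness_k = 16L) {
  coords <- as.matrix(coords)
  if (!(shell_radius > probe && probe > 0))
    config_error("need shell_radius > probe > 0")
  if (grid_spacing > 1.0) config_error("grid_spacing must be <= 1.0 Angstrom")
  d_center <- sqrt(rowSums(sweep(coords, 2, center)^2))
  if (!any(d_center <= 2 * shell_radius))
    compute_error("no cavity context: no atoms within 2 x shell_radius of center")

  rad <- vdw_radius(elements)
  s <- grid_spacing
  # grid must extend one shell_radius beyond the candidate shell so rays
  # starting near the shell edge can still encounter atoms
  half <- 2 * shell_radius + max(rad) + s
  ncell <- 2L * ceiling(half / s) + 1L
  mid <- (ncell + 1L) / 2
  ax <- function(k) center[k] + (seq_len(ncell) - mid) * s

  occ <- array(FALSE, dim = c(ncell, ncell, ncell))   # inside vdW sphere
  excl <- array(FALSE, dim = c(ncell, ncell, ncell))  # inside vdW + probe
  gx <- ax(1); gy <- ax(2); gz <- ax(3)
  keep <- d_center <= half + max(rad)
  crd <- coords[keep, , drop = FALSE]; rd <- rad[keep]
  for (i in seq_len(nrow(crd))) {
    r2 <- rd[i] + probe
    ix <- which(abs(gx - crd[i, 1]) <= r2)
    iy <- which(abs(gy - crd[i, 2]) <= r2)
    iz <- which(abs(gz - crd[i, 3]) <= r2)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - crd[i, 1])^2
    dy2 <- (gy[iy] - crd[i, 2])^2
    dz2 <- (gz[iz] - crd[i, 3])^2
    dd <- outer(outer(dx2, dy2, "+"), dz2, "+")
    blk <- occ[ix, iy, iz, drop = FALSE]
    blk[dd <= rd[i]^2] <- TRUE
    occ[ix, iy, iz] <- blk
    blk <- excl[ix, iy, iz, drop = FALSE]
    blk[dd <= r2^2] <- TRUE
    excl[ix, iy, iz] <- blk
  }

  # candidate points: inside the shell, outside all inflated spheres
  off <- seq_len(ncell) - mid
  d2 <- outer(outer(off^2, off^2, "+"), off^2, "+") * s^2
  cand <- which(d2 <= shell_radius^2 & !excl, arr.ind = TRUE)
  if (!nrow(cand)) return(0)

  blocked <- matrix(FALSE, nrow(cand), nrow(LATTICE_DIRS))
  for (di in seq_len(nrow(LATTICE_DIRS))) {
    d <- LATTICE_DIRS[di, ]
    steplen <- s * sqrt(sum(d^2))
    nstep <- floor(shell_radius / steplen)
    hit <- rep(FALSE, nrow(cand))
    for (k in seq_len(nstep)) {
      px <- cand[, 1] + k * d[1]
      py <- cand[, 2] + k * d[2]
      pz <- cand[, 3] + k * d[3]
      ok <- !hit & px >= 1 & px <= ncell & py >= 1 & py <= ncell &
        pz >= 1 & pz <= ncell
      if (!any(ok)) break
      idx <- cbind(px[ok], py[ok], pz[ok])
      hit[ok] <- occ[idx]
    }
    blocked[, di] <- hit
  }
  buried <- rowSums(blocked) >= buriedness_k
  sum(buried) * s^3
}
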