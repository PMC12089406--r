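# idealised staggered ethane, C-C along z
ethane <- function() {
  cc <- 1.54; ch <- 1.09; tet <- acos(-1 / 3)
  c1 <- c(0, 0, 0); c2 <- c(0, 0, cc)
  h_on <- function(c0, axis, phis) {
    t(vapply(phis, function(phi)
      c0 + ch * (cos(tet) * axis +
                   sin(tet) * c(cos(phi), sin(phi), 0)),
      numeric(3)))
  }
  h1 <- h_on(c1, c(0, 0, 1) * -1, c(0, 2, 4) * pi / 3)
  h2 <- h_on(c2, c(0, 0, 1), c(1, 3, 5) * pi / 3)
  mk_ens(c("C1", "C2", paste0("H", 1:6)),
         c("C", "C", rep("H", 6)),
         rbind(c1, c2, h1, h2), resname = "ETH")
}

test_that("bond perception follows covalent radii with hydrogen rules", {
  two_c <- function(d) mk_ens(c("C1", "C2"), c("C", "C"),
                              rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(nrow(infer_bonds(two_c(1.54))$edges), 1L)
  expect_equal(nrow(infer_bonds(two_c(2.50))$edges), 0L)

  eth <- ethane()
  g <- infer_bonds(eth)
  expect_equal(nrow(g$edges), 7L)
  # brute-force oracle over all 28 pairs with the same radii table
  x <- frame_coords(eth); el <- eth$atoms$elem
  expected <- 0L
  for (i in 1:7) for (j in (i + 1):8) {
    d <- sqrt(sum((x[i, ] - x[j, ])^2))
    if (el[i] == "H" && el[j] == "H") next
    if (d <= covalent_radius(el[i]) + covalent_radius(el[j]) + 0.45)
      expected <- expected + 1L
  }
  expect_equal(nrow(g$edges), expected)
  # symmetry/determinism: subset order does not matter
  g2 <- infer_bonds(eth, rev(seq_len(8)))
  expect_equal(g$edges, g2$edges)
})

test_that("carbon-site classification separates CH/CH2/CH3 and exclusions", {
  # leucine-fragment analogue: Cb-Cg(-Cd1)(-Cd2), the tertiary carbon
  leu <- mk_ens(c("CB", "CG", "CD1", "CD2"), rep("C", 4),
                rbind(c(0, 0, 0), c(1.52, 0, 0),
                      c(2.1, 1.4, 0), c(2.1, -0.7, 1.2)))
  g <- infer_bonds(leu)
  sm <- classify_carbon_sites(g, leu, 1:4)
  expect_equal(sm$sites[["CG"]]$site_class, "CH")
  expect_equal(sm$sites[["CD1"]]$site_class, "CH3")
  expect_setequal(sm$sites[["CG"]]$heavy_neighbors, c(1L, 3L, 4L))

  # amide carbonyl carbon is excluded via the short C-O bond
  amide <- mk_ens(c("N", "C", "O", "CA"), c("N", "C", "O", "C"),
                  rbind(c(-1.33, 0, 0), c(0, 0, 0), c(0.61, 1.07, 0),
                        c(0.8, -1.3, 0)))
  sm2 <- classify_carbon_sites(infer_bonds(amide), amide, 1:4)
  expect_false("C" %in% names(sm2$sites))
  expect_true("CA" %in% names(sm2$sites))

  # planar all-3-neighbour ring (benzene) is excluded by the proxy
  ring_xy <- t(vapply(0:5, function(k)
    1.39 * c(cos(k * pi / 3), sin(k * pi / 3), 0), numeric(3)))
  h_xy <- t(vapply(0:5, function(k)
    2.48 * c(cos(k * pi / 3), sin(k * pi / 3), 0), numeric(3)))
  benz <- mk_ens(c(paste0("C", 1:6), paste0("H", 1:6)),
                 c(rep("C", 6), rep("H", 6)), rbind(ring_xy, h_xy))
  sm3 <- classify_carbon_sites(infer_bonds(benz), benz, 1:12)
  expect_length(sm3$sites, 0L)
})

test_that("hydrogen placement is ideal-geometry and count-consistent", {
  # CH with neighbours at exact tetrahedral vertices: H forced onto the
  # fourth vertex
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)) / sqrt(3)
  ch <- mk_ens(c("C0", "N1", "N2", "N3"), c("C", "C", "C", "C"),
               rbind(c(0, 0, 0), 1.52 * v))
  sm <- classify_carbon_sites(infer_bonds(ch), ch, 1:4)
  H <- place_site_hydrogens(sm$sites[["C0"]], frame_coords(ch))
  expect_equal(nrow(H), 1L)
  expect_equal(as.vector(H), 1.09 * c(-1, -1, 1) / sqrt(3),
               tolerance = 1e-9)

  # CH3: all H-C-H angles 109.47 within 0.5 degree, C-H exactly 1.09
  eth <- ethane()
  site <- list(label = "C1", carbon_index = 1L, site_class = "CH3",
               heavy_neighbors = 2L, hydrogen_indices = integer(),
               methyl_ref = NA_integer_)
  H3 <- place_site_hydrogens(site, frame_coords(eth))
  expect_equal(nrow(H3), 3L)
  for (r in 1:3)
    expect_equal(sqrt(sum(H3[r, ]^2)), 1.09, tolerance = 1e-9)
  for (i in 1:2) for (j in (i + 1):3) {
    u <- H3[i, ] / sqrt(sum(H3[i, ]^2))
    w <- H3[j, ] / sqrt(sum(H3[j, ]^2))
    ang <- acos(sum(u * w)) * 180 / pi
    expect_equal(ang, 109.47, tolerance = 0.5)
  }

  # CH2: each placed H equidistant from both heavy neighbours
  ch2 <- mk_ens(c("CA", "CB", "CG"), rep("C", 3),
                rbind(c(0, 0, 0), c(1.52, 0, 0),
                      c(-0.5, sqrt(1.52^2 - 0.25), 0)))
  smb <- classify_carbon_sites(infer_bonds(ch2), ch2, 1:3)
  H2 <- place_site_hydrogens(smb$sites[["CA"]], frame_coords(ch2))
  expect_equal(nrow(H2), 2L)
  x <- frame_coords(ch2)
  for (r in 1:2)
    expect_equal(sqrt(sum((H2[r, ] - x[2, ])^2)),
                 sqrt(sum((H2[r, ] - x[3, ])^2)), tolerance = 1e-9)
  # H-C-H angle is tetrahedral
  u1 <- H2[1, ] / 1.09; u2 <- H2[2, ] / 1.09
  expect_equal(acos(sum(u1 * u2)) * 180 / pi, 109.47, tolerance = 0.01)

  # count invariant: placed H + heavy neighbours = 4 for all DKP sites
  for (id in 1:3) {
    s <- build_dkp(id)
    for (st in s$sites$sites) {
      H <- place_site_hydrogens(st, frame_coords(s$ensemble))
      expect_equal(nrow(H) + length(st$heavy_neighbors), 4L)
    }
  }
})

test_that("hydrogen placement commutes with rigid-body motion", {
  s <- build_dkp(2)
  x <- frame_coords(s$ensemble)
  set.seed(31)
  for (k in 1:4) {
    R <- random_rotation(); tr <- rnorm(3, 0, 8)
    xt <- apply_rigid(x, R, tr)
    for (st in s$sites$sites) {
      H_then <- apply_rigid(place_site_hydrogens(st, x), R, tr)
      H_after <- place_site_hydrogens(st, xt)
      expect_lt(max(abs(H_then - H_after)), 1e-6)
    }
  }
})

test_that("degenerate neighbour geometry is rejected", {
  lin <- mk_ens(c("CA", "CB", "CG"), rep("C", 3),
                rbind(c(0, 0, 0), c(1.5, 0, 0), c(-1.5, 0, 0)))
  site <- list(label = "CA", carbon_index = 1L, site_class = "CH2",
               heavy_neighbors = c(2L, 3L), hydrogen_indices = integer(),
               methyl_ref = NA_integer_)
  expect_error(place_site_hydrogens(site, frame_coords(lin)),
               "degenerate", class = "nacsel_compute_error")
})
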