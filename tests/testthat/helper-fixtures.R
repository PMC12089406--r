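# Shared fixtures and independent oracles, all generated in code.

# minimal hand-built ensemble
mk_ens <- function(name, elem, xyz, resname = "LIG", resid = 1L,
                   chain = "A", kind = "hetero") {
  n <- length(name)
  atoms <- data.frame(serial = seq_len(n), name = name, elem = elem,
                      resname = rep_len(resname, n),
                      resid = rep_len(resid, n),
                      chain = rep_len(chain, n),
                      kind = rep_len(kind, n),
                      stringsAsFactors = FALSE)
  conformer_ensemble(atoms, list(xyz))
}

# one PDB ATOM/HETATM line
pdb_line <- function(rec, serial, name, resname, chain, resid, x, y, z,
                     elem) {
  sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          rec, serial, name, resname, chain, resid, x, y, z, elem)
}

# independent brute-force NAC tally: plain double loop, law-of-cosines
# angle, no shared counting code with tally_ensemble()
oracle_tally <- function(ens, sites, oxo_index, crit = nac_criteria()) {
  labs <- site_labels(sites)
  counts <- stats::setNames(integer(length(labs)), labs)
  lo <- crit$theta_center - crit$theta_tol
  hi <- min(crit$theta_center + crit$theta_tol, 180)
  for (f in seq_len(n_frames(ens))) {
    x <- frame_coords(ens, f)
    O <- x[oxo_index, ]
    for (s in sites$sites) {
      H <- place_site_hydrogens(s, x)
      C <- x[s$carbon_index, ]
      hit <- FALSE
      for (r in seq_len(nrow(H))) {
        h <- H[r, ]
        d_oh <- sqrt(sum((O - h)^2))
        d_ch <- sqrt(sum((C - h)^2))
        d_oc <- sqrt(sum((O - C)^2))
        cth <- (d_oh^2 + d_ch^2 - d_oc^2) / (2 * d_oh * d_ch)
        th <- acos(min(1, max(-1, cth))) * 180 / pi
        if (d_oh <= crit$d_max && th >= lo && th <= hi) hit <- TRUE
      }
      if (hit) counts[s$label] <- counts[s$label] + 1L
    }
  }
  counts
}

# Fibonacci-sphere cage of carbon atoms whose probe-accessible cavity has
# the requested radius (atom centres at cavity_r + vdW(C) + probe)
cage_coords <- function(cavity_r, n = 500, probe = 1.4, vdw = 1.7) {
  z <- seq(-1 + 1 / n, 1 - 1 / n, length.out = n)
  th <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z) *
    (cavity_r + vdw + probe)
}

# synthetic C-alpha trace of a folded-ish chain
ca_trace <- function(n, seed = 1) {
  set.seed(seed)
  aa <- c("ALA", "GLY", "SER", "LEU", "VAL", "THR", "PHE", "TYR", "LYS",
          "ARG", "ASP", "GLU", "ILE", "MET", "TRP", "HIS")
  seq3 <- sample(aa, n, replace = TRUE)
  xyz <- cbind(cumsum(rnorm(n, 3.8, 0.1)),
               5 * sin(seq_len(n) / 3) + rnorm(n, 0, 0.2),
               5 * cos(seq_len(n) / 4) + rnorm(n, 0, 0.2))
  atoms <- data.frame(serial = seq_len(n), name = "CA", elem = "C",
                      resname = seq3, resid = seq_len(n), chain = "A",
                      kind = "polymer", stringsAsFactors = FALSE)
  conformer_ensemble(atoms, list(xyz))
}

random_rotation <- function() {
  q <- rnorm(4)
  nacsel:::quat_rotation(q)
}

apply_rigid <- function(x, R, t) {
  t(R %*% t(x)) + matrix(t, nrow(x), 3, byrow = TRUE)
}

# rigidly transform every frame of an ensemble
transform_ensemble <- function(ens, R, t) {
  ens$frames <- lapply(ens$frames, apply_rigid, R = R, t = t)
  ens
}
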