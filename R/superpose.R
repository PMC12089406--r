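#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between paired atoms, such that `R %*% x_A + t` best fits `x_B`.  The
#' returned rotation always has determinant +1 (reflections are never
#' introduced).  No outlier-rejection cycles are applied: every supplied
#' pair enters the fit and the RMSD.
#'
#' @param xa,xb numeric matrices, atoms x 3 (Angstrom), e.g. from
#'   [frame_coords()].
#' @param pairing two-column integer matrix of (index in `xa`, index in
#'   `xb`) pairs; defaults to the identity pairing when both frames have
#'   the same number of rows.
#' @return A list of class `nac_superposition` with elements `rotation`
#'   (3 x 3), `translation` (length 3), `rmsd` (Angstrom) and `n_pairs`.
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' superpose(x, x)$rmsd
#' @export
superpose <- function(xa, xb, pairing = NULL) {
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  if (is.null(pairing)) {
    if (nrow(xa) != nrow(xb))
      config_error("frames differ in size; supply an explicit pairing")
    pairing <- cbind(seq_len(nrow(xa)), seq_len(nrow(xa)))
  }
  pairing <- as.matrix(pairing)
  if (nrow(pairing) < 3L)
    compute_error("superposition needs at least 3 atom pairs")
  A <- xa[pairing[, 1], , drop = FALSE]
  B <- xb[pairing[, 2], , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  # collinear or coincident points leave the rotation underdetermined
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    compute_error("degenerate geometry: paired atoms are (nearly) collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cb - as.vector(R %*% ca)
  fitted <- t(R %*% t(A)) + matrix(tr, nrow(A), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_pairs = nrow(pairing)),
            class = "nac_superposition")
}

#' @export
print.nac_superposition <- function(x, ...) {
  cat(sprintf("Rigid-body superposition: %d pairs, rmsd %.3f Angstrom\n",
              x$n_pairs, x$rmsd))
  invisible(x)
}

# One-letter sequence of the C-alpha trace, 'X' for nonstandard residues.
.calpha_info <- function(ens) {
  idx <- which(ens$atoms$kind == "polymer" & ens$atoms$name == "CA" &
                 ens$atoms$elem == "C")
  if (!length(idx)) compute_error("no C-alpha atoms found")
  seq1 <- bio3d::aa321(ens$atoms$resname[idx])
  seq1[is.na(seq1) | seq1 == ""] <- "X"
  list(idx = idx, seq = seq1)
}

#' Whole-structure C-alpha superposition of two (homologous) proteins
#'
#' Pairs C-alpha atoms of residues matched by a global sequence alignment
#' (identity scoring), then applies [superpose()].  Alignment-based
#' pairing, rather than residue numbering, is required because homologues
#' with 35-42 percent identity rarely share numbering.
#'
#' @param ensA,ensB ensembles ([conformer_ensemble()]); frame 1 is used.
#' @param gap_opening,gap_extension alignment gap penalties.
#' @return As [superpose()], plus `pairing` (atom-index pairs used).
#' @export
superpose_calpha <- function(ensA, ensB, gap_opening = 10,
                             gap_extension = 0.5) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    config_error("superpose_calpha requires the Biostrings package")
  a <- .calpha_info(ensA); b <- .calpha_info(ensB)
  alpha <- unique(c(a$seq, b$seq, LETTERS))
  sm <- matrix(0, length(alpha), length(alpha),
               dimnames = list(alpha, alpha))
  diag(sm) <- 1
  pa <- Biostrings::pairwiseAlignment(
    paste(a$seq, collapse = ""), paste(b$seq, collapse = ""),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_opening, gapExtension = gap_extension)
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- 0L; ib <- 0L; pairs <- NULL
  for (k in seq_along(sa)) {
    if (sa[k] != "-") ia <- ia + 1L
    if (sb[k] != "-") ib <- ib + 1L
    if (sa[k] != "-" && sb[k] != "-")
      pairs <- rbind(pairs, c(a$idx[ia], b$idx[ib]))
  }
  if (is.null(pairs) || nrow(pairs) < 3L)
    compute_error("sequence alignment produced fewer than 3 C-alpha pairs")
  fit <- superpose(frame_coords(ensA, 1L), frame_coords(ensB, 1L), pairs)
  fit$pairing <- pairs
  fit
}

#' Serialise a superposition result as JSON
#' @param fit result of [superpose()] / [superpose_calpha()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_superposition <- function(fit, path) {
  stopifnot(inherits(fit, "nac_superposition"))
  jsonlite::write_json(
    list(rmsd_A = fit$rmsd, n_pairs = fit$n_pairs,
         matrix = cbind(fit$rotation, fit$translation)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
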