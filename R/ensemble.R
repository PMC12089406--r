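#' Conformer ensemble container
#'
#' An ordered set of coordinate models (frames) sharing one atom topology,
#' e.g. the models of a multi-MODEL PDB file or snapshots exported from a
#' molecular-dynamics trajectory.
#'
#' @param atoms data.frame with one row per atom and columns `serial`
#'   (integer), `name` (atom name), `elem` (element symbol, upper case),
#'   `resname`, `resid` (integer), `chain` (single character) and `kind`
#'   (one of `"polymer"`, `"hetero"`, `"water"`).
#' @param frames list of numeric matrices, one per model, each
#'   `nrow(atoms)` x 3, coordinates in Angstrom.
#'
#' @return An object of class `ConformerEnsemble`: a list with elements
#'   `atoms`, `frames` and `n_frames`.
#' @examples
#' atoms <- data.frame(serial = 1:2, name = c("FE", "O1"),
#'                     elem = c("FE", "O"), resname = c("FE", "OXO"),
#'                     resid = 1:2, chain = "A", kind = "hetero")
#' ens <- conformer_ensemble(atoms, list(rbind(c(0, 0, 0), c(0, 0, 1.62))))
#' n_frames(ens)
#' @export
conformer_ensemble <- function(atoms, frames) {
  req <- c("serial", "name", "elem", "resname", "resid", "chain", "kind")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    config_error(paste0("atom table lacks column(s): ",
                        paste(miss, collapse = ", ")))
  if (!length(frames)) config_error("ensemble needs at least one frame")
  if (!all(atoms$kind %in% c("polymer", "hetero", "water")))
    config_error("atom kind must be polymer, hetero or water")
  n <- nrow(atoms)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3L || nrow(f) != n)
      parse_error(sprintf(
        "frame %d has %s coordinate rows, topology has %d atoms",
        i, if (is.matrix(f)) nrow(f) else "malformed", n))
    if (!all(is.finite(f)))
      parse_error(sprintf("frame %d contains non-finite coordinates", i))
    frames[[i]] <- unname(f)
  }
  structure(list(atoms = atoms, frames = frames,
                 n_frames = length(frames)),
            class = "ConformerEnsemble")
}

#' Number of frames in an ensemble
#' @param ens a [conformer_ensemble()].
#' @return integer frame count.
#' @export
n_frames <- function(ens) {
  stopifnot(inherits(ens, "ConformerEnsemble"))
  ens$n_frames
}

#' Coordinates of one frame
#' @param ens a [conformer_ensemble()].
#' @param i 1-based frame index.
#' @return numeric matrix, atoms x 3, Angstrom.
#' @export
frame_coords <- function(ens, i = 1L) {
  stopifnot(inherits(ens, "ConformerEnsemble"))
  if (i < 1L || i > ens$n_frames)
    config_error(sprintf("frame index %d outside 1..%d", i, ens$n_frames))
  ens$frames[[i]]
}

#' @export
print.ConformerEnsemble <- function(x, ...) {
  cat(sprintf("ConformerEnsemble: %d atoms, %d frame(s)\n",
              nrow(x$atoms), x$n_frames))
  tab <- table(x$atoms$kind)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
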