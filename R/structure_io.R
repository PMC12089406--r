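WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3", "SOL")

# Map a bio3d atom table (+ xyz) to a ConformerEnsemble, resolving
# alternate locations to the highest-occupancy record (ties -> altloc 'A',
# then file order).
.bio3d_to_ensemble <- function(atom, xyz) {
  alt <- atom$alt
  if (is.null(alt)) alt <- rep(NA_character_, nrow(atom))
  keep <- rep(TRUE, nrow(atom))
  has_alt <- !is.na(alt) & alt != "" & alt != " "
  if (any(has_alt)) {
    key <- paste(atom$chain, atom$resno, atom$insert, atom$resid,
                 atom$elety, sep = "|")
    occ <- atom$o
    occ[is.na(occ)] <- 1
    for (k in unique(key[has_alt])) {
      idx <- which(key == k)
      if (length(idx) < 2L) next
      best <- idx[order(-occ[idx], alt[idx] != "A", idx)][1L]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  atom <- atom[keep, , drop = FALSE]
  elem <- toupper(trimws(atom$elesy))
  noelem <- is.na(elem) | elem == ""
  if (any(noelem)) {
    # fall back on the first alphabetic character of the atom name
    guess <- sub("^[0-9' ]*", "", atom$elety[noelem])
    elem[noelem] <- toupper(substr(guess, 1L, 1L))
  }
  chain <- atom$chain
  chain[is.na(chain)] <- " "
  kind <- ifelse(atom$type == "ATOM", "polymer",
                 ifelse(toupper(atom$resid) %in% WATER_RESNAMES,
                        "water", "hetero"))
  atoms <- data.frame(
    serial  = as.integer(atom$eleno),
    name    = trimws(atom$elety),
    elem    = elem,
    resname = trimws(atom$resid),
    resid   = as.integer(atom$resno),
    chain   = chain,
    kind    = kind,
    stringsAsFactors = FALSE
  )
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0L) parse_error("structure contains no coordinates")
  cols <- as.vector(rbind(3L * which(keep) - 2L,
                          3L * which(keep) - 1L,
                          3L * which(keep)))
  xyz <- xyz[, cols, drop = FALSE]
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  conformer_ensemble(atoms, frames)
}

# Validate per-model atom counts of a multi-MODEL PDB file before handing
# it to the parser, so a malformed model is named explicitly.
.check_pdb_models <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) < 2L) return(invisible(TRUE))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    parse_error("unbalanced MODEL/ENDMDL records")
  counts <- mapply(function(s, e)
    sum(grepl("^(ATOM  |HETATM)", lines[s:e])), starts, ends)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1L])[1L]
    parse_error(sprintf(
      "inconsistent atom count across models: model %d has %d atoms, model 1 has %d",
      bad, counts[bad], counts[1L]))
  }
  invisible(TRUE)
}

#' Read a coordinate file into a conformer ensemble
#'
#' Reads PDB (including multi-MODEL files) or mmCIF coordinates.  HETATM
#' records are retained; alternate locations are resolved to the
#' highest-occupancy copy, ties to altloc `A`.  Models become frames in
#' file order (frame 1 is the first MODEL).
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension), `"pdb"`, `"cif"`.
#' @return A [conformer_ensemble()].
#' @seealso [write_structure()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path))
    parse_error(sprintf("cannot read '%s': no such file", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  if (format == "pdb") {
    lines <- readLines(path, warn = FALSE)
    if (!any(grepl("^(ATOM  |HETATM)", lines)))
      parse_error(sprintf("'%s' contains no ATOM/HETATM records", path))
    .check_pdb_models(lines)
    multi <- length(grep("^MODEL", lines)) > 1L
    pdb <- tryCatch(bio3d::read.pdb(path, multi = multi, rm.alt = FALSE,
                                    verbose = FALSE),
                    error = function(e)
                      parse_error(sprintf("PDB parse failure for '%s': %s",
                                          path, conditionMessage(e))))
    .bio3d_to_ensemble(pdb$atom, if (multi) pdb$xyz else
      matrix(pdb$xyz, nrow = 1L))
  } else {
    cif <- tryCatch(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
                    error = function(e)
                      parse_error(sprintf("mmCIF parse failure for '%s': %s",
                                          path, conditionMessage(e))))
    .bio3d_to_ensemble(cif$atom, matrix(cif$xyz, nrow = 1L))
  }
}

#' Write a conformer ensemble as a (multi-model) PDB file
#'
#' Coordinates are written at standard PDB precision (3 decimals);
#' ensembles with more than one frame produce MODEL/ENDMDL blocks.
#'
#' @param ens a [conformer_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(ens, path) {
  stopifnot(inherits(ens, "ConformerEnsemble"))
  a <- ens$atoms
  xyz <- do.call(rbind, lapply(ens$frames, function(f) as.vector(t(f))))
  bio3d::write.pdb(
    file  = path,
    xyz   = xyz,
    type  = ifelse(a$kind == "polymer", "ATOM", "HETATM"),
    resno = a$resid,
    resid = a$resname,
    eleno = a$serial,
    elety = a$name,
    chain = ifelse(a$chain == " ", "", a$chain),
    elesy = a$elem
  )
  invisible(path)
}
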