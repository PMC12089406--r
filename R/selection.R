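#' Select atoms by conjunctive filters
#'
#' All supplied filters must match (logical AND).  At least one filter is
#' required.  An empty result is valid and returned as an empty integer
#' vector.
#'
#' @param ens a [conformer_ensemble()].
#' @param element,resname,chain,name,kind optional character vectors of
#'   admissible values for the corresponding atom fields.
#' @return Integer vector of atom indices in topology order.
#' @examples
#' th <- build_theozyme()
#' select_atoms(th, element = "FE")
#' @export
select_atoms <- function(ens, element = NULL, resname = NULL, chain = NULL,
                         name = NULL, kind = NULL) {
  stopifnot(inherits(ens, "ConformerEnsemble"))
  if (is.null(element) && is.null(resname) && is.null(chain) &&
      is.null(name) && is.null(kind))
    config_error("select_atoms needs at least one filter")
  a <- ens$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(element)) sel <- sel & a$elem    %in% toupper(element)
  if (!is.null(resname)) sel <- sel & a$resname %in% resname
  if (!is.null(chain))   sel <- sel & a$chain   %in% chain
  if (!is.null(name))    sel <- sel & a$name    %in% name
  if (!is.null(kind))    sel <- sel & a$kind    %in% kind
  which(sel)
}

#' Locate the ferryl (oxo) oxygen of an Fe(IV)=O centre
#'
#' The abstraction reference of the NAC criterion is the oxo oxygen bound
#' to iron.  It is identified in the first frame as the unique oxygen
#' whose Fe distance falls in `d_range` and that is not bonded to any
#' carbon (which excludes carboxylate, alpha-ketoglutarate and succinate
#' oxygens).  Resting-state crystal structures carry no ferryl oxygen; in
#' that case supply an explicit proxy atom index to downstream functions
#' instead.
#'
#' @param ens a [conformer_ensemble()].
#' @param fe_index index of the iron atom; defaults to the unique FE atom.
#' @param d_range numeric length-2, admissible Fe-O distance in Angstrom.
#' @return Integer atom index of the oxo oxygen.
#' @export
identify_oxo <- function(ens, fe_index = NULL, d_range = c(1.5, 1.9)) {
  stopifnot(inherits(ens, "ConformerEnsemble"))
  a <- ens$atoms
  if (is.null(fe_index)) {
    fe_index <- which(a$elem == "FE")
    if (length(fe_index) != 1L)
      config_error(sprintf("expected exactly one FE atom, found %d",
                           length(fe_index)))
  }
  if (a$elem[fe_index] != "FE")
    config_error(sprintf("atom %d is %s, not iron", fe_index,
                         a$elem[fe_index]))
  x <- frame_coords(ens, 1L)
  fe <- x[fe_index, ]
  ox <- which(a$elem == "O")
  d_fe <- sqrt(rowSums((x[ox, , drop = FALSE] -
                          matrix(fe, length(ox), 3, byrow = TRUE))^2))
  cand <- ox[d_fe >= d_range[1] & d_fe <= d_range[2]]
  if (length(cand)) {
    # drop oxygens covalently bonded to carbon
    cc <- which(a$elem == "C")
    if (length(cc)) {
      c_bond <- covalent_radius("C") + covalent_radius("O") + 0.45
      bonded <- vapply(cand, function(i) {
        d <- sqrt(rowSums((x[cc, , drop = FALSE] -
                             matrix(x[i, ], length(cc), 3, byrow = TRUE))^2))
        any(d <= c_bond)
      }, logical(1))
      cand <- cand[!bonded]
    }
  }
  if (length(cand) == 0L)
    compute_error(paste0(
      "no oxo found: no carbon-free oxygen within [",
      d_range[1], ", ", d_range[2], "] Angstrom of Fe; ",
      "for resting-state models supply an explicit proxy oxygen index"))
  if (length(cand) > 1L)
    compute_error(paste0("ambiguous oxo assignment, candidate atom indices: ",
                         paste(cand, collapse = ", ")))
  cand
}
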