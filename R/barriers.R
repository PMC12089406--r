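#' Construct a hydrogen-abstraction barrier table
#'
#' Maps site labels to activation free energies of hydrogen abstraction
#' (kcal/mol), typically transcribed from theozyme-model DFT results.
#'
#' @param entries named numeric vector, `site label -> kcal/mol`.
#' @param substrate_id optional compound identifier.
#' @return Object of class `BarrierTable`.
#' @export
barrier_table <- function(entries, substrate_id = NULL) {
  if (!length(entries)) config_error("barrier table is empty")
  if (is.null(names(entries)) || any(names(entries) == ""))
    config_error("all barrier entries need a site label")
  if (anyDuplicated(names(entries)))
    config_error(paste0("duplicate site label(s): ",
                        paste(unique(names(entries)[duplicated(names(entries))]),
                              collapse = ", ")))
  if (!all(is.finite(entries) & entries > 0))
    config_error("barriers must be finite and positive")
  structure(list(substrate_id = substrate_id, entries = entries),
            class = "BarrierTable")
}

#' Load a barrier table from a two-column TSV file
#'
#' Expected format: `site<TAB>kcal_per_mol`, `#` comments allowed, no
#' header.  Shipped defaults for the pathway substrates live under
#' `system.file("extdata", package = "nacsel")`
#' (`barriers_substrate{1,2,3}.tsv`); they contain only the
#' text-documented values, further sites must be transcribed by the
#' user.
#'
#' @param path TSV file path.
#' @param substrate_id optional identifier stored in the table.
#' @return A [barrier_table()].
#' @export
load_barriers <- function(path, substrate_id = NULL) {
  if (!file.exists(path))
    parse_error(sprintf("barrier table '%s' not found", path))
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE, quote = "",
               col.names = c("site", "barrier")),
    error = function(e)
      parse_error(sprintf("cannot parse barrier table '%s': %s", path,
                          conditionMessage(e))))
  if (!is.numeric(df$barrier)) {
    bad <- df$site[is.na(suppressWarnings(as.numeric(df$barrier)))]
    parse_error(paste0("non-numeric barrier for site(s): ",
                       paste(bad, collapse = ", ")))
  }
  barrier_table(setNames(df$barrier, df$site), substrate_id)
}

#' Inherently most reactive site of a barrier table
#'
#' The site with the minimal hydrogen-abstraction barrier, i.e. the site
#' a bare (protein-free) Fe(IV)-oxo model would attack.  Exact ties
#' return all tied labels with `tie = TRUE`; such a table cannot support
#' a strategy call until resolved.
#'
#' @param table a [barrier_table()].
#' @return List with `site_label` (character, length >= 1), `barrier`
#'   (kcal/mol) and `tie` (logical).
#' @export
inherent_site <- function(table) {
  stopifnot(inherits(table, "BarrierTable"))
  b <- table$entries
  m <- min(b)
  labs <- names(b)[b == m]
  list(site_label = labs, barrier = m, tie = length(labs) > 1L)
}
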