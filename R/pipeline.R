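nacsel_version <- function() {
  as.character(utils::packageVersion("nacsel"))
}

.input_digest <- function(path) {
  unname(tools::md5sum(path))
}

.criteria_from_config <- function(config) {
  cr <- config$criteria
  nac_criteria(
    d_max = if (!is.null(cr$d_max)) cr$d_max else 2.8,
    theta_center = if (!is.null(cr$theta_center)) cr$theta_center else 170,
    theta_tol = if (!is.null(cr$theta_tol)) cr$theta_tol else 15)
}

.resolve_labels <- function(config) {
  if (!is.null(config$site_labels)) {
    if (is.character(config$site_labels) && length(config$site_labels) == 1L &&
        file.exists(config$site_labels)) {
      cfg <- yaml::read_yaml(config$site_labels)
      return(unlist(cfg))
    }
    return(unlist(config$site_labels))
  }
  if (!is.null(config$substrate_id))
    return(default_site_labels(config$substrate_id))
  NULL
}

.cleanup_on_error <- function(paths, expr) {
  tryCatch(expr, error = function(e) {
    for (p in paths) if (file.exists(p)) unlink(p)
    stop(e)
  })
}

#' Load a pipeline configuration from YAML
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    config_error(sprintf("config file '%s' not found", path))
  yaml::read_yaml(path)
}

#' Run the NAC counting pipeline
#'
#' Reads a conformer ensemble, perceives the substrate's candidate C-H
#' sites, locates the ferryl oxygen, tallies near-attack conformations
#' per site, and writes a TSV report (with a provenance header recording
#' tool version, criteria and input digest) plus a JSON twin.
#'
#' @param config named list (or path handled by [read_config()]) with
#'   elements: `input` (multi-model PDB/mmCIF path), `outdir`,
#'   `substrate_resname` (default `"DKP"`), `site_labels` (YAML path or
#'   named map) or `substrate_id` (use shipped labels), optional
#'   `oxo_index`, `criteria` (`d_max`, `theta_center`, `theta_tol`),
#'   `rotamers`, `keep_records`, `prefix`.
#' @return Invisibly, a list with the `NACSummary` and the written
#'   `paths`.
#' @export
run_nac <- function(config) {
  if (is.character(config)) config <- read_config(config)
  crit <- .criteria_from_config(config)      # validate before any I/O
  if (is.null(config$input)) config_error("config needs 'input'")
  if (is.null(config$outdir)) config_error("config needs 'outdir'")
  resname <- if (!is.null(config$substrate_resname))
    config$substrate_resname else "DKP"
  prefix <- if (!is.null(config$prefix)) config$prefix else "nac"
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(config$outdir, paste0(prefix, "_report.tsv"))
  jsn <- file.path(config$outdir, paste0(prefix, "_report.json"))

  .cleanup_on_error(c(tsv, jsn), {
    ens <- read_structure(config$input)
    sub <- select_atoms(ens, resname = resname)
    if (!length(sub))
      config_error(sprintf("no atoms with substrate residue name '%s'",
                           resname))
    graph <- infer_bonds(ens, sub)
    labels <- .resolve_labels(config)
    sites <- classify_carbon_sites(graph, ens, sub, labels = labels,
                                   labeled_only = !is.null(labels),
                                   substrate_id = config$substrate_id)
    oxo <- if (!is.null(config$oxo_index)) as.integer(config$oxo_index)
    else identify_oxo(ens)
    rot <- if (!is.null(config$rotamers)) as.integer(config$rotamers) else 1L
    summ <- tally_ensemble(ens, sites, oxo, crit, rotamers = rot,
                           keep_records = isTRUE(config$keep_records))

    default_crit <- identical(unclass(crit), unclass(nac_criteria()))
    header <- c(
      sprintf("# nacsel %s NAC report", nacsel_version()),
      sprintf("# criteria: d_max=%g A, theta=%g+/-%g deg%s", crit$d_max,
              crit$theta_center, crit$theta_tol,
              if (default_crit) "" else " [non-default]"),
      sprintf("# input: %s md5=%s", config$input,
              .input_digest(config$input)),
      sprintf("# oxo_index: %d  frames: %d", oxo, summ$n_frames))
    writeLines(header, tsv)
    tab <- data.frame(site = summ$per_site$site,
                      n_active = summ$per_site$n_active,
                      n_frames = summ$n_frames,
                      fraction = summ$per_site$fraction,
                      mean_d_active = summ$per_site$mean_d_active)
    suppressWarnings(write.table(tab, tsv, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    jsonlite::write_json(
      list(tool = "nacsel", version = nacsel_version(),
           criteria = unclass(crit), input = config$input,
           input_md5 = .input_digest(config$input), oxo_index = oxo,
           n_frames = summ$n_frames, per_site = summ$per_site,
           predicted = predict_sites(summ)),
      jsn, auto_unbox = TRUE, digits = NA)
    if (isTRUE(config$keep_records)) {
      csv <- file.path(config$outdir, paste0(prefix, "_records.csv"))
      write.csv(summ$records, csv, row.names = FALSE)
    }
    invisible(list(summary = summ, paths = c(tsv = tsv, json = jsn)))
  })
}

#' Run the selectivity-strategy classifier
#'
#' Combines a hydrogen-abstraction barrier table (inherent reactivity),
#' an observed hydroxylation site (user-supplied experiment and/or the
#' top NAC prediction), and directing-group evidence into a
#' [classify_strategy()] call, written as JSON.
#'
#' @param config named list with `barrier_table` (TSV path), `outdir`,
#'   and an observed site: `observed_site` (experimental label) and/or
#'   `nac_report` (JSON written by [run_nac()], whose top predicted site
#'   is used).  Evidence: either `evidence_present` (logical) with
#'   optional `evidence_pairs`, or `input` + `substrate_resname` +
#'   `reacting site` detection parameters (`hbond_cutoff`,
#'   `max_bond_separation`, `substrate_id`/`site_labels`).  Optional
#'   `enzyme` names the system in the narrative.
#' @return Invisibly, list with the `StrategyCall` and `paths`.
#' @export
run_strategy <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$barrier_table))
    config_error("config needs 'barrier_table'")
  if (is.null(config$outdir)) config_error("config needs 'outdir'")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  prefix <- if (!is.null(config$prefix)) config$prefix else "strategy"
  jsn <- file.path(config$outdir, paste0(prefix, ".json"))

  .cleanup_on_error(jsn, {
    table <- load_barriers(config$barrier_table, config$substrate_id)
    inherent <- inherent_site(table)

    predicted <- NULL
    if (!is.null(config$nac_report)) {
      rep <- jsonlite::read_json(config$nac_report, simplifyVector = TRUE)
      if (length(rep$predicted) && nrow(rep$predicted))
        predicted <- rep$predicted$site[1]
    }
    observed <- config$observed_site
    source <- "experiment"
    if (is.null(observed)) {
      if (is.null(predicted))
        config_error("no observed site: supply 'observed_site' or a 'nac_report' with an active site")
      observed <- predicted
      source <- "nac_prediction"
    }
    discrepancy <- !is.null(predicted) && !is.null(config$observed_site) &&
      predicted != config$observed_site

    evidence <- NULL
    if (!is.null(config$evidence_present)) {
      evidence <- structure(
        list(present = isTRUE(config$evidence_present),
             pairs = if (!is.null(config$evidence_pairs))
               as.data.frame(config$evidence_pairs)
             else data.frame(substrate_o = integer(), partner = integer(),
                             distance = numeric()),
             directing_hydroxyl_site_distance_bonds = NA_integer_,
             cutoff = NA_real_),
        class = "HBondEvidence")
    } else if (!is.null(config$input)) {
      ens <- read_structure(config$input)
      resname <- if (!is.null(config$substrate_resname))
        config$substrate_resname else "DKP"
      sub <- select_atoms(ens, resname = resname)
      graph <- infer_bonds(ens, sub)
      labels <- .resolve_labels(config)
      sites <- classify_carbon_sites(graph, ens, sub, labels = labels,
                                     labeled_only = !is.null(labels))
      evidence <- detect_directing_contact(
        ens, graph, sites, observed,
        cutoff = if (!is.null(config$hbond_cutoff))
          config$hbond_cutoff else 3.5,
        max_bond_separation = if (!is.null(config$max_bond_separation))
          config$max_bond_separation else 2L)
    }

    call <- classify_strategy(inherent, observed, evidence,
                              enzyme = config$enzyme,
                              observed_source = source)
    out <- list(tool = "nacsel", version = nacsel_version(),
                strategy = call$strategy,
                inherent_site = call$inherent_site,
                inherent_barrier = call$inherent_barrier,
                observed_site = call$observed_site,
                observed_source = source,
                nac_predicted_site = predicted,
                discrepancy_flag = discrepancy,
                evidence_present = !is.null(evidence) &&
                  isTRUE(evidence$present),
                narrative = call$narrative)
    jsonlite::write_json(out, jsn, auto_unbox = TRUE, digits = NA)
    invisible(list(call = call, paths = c(json = jsn)))
  })
}

# find one atom by (name, resname, resid, chain); error lists near-misses
.find_atom <- function(ens, spec) {
  a <- ens$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(spec$name))    sel <- sel & a$name == spec$name
  if (!is.null(spec$resname)) sel <- sel & a$resname == spec$resname
  if (!is.null(spec$resid))   sel <- sel & a$resid == spec$resid
  if (!is.null(spec$chain))   sel <- sel & a$chain == spec$chain
  hit <- which(sel)
  if (length(hit) == 1L) return(hit)
  if (length(hit) > 1L)
    config_error(sprintf("ambiguous atom spec (%s): %d matches",
                         paste(unlist(spec), collapse = "/"), length(hit)))
  near <- which(toupper(a$name) == toupper(spec$name %||% ""))
  config_error(sprintf(
    "atom not found (%s)%s", paste(unlist(spec), collapse = "/"),
    if (length(near)) paste0("; near matches: ",
                             paste(utils::head(sprintf("%s %s%d:%s",
                                                       a$name[near], a$resname[near],
                                                       a$resid[near], a$chain[near]), 5),
                                   collapse = ", "))
    else ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run structural measurements
#'
#' Evaluates distance, angle and C-alpha RMSD requests against a
#' structure and writes a TSV (distances to 0.1 Angstrom, angles to 1
#' degree) plus a JSON twin with machine-precision values.
#'
#' @param config named list with `input` (structure path), `outdir`,
#'   and `requests`: a list of requests, each a list with `type`
#'   (`"distance"`, `"angle"` or `"rmsd"`), for distance/angle an
#'   `atoms` list of 2/3 atom specs (`name`, optional `resname`,
#'   `resid`, `chain`), for rmsd an `other` structure path (self-RMSD
#'   when `other` equals `input`).
#' @return Invisibly, list with the measurement data.frame and `paths`.
#' @export
run_measure <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$input)) config_error("config needs 'input'")
  if (is.null(config$outdir)) config_error("config needs 'outdir'")
  if (!length(config$requests)) config_error("config needs 'requests'")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  prefix <- if (!is.null(config$prefix)) config$prefix else "measure"
  tsv <- file.path(config$outdir, paste0(prefix, ".tsv"))
  jsn <- file.path(config$outdir, paste0(prefix, ".json"))

  .cleanup_on_error(c(tsv, jsn), {
    ens <- read_structure(config$input)
    x <- frame_coords(ens, 1L)
    rows <- list()
    for (rq in config$requests) {
      if (rq$type == "distance") {
        i <- .find_atom(ens, rq$atoms[[1]]); j <- .find_atom(ens, rq$atoms[[2]])
        v <- sqrt(sum((x[i, ] - x[j, ])^2))
        lab <- sprintf("d(%s,%s)", rq$atoms[[1]]$name, rq$atoms[[2]]$name)
        rows[[length(rows) + 1L]] <- data.frame(
          request = lab, type = "distance_A", value = v,
          reported = sprintf("%.1f", v))
      } else if (rq$type == "angle") {
        i <- .find_atom(ens, rq$atoms[[1]])
        j <- .find_atom(ens, rq$atoms[[2]])
        k <- .find_atom(ens, rq$atoms[[3]])
        g <- oh_geometry(x[i, ], x[j, ], x[k, ])
        lab <- sprintf("angle(%s,%s,%s)", rq$atoms[[1]]$name,
                       rq$atoms[[2]]$name, rq$atoms[[3]]$name)
        rows[[length(rows) + 1L]] <- data.frame(
          request = lab, type = "angle_deg", value = g$theta_OHC,
          reported = sprintf("%.0f", g$theta_OHC))
      } else if (rq$type == "rmsd") {
        other <- read_structure(rq$other)
        fit <- superpose_calpha(ens, other)
        rows[[length(rows) + 1L]] <- data.frame(
          request = sprintf("calpha_rmsd(%s)", basename(rq$other)),
          type = "rmsd_A", value = fit$rmsd,
          reported = sprintf("%.2f", fit$rmsd))
      } else config_error(sprintf("unknown request type '%s'", rq$type))
    }
    tab <- do.call(rbind, rows)
    writeLines(c(sprintf("# nacsel %s measurement report", nacsel_version()),
                 sprintf("# input: %s md5=%s", config$input,
                         .input_digest(config$input))), tsv)
    suppressWarnings(write.table(tab, tsv, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    jsonlite::write_json(
      list(tool = "nacsel", version = nacsel_version(),
           input = config$input, measurements = tab),
      jsn, auto_unbox = TRUE, digits = NA)
    invisible(list(measurements = tab, paths = c(tsv = tsv, json = jsn)))
  })
}
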