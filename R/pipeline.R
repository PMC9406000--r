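#' Run the full CSP titration analysis pipeline
#'
#' Orchestrates the stages end to end: read the titration peak lists (or a
#' long-format shift CSV), build the CSP profile, flag significant
#' residues, fit every configured binding site globally, convert each
#' fitted Kd into a physiological occupancy estimate, and optionally
#' analyse an ion trajectory for contact persistence. Writes a
#' machine-readable JSON report.
#'
#' @param config A named list, or a path to a YAML file with the same
#'   structure. Recognised fields:
#' \describe{
#'   \item{reference, points}{`reference`: path to the apo peak list;
#'     `points`: list of `list(path =, ligand_conc =)` for the titration
#'     points. Alternative: `shift_csv`, one CSV for the whole titration.}
#'   \item{protein_conc_mm}{Monomeric protein concentration, mM
#'     (required for fitting). `tetramer: true` multiplies by 4.}
#'   \item{scale_n}{15N scaling divisor (default 6.5).}
#'   \item{sites}{Path to a sites YAML ([read_sites_yaml()]) or the
#'     string `"ttr"` for the built-in presets (default).}
#'   \item{occupancy_ligand_mm}{Ligand concentration for occupancy
#'     estimates, mM; default 2.4, the normal extracellular calcium
#'     level.}
#'   \item{ratio_pairs}{Optional list of `list(numerator =,
#'     denominator =)` site ids for Kd fold changes.}
#'   \item{contacts}{Optional list: `traj` (multi-model PDB path),
#'     `ion_names`, `cutoff` (3.5), `threshold` (0.5), `scope` ("all").}
#'   \item{out_csp_tsv, out_report}{Optional output paths for the CSP
#'     table and the JSON report.}
#' }
#' @param quiet Suppress stage-boundary log messages.
#' @return The report, invisibly (a nested list; also written to
#'   `out_report` if configured). Any stage failure aborts with an error
#'   message naming the stage.
#' @seealso [validate_report()] for the report structure.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stop("stage config: file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))

  tables <- stage("input", {
    if (!is.null(config$shift_csv)) {
      read_shift_csv(config$shift_csv,
                     protein_conc_monomer = config$protein_conc_mm %||% NA_real_)
    } else {
      if (is.null(config$reference) || is.null(config$points))
        stop("need either 'shift_csv' or 'reference' + 'points'")
      if (!file.exists(config$reference))
        stop("reference list not found: ", config$reference)
      T0 <- config$protein_conc_mm %||% NA_real_
      ref <- read_sparky_list(config$reference,
                              condition(0, protein_conc_monomer = T0))
      pts <- lapply(config$points, function(p) {
        if (!file.exists(p$path))
          stop("point list not found: ", p$path)
        read_sparky_list(p$path,
                         condition(p$ligand_conc, protein_conc_monomer = T0))
      })
      c(list(ref), pts)
    }
  })
  say("input: ", length(tables), " titration point(s), ",
      nrow(tables[[1]]$peaks), " reference residue(s)")

  scale_n <- config$scale_n %||% 6.5
  profile <- stage("csp", build_profile(tables, scale_N = scale_n))
  if (!is.null(config$out_csp_tsv))
    stage("csp", write_csp_table(profile, config$out_csp_tsv))
  sig <- stage("significance",
               significance(profile, length(profile$ligand_conc)))
  say("csp: ", sum(profile$tracked), " tracked observations; ",
      length(sig$flagged), " residue(s) flagged at the final point")

  sites <- stage("sites", {
    s <- config$sites %||% "ttr"
    if (identical(s, "ttr")) ttr_sites() else read_sites_yaml(s)
  })
  T0 <- config$protein_conc_mm
  if (is.null(T0)) stop("stage fit: 'protein_conc_mm' is required",
                        call. = FALSE)
  if (isTRUE(config$tetramer)) T0 <- 4 * T0
  fits <- stage("fit", {
    out <- list()
    for (s in sites) {
      usable <- intersect(s$residues, profile$residues)
      if (length(usable) == 0) next
      npts <- rowSums(profile$tracked[match(usable, profile$residues), ,
                                      drop = FALSE])
      if (any(npts < 3)) next
      out[[s$site_id]] <- fit_site(profile, binding_site(s$site_id, usable),
                                   T0 = T0)
    }
    if (length(out) == 0) stop("no site had enough tracked residues to fit")
    out
  })
  say("fit: ", length(fits), " site(s) fitted (",
      paste(vapply(fits, function(f)
        sprintf("%s Kd=%.3g", f$site_id, f$kd), character(1)),
        collapse = "; "), ")")

  lig <- config$occupancy_ligand_mm %||% 2.4
  occupancy <- lapply(fits, function(f) {
    oc <- fraction_bound(lig, f$kd)
    list(site_id = f$site_id, ligand_conc = lig, kd = f$kd,
         fraction_bound = oc$fraction_bound, percent = oc$percent)
  })

  ratios <- list()
  for (pr in config$ratio_pairs %||% list()) {
    a <- fits[[pr$numerator]]; b <- fits[[pr$denominator]]
    if (is.null(a) || is.null(b))
      stop("stage ratios: unknown site id in ratio_pairs", call. = FALSE)
    rr <- kd_ratio(a$kd, b$kd)
    ratios[[paste0(pr$numerator, "/", pr$denominator)]] <-
      list(fold = unname(rr["fold"]), rounded = unname(rr["rounded"]))
  }

  contacts <- NULL
  if (!is.null(config$contacts)) {
    cc <- config$contacts
    contacts <- stage("contacts", {
      traj <- read_multimodel_pdb(cc$traj,
                                  ion_names = cc$ion_names %||% c("CA", "CAL"))
      pp <- persistence(traj, cutoff = cc$cutoff %||% 3.5,
                        threshold = cc$threshold %||% 0.5,
                        atom_scope = cc$scope %||% "all")
      list(cutoff = pp$cutoff, threshold = pp$threshold,
           atom_scope = pp$atom_scope, table = pp$table,
           persistent = pp$persistent)
    })
    say("contacts: ", length(contacts$persistent), " persistent residue(s)")
  }

  report <- list(
    schema_version = "1.0",
    csp = list(
      n_points = length(profile$ligand_conc),
      ligand_conc_mm = profile$ligand_conc,
      n_residues = length(profile$residues),
      n_tracked_observations = sum(profile$tracked),
      scale_n = scale_n),
    significance = list(point_index = sig$point_index,
                        ligand_conc_mm = sig$ligand_conc,
                        mean_ppm = sig$mean, sd_ppm = sig$sd,
                        threshold_ppm = sig$threshold,
                        flagged = as.integer(sig$flagged)),
    fits = lapply(fits, function(f)
      list(site_id = f$site_id, residues = as.integer(f$residues),
           kd_mm = f$kd, kd_se_mm = f$kd_se,
           dmax_ppm = as.list(f$dmax), dmax_se_ppm = as.list(f$dmax_se),
           r_squared = f$r_squared, p_value = f$p_value,
           n_obs = f$n_obs, converged = f$converged)),
    occupancy = occupancy,
    kd_ratios = ratios,
    contacts = contacts)
  full <- list(report = report,
               metadata = list(generated = format(Sys.time(), tz = "UTC"),
                               package_version =
                                 as.character(utils::packageVersion("shiftbind"))))
  if (!is.null(config$out_report)) {
    jsonlite::write_json(full, config$out_report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    say("report written to ", config$out_report)
  }
  invisible(full)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate the structure of a pipeline report
#'
#' Checks a report produced by [run_pipeline()] against the shipped
#' structural schema (`inst/extdata/report-schema.json` documents the
#' expected layout): required sections, required fields per fitted site,
#' and basic value constraints (positive Kd, occupancy fractions in
#' \[0, 1\]).
#'
#' @param report A report list as returned by [run_pipeline()], or a path
#'   to a report JSON.
#' @return `TRUE` invisibly if valid; otherwise an error listing every
#'   violation found.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  bad <- character(0)
  need <- function(ok, msg) if (!isTRUE(ok)) bad <<- c(bad, msg)
  need(is.list(report$report), "missing 'report' section")
  need(is.list(report$metadata), "missing 'metadata' section")
  r <- report$report
  need(identical(as.character(r$schema_version), "1.0"),
       "schema_version must be '1.0'")
  for (sec in c("csp", "significance", "fits", "occupancy"))
    need(is.list(r[[sec]]), paste0("missing '", sec, "' section"))
  for (f in r$fits) {
    for (fld in c("site_id", "kd_mm", "r_squared", "p_value", "n_obs",
                  "converged"))
      need(!is.null(f[[fld]]),
           paste0("fit '", f$site_id %||% "?", "': missing ", fld))
    if (!is.null(f$kd_mm))
      need(f$kd_mm > 0, paste0("fit '", f$site_id, "': kd must be > 0"))
  }
  for (o in r$occupancy)
    need(!is.null(o$fraction_bound) && o$fraction_bound >= 0 &&
           o$fraction_bound <= 1,
         paste0("occupancy '", o$site_id %||% "?",
                "': fraction_bound outside [0, 1]"))
  if (length(bad) > 0)
    stop("invalid report:\n  - ", paste(bad, collapse = "\n  - "),
         call. = FALSE)
  invisible(TRUE)
}
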