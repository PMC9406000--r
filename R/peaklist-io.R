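#' Read a Sparky-style assigned peak list
#'
#' Parses the three-column whitespace table ("Assignment  w1  w2") exported
#' by Sparky/NMRFAM-SPARKY for a 2D 1H-15N correlation spectrum. Assignments
#' must look like `D99N-H` (one-letter code, residue number, optional
#' `N-H`/`NH`/`N-HN` suffix). The file carries no condition metadata;
#' supply it via `condition`.
#'
#' @param path Path to the `.list` file.
#' @param condition A [condition()] object for this titration point.
#' @param axis_order Which axis is `w1`: `"N-H"` (default, w1 = 15N,
#'   w2 = 1H, the usual order for 15N-1H correlation maps) or `"H-N"` for
#'   lists exported with the axes swapped.
#'
#' @return A [shift_table()].
#' @examples
#' f <- tempfile(fileext = ".list")
#' writeLines(c("Assignment  w1  w2", "D99N-H 115.20 8.41",
#'              "E66N-H 120.10 7.95"), f)
#' read_sparky_list(f, condition(0, 0.1))
#' @export
read_sparky_list <- function(path, condition, axis_order = c("N-H", "H-N")) {
  axis_order <- match.arg(axis_order)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines) &
    !grepl("^\\s*Assignment\\b", lines, ignore.case = TRUE)
  idx <- which(keep)
  res_num <- integer(0); res_code <- character(0)
  w1 <- numeric(0); w2 <- numeric(0)
  for (i in idx) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 3)
      stop("line ", i, ": expected >= 3 fields, got ", length(tok),
           call. = FALSE)
    m <- regmatches(tok[1],
                    regexec("^([A-Za-z])([0-9]+)(N-HN|N-H|NH|N)?$", tok[1]))[[1]]
    if (length(m) == 0)
      stop("line ", i, ": unparsable assignment '", tok[1], "'", call. = FALSE)
    v1 <- suppressWarnings(as.numeric(tok[2]))
    v2 <- suppressWarnings(as.numeric(tok[3]))
    if (is.na(v1) || is.na(v2))
      stop("line ", i, ": non-numeric shift in '", trimws(lines[i]), "'",
           call. = FALSE)
    rn <- as.integer(m[3])
    if (rn %in% res_num)
      stop("line ", i, ": duplicate residue ", rn, call. = FALSE)
    res_num <- c(res_num, rn); res_code <- c(res_code, toupper(m[2]))
    w1 <- c(w1, v1); w2 <- c(w2, v2)
  }
  if (axis_order == "N-H")
    shift_table(res_num, res_code, shift_N = w1, shift_H = w2,
                condition = condition)
  else
    shift_table(res_num, res_code, shift_N = w2, shift_H = w1,
                condition = condition)
}

#' Write a shift table as a Sparky-style peak list
#'
#' Inverse of [read_sparky_list()]; shifts are written with 5 decimals so
#' that sub-milli-ppm peak movements survive a write/read cycle (exported
#' Sparky lists carry 3-5).
#'
#' @param table A [shift_table()].
#' @param path Output path.
#' @param axis_order See [read_sparky_list()].
#' @return Invisibly, `path`.
#' @export
write_sparky_list <- function(table, path, axis_order = c("N-H", "H-N")) {
  axis_order <- match.arg(axis_order)
  stopifnot(inherits(table, "shift_table"))
  p <- table$peaks
  a <- if (axis_order == "N-H") p$shift_N else p$shift_H
  b <- if (axis_order == "N-H") p$shift_H else p$shift_N
  lines <- c(sprintf("%12s %10s %10s", "Assignment", "w1", "w2"),
             sprintf("%12s %10.5f %10.5f",
                     paste0(p$residue_code, p$residue_number, "N-H"), a, b))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Read a long-format shift CSV covering a whole titration
#'
#' Expects columns `residue_number`, `residue_code`, `shift_N`, `shift_H`,
#' `ligand_conc` and optionally `protein_conc_monomer`, `ph`,
#' `nacl_background`, `temperature`, `label` (constant within a ligand
#' concentration). One [shift_table()] is built per distinct `ligand_conc`,
#' returned in ascending concentration order.
#'
#' @param path Path to the CSV file.
#' @param protein_conc_monomer,ph,nacl_background,temperature Fallback
#'   condition values used when the file has no such column.
#' @return A list of [shift_table()] objects, ascending in `ligand_conc`.
#' @export
read_shift_csv <- function(path, protein_conc_monomer = NA_real_,
                           ph = NA_real_, nacl_background = 0,
                           temperature = 25) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("residue_number", "residue_code", "shift_N", "shift_H",
           "ligand_conc")
  missing <- setdiff(req, names(d))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dup <- duplicated(d[, c("residue_number", "ligand_conc")])
  if (any(dup))
    stop("duplicated (residue_number, ligand_conc) row(s), e.g. residue ",
         d$residue_number[dup][1], " at ", d$ligand_conc[dup][1], " mM",
         call. = FALSE)
  opt <- function(col, fallback, sub) {
    if (col %in% names(d)) sub[[col]][1] else fallback
  }
  concs <- sort(unique(d$ligand_conc))
  lapply(concs, function(cc) {
    sub <- d[d$ligand_conc == cc, , drop = FALSE]
    shift_table(sub$residue_number, sub$residue_code, sub$shift_N,
                sub$shift_H,
                condition(ligand_conc = cc,
                          protein_conc_monomer =
                            opt("protein_conc_monomer", protein_conc_monomer, sub),
                          ph = opt("ph", ph, sub),
                          nacl_background =
                            opt("nacl_background", nacl_background, sub),
                          temperature = opt("temperature", temperature, sub),
                          label = opt("label", "", sub)))
  })
}

#' Write a CSP profile as a TSV table
#'
#' One row per (residue, titration point): columns `residue`, `ligand_conc`,
#' `delta_H`, `delta_N`, `delta_combined`, `tracked`. Untracked
#' (residue, point) cells get `tracked = FALSE` and empty shift fields.
#' Values are written with 6 decimals so a re-read reproduces them to 1e-6.
#'
#' @param profile A [build_profile()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_csp_table()]
#' @export
write_csp_table <- function(profile, path) {
  stopifnot(inherits(profile, "csp_profile"))
  if (length(profile$residues) == 0)
    stop("empty profile", call. = FALSE)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  np <- length(profile$ligand_conc)
  rows <- character(0)
  for (r in seq_along(profile$residues)) for (j in seq_len(np)) {
    tr <- profile$tracked[r, j]
    rows <- c(rows, paste(
      profile$residues[r], profile$ligand_conc[j],
      if (tr) fmt(profile$delta_H[r, j]) else "",
      if (tr) fmt(profile$delta_N[r, j]) else "",
      if (tr) fmt(profile$delta_combined[r, j]) else "",
      tolower(tr), sep = "\t"))
  }
  lines <- c(paste("residue", "ligand_conc", "delta_H", "delta_N",
                   "delta_combined", "tracked", sep = "\t"), rows)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Read back a CSP TSV written by [write_csp_table()]
#'
#' @param path Path to the TSV.
#' @param scale_N 15N scaling divisor recorded with the profile (not stored
#'   in the TSV), default 6.5.
#' @param reference_index Index of the reference point among the distinct
#'   ligand concentrations (ascending), default 1.
#' @return A `csp_profile` object (conditions carry concentrations only).
#' @export
read_csp_table <- function(path, scale_N = 6.5, reference_index = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  req <- c("residue", "ligand_conc", "delta_H", "delta_N", "delta_combined",
           "tracked")
  missing <- setdiff(req, names(d))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  residues <- sort(unique(d$residue))
  concs <- sort(unique(d$ligand_conc))
  shape <- function(col) {
    m <- matrix(NA_real_, length(residues), length(concs),
                dimnames = list(residues, concs))
    m[cbind(match(d$residue, residues), match(d$ligand_conc, concs))] <- d[[col]]
    m
  }
  tracked <- matrix(FALSE, length(residues), length(concs),
                    dimnames = list(residues, concs))
  tracked[cbind(match(d$residue, residues), match(d$ligand_conc, concs))] <-
    as.logical(d$tracked)
  new_csp_profile(residues = residues, ligand_conc = concs,
                  conditions = lapply(concs, condition),
                  reference_index = as.integer(reference_index),
                  delta_H = shape("delta_H"), delta_N = shape("delta_N"),
                  delta_combined = shape("delta_combined"),
                  tracked = tracked, scale_N = scale_N)
}
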