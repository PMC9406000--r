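#' Titration-point condition metadata
#'
#' Bundles the solution conditions of one titration point. Peak-list files
#' carry no condition information, so conditions are always supplied by the
#' caller and attached to the [shift_table()] holding that point's peaks.
#'
#' @param ligand_conc Total ligand (CaCl2 or NaCl) concentration, mM.
#' @param protein_conc_monomer Total monomeric protein concentration, mM.
#'   Note this is per monomer: a 25 uM tetramer solution is 0.1 mM monomer.
#' @param ph Solution pH.
#' @param nacl_background Background NaCl concentration, mM (on top of
#'   `ligand_conc` when the titrant is CaCl2).
#' @param temperature Temperature, degrees C.
#' @param label Free-text label for the condition.
#'
#' @return An object of class `"titration_condition"`: a list with the
#'   above fields.
#' @examples
#' condition(ligand_conc = 10, protein_conc_monomer = 0.1, ph = 6.5)
#' @export
condition <- function(ligand_conc, protein_conc_monomer = NA_real_,
                      ph = NA_real_, nacl_background = 0,
                      temperature = 25, label = "") {
  ligand_conc <- as.numeric(ligand_conc)
  protein_conc_monomer <- as.numeric(protein_conc_monomer)
  nacl_background <- as.numeric(nacl_background)
  for (nm in c("ligand_conc", "protein_conc_monomer", "nacl_background")) {
    v <- get(nm)
    if (length(v) != 1L || (!is.na(v) && v < 0))
      stop("'", nm, "' must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(ligand_conc = ligand_conc,
         protein_conc_monomer = protein_conc_monomer,
         ph = as.numeric(ph), nacl_background = nacl_background,
         temperature = as.numeric(temperature), label = as.character(label)),
    class = "titration_condition")
}

#' Assigned amide peak table for one titration point
#'
#' Holds the assigned backbone amide (1H-15N) cross-peak positions of one
#' spectrum together with its [condition()]. One peak per residue; prolines
#' have no backbone amide proton and are dropped with a warning if supplied.
#'
#' @param residue_number Integer vector of residue numbers (>= 1).
#' @param residue_code One-letter amino-acid codes, same length.
#' @param shift_N 15N chemical shifts, ppm.
#' @param shift_H 1H chemical shifts, ppm.
#' @param condition A [condition()] object.
#'
#' @details Shifts outside the typical amide windows (1H 4-13 ppm, 15N
#'   95-140 ppm) trigger a warning but are retained: folded or unusual peaks
#'   are legitimate, a warning guards against axis-order mistakes.
#'
#' @return An object of class `"shift_table"`: a list with a `peaks` data
#'   frame (columns `residue_number`, `residue_code`, `shift_N`, `shift_H`,
#'   ordered by residue number) and the `condition`.
#' @examples
#' shift_table(c(66, 99), c("E", "D"), c(120.10, 115.20), c(7.95, 8.41),
#'             condition(0, 0.1))
#' @export
shift_table <- function(residue_number, residue_code, shift_N, shift_H,
                        condition) {
  if (!inherits(condition, "titration_condition"))
    stop("'condition' must be a condition object", call. = FALSE)
  residue_number <- as.integer(residue_number)
  n <- length(residue_number)
  if (length(residue_code) != n || length(shift_N) != n || length(shift_H) != n)
    stop("peak fields must have equal length", call. = FALSE)
  if (n > 0 && any(residue_number < 1L))
    stop("residue numbers must be >= 1", call. = FALSE)
  if (anyDuplicated(residue_number))
    stop("duplicate residue number(s): ",
         paste(unique(residue_number[duplicated(residue_number)]),
               collapse = ", "), call. = FALSE)
  residue_code <- toupper(as.character(residue_code))
  pro <- residue_code == "P"
  if (any(pro)) {
    warning("dropping ", sum(pro),
            " proline peak(s): prolines have no backbone amide")
    residue_number <- residue_number[!pro]
    residue_code <- residue_code[!pro]
    shift_N <- shift_N[!pro]
    shift_H <- shift_H[!pro]
  }
  shift_N <- as.numeric(shift_N)
  shift_H <- as.numeric(shift_H)
  odd_H <- shift_H < 4 | shift_H > 13
  odd_N <- shift_N < 95 | shift_N > 140
  if (any(odd_H, na.rm = TRUE) || any(odd_N, na.rm = TRUE))
    warning(sum(odd_H | odd_N, na.rm = TRUE),
            " peak(s) outside the typical amide window (1H 4-13 ppm, ",
            "15N 95-140 ppm); check axis order")
  o <- order(residue_number)
  structure(
    list(peaks = data.frame(residue_number = residue_number[o],
                            residue_code = residue_code[o],
                            shift_N = shift_N[o], shift_H = shift_H[o]),
         condition = condition),
    class = "shift_table")
}

#' @export
print.titration_condition <- function(x, ...) {
  cat(sprintf("condition: ligand %.4g mM, protein %.4g mM monomer, pH %s",
              x$ligand_conc, x$protein_conc_monomer,
              ifelse(is.na(x$ph), "?", format(x$ph))))
  if (!is.na(x$nacl_background) && x$nacl_background > 0)
    cat(sprintf(", %.4g mM NaCl", x$nacl_background))
  if (nzchar(x$label)) cat(" [", x$label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
print.shift_table <- function(x, ...) {
  cat(sprintf("shift_table: %d assigned amide peak(s)\n", nrow(x$peaks)))
  print(x$condition)
  if (nrow(x$peaks) > 0) print(utils::head(x$peaks, 10))
  if (nrow(x$peaks) > 10) cat("... (", nrow(x$peaks) - 10, " more)\n", sep = "")
  invisible(x)
}
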