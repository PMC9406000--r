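#' Combined amide chemical shift perturbation
#'
#' The combined CSP statistic for a backbone amide,
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N / s)^2},}
#' with the 15N difference down-weighted by `scale_N` to put both nuclei on
#' a comparable ppm scale.
#'
#' @param delta_H 1H shift difference, ppm. Vectorised.
#' @param delta_N 15N shift difference, ppm. Vectorised.
#' @param scale_N Positive 15N scaling divisor. Default 6.5 (the ratio of
#'   typical amide 15N to 1H shift dispersions; some literature uses 5).
#' @return Combined CSP in ppm, non-negative, symmetric in the sign of both
#'   inputs.
#' @examples
#' combined_csp(0.03, 0.13)          # 0.036056
#' combined_csp(-0.03, -0.13)        # identical
#' @export
combined_csp <- function(delta_H, delta_N, scale_N = 6.5) {
  if (!is.numeric(scale_N) || length(scale_N) != 1L || is.na(scale_N) ||
      scale_N <= 0)
    stop("'scale_N' must be a positive number", call. = FALSE)
  sqrt(delta_H^2 + (delta_N / scale_N)^2)
}

# internal constructor shared by build_profile() and read_csp_table()
new_csp_profile <- function(residues, ligand_conc, conditions,
                            reference_index, delta_H, delta_N,
                            delta_combined, tracked, scale_N) {
  structure(
    list(residues = residues, ligand_conc = ligand_conc,
         conditions = conditions, reference_index = reference_index,
         delta_H = delta_H, delta_N = delta_N,
         delta_combined = delta_combined, tracked = tracked,
         scale_N = scale_N),
    class = "csp_profile")
}

#' Build a per-residue CSP profile across a titration
#'
#' Computes, for every residue assigned in the reference (apo) spectrum,
#' the 1H and 15N shift differences and the combined CSP at every titration
#' point, relative to the reference. Under fast exchange each residue shows
#' a single peak moving continuously with ligand concentration, so peaks
#' are matched by assignment.
#'
#' @param tables List of [shift_table()] objects (>= 2), one per titration
#'   point, each carrying its ligand concentration in its condition.
#' @param reference_index Index of the reference table in `tables`
#'   (default: the table with the lowest ligand concentration, which must
#'   be unique).
#' @param scale_N 15N scaling divisor passed to [combined_csp()].
#'
#' @details Residues missing from a non-reference point are marked
#'   untracked at that point only (peak overlap or broadening at that
#'   condition). Residues present at some point but absent from the
#'   reference cannot be referenced and are excluded with a warning.
#'
#' @return A `csp_profile` object: residue-by-point matrices `delta_H`,
#'   `delta_N`, `delta_combined` and logical `tracked`, plus `residues`,
#'   `ligand_conc`, `conditions`, `reference_index` and `scale_N`.
#' @export
build_profile <- function(tables, reference_index = NULL, scale_N = 6.5) {
  if (!is.list(tables) || length(tables) < 2 ||
      !all(vapply(tables, inherits, logical(1), "shift_table")))
    stop("'tables' must be a list of >= 2 shift_table objects",
         call. = FALSE)
  concs <- vapply(tables, function(t) t$condition$ligand_conc, numeric(1))
  if (is.null(reference_index)) {
    reference_index <- which(concs == min(concs))
    if (length(reference_index) != 1)
      stop("reference table is ambiguous; pass 'reference_index'",
           call. = FALSE)
  }
  reference_index <- as.integer(reference_index)
  if (reference_index < 1 || reference_index > length(tables))
    stop("reference table missing: index ", reference_index,
         " out of range", call. = FALSE)
  ref <- tables[[reference_index]]$peaks
  if (nrow(ref) == 0) stop("reference table has no peaks", call. = FALSE)
  residues <- ref$residue_number
  np <- length(tables)
  mk <- function() matrix(NA_real_, length(residues), np,
                          dimnames = list(residues, concs))
  dH <- mk(); dN <- mk(); dC <- mk()
  tracked <- matrix(FALSE, length(residues), np,
                    dimnames = list(residues, concs))
  extra <- integer(0)
  for (j in seq_len(np)) {
    p <- tables[[j]]$peaks
    extra <- union(extra, setdiff(p$residue_number, residues))
    i <- match(p$residue_number, residues)
    ok <- !is.na(i)
    dH[i[ok], j] <- p$shift_H[ok] - ref$shift_H[i[ok]]
    dN[i[ok], j] <- p$shift_N[ok] - ref$shift_N[i[ok]]
    tracked[i[ok], j] <- TRUE
  }
  if (length(extra) > 0)
    warning("residue(s) absent from the reference excluded: ",
            paste(sort(extra), collapse = ", "))
  dC[] <- combined_csp(dH, dN, scale_N)
  new_csp_profile(residues = residues, ligand_conc = concs,
                  conditions = lapply(tables, function(t) t$condition),
                  reference_index = reference_index,
                  delta_H = dH, delta_N = dN, delta_combined = dC,
                  tracked = tracked, scale_N = scale_N)
}

#' @export
print.csp_profile <- function(x, ...) {
  cat(sprintf(paste0("csp_profile: %d residue(s) x %d titration point(s) ",
                     "(reference point %d, scale_N = %g)\n"),
              length(x$residues), length(x$ligand_conc),
              x$reference_index, x$scale_N))
  cat("ligand (mM):", paste(format(x$ligand_conc), collapse = ", "), "\n")
  cat(sprintf("tracked observations: %d of %d\n",
              sum(x$tracked), length(x$tracked)))
  invisible(x)
}

#' Flag significantly perturbed residues at one titration point
#'
#' Applies the conventional mean + 2 sigma rule: the combined CSPs of all
#' residues tracked at the point give an ensemble mean and sample (n - 1)
#' standard deviation; residues strictly above mean + 2 sd are flagged as
#' significantly perturbed. With zero ensemble variance nothing is flagged
#' (strict inequality).
#'
#' @param profile A [build_profile()] result.
#' @param point_index Index of the titration point (column) to test.
#' @return An object of class `"csp_significance"`: list with `mean`, `sd`,
#'   `threshold` (= mean + 2 sd), `flagged` (integer residue numbers),
#'   `point_index`, `ligand_conc`, `n_tracked`.
#' @export
significance <- function(profile, point_index) {
  stopifnot(inherits(profile, "csp_profile"))
  point_index <- as.integer(point_index)
  if (point_index < 1 || point_index > length(profile$ligand_conc))
    stop("point_index out of range", call. = FALSE)
  tr <- profile$tracked[, point_index]
  if (sum(tr) < 2)
    stop("need >= 2 tracked residues at the point, got ", sum(tr),
         call. = FALSE)
  v <- profile$delta_combined[tr, point_index]
  m <- mean(v); s <- stats::sd(v)
  thr <- m + 2 * s
  structure(
    list(mean = m, sd = s, threshold = thr,
         flagged = sort(profile$residues[tr][v > thr]),
         point_index = point_index,
         ligand_conc = profile$ligand_conc[point_index],
         n_tracked = sum(tr)),
    class = "csp_significance")
}

#' @export
print.csp_significance <- function(x, ...) {
  cat(sprintf(paste0("CSP significance at %g mM (%d tracked residues):\n",
                     "  mean = %.4f ppm, sd = %.4f ppm, ",
                     "threshold (mean + 2 sd) = %.4f ppm\n"),
              x$ligand_conc, x$n_tracked, x$mean, x$sd, x$threshold))
  if (length(x$flagged) == 0) cat("  no residue above threshold\n")
  else cat("  flagged residues:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Compare a cation titration against a salt control
#'
#' Distinguishes specific cation binding from a generic ionic-strength
#' effect: residues significant in the test titration (e.g. CaCl2) but not
#' in the matched-concentration control (e.g. NaCl) are reported as
#' cation-specific. Also reports each profile's mean and sd of the 1H shift
#' change, the statistic used to characterise bulk salt effects.
#'
#' @param test,control [build_profile()] results for the cation titration
#'   and the salt control.
#' @param point_conc Ligand concentration (mM) at which to compare; each
#'   profile's nearest point within 10% is used.
#' @return An object of class `"salt_comparison"`: per-residue `delta_H`
#'   and `delta_combined` for both profiles at the matched point, the
#'   per-profile `mean_delta_H`/`sd_delta_H`, both flagged sets and
#'   `specific` (flagged in test only).
#' @export
salt_comparison <- function(test, control, point_conc) {
  stopifnot(inherits(test, "csp_profile"), inherits(control, "csp_profile"))
  pick <- function(profile, who) {
    d <- abs(profile$ligand_conc - point_conc)
    j <- which.min(d)
    if (d[j] > 0.1 * point_conc)
      stop(who, " profile has no point within 10% of ", point_conc, " mM",
           call. = FALSE)
    j
  }
  jt <- pick(test, "test"); jc <- pick(control, "control")
  overlap <- intersect(test$residues[test$tracked[, jt]],
                       control$residues[control$tracked[, jc]])
  if (length(overlap) == 0)
    stop("no overlapping tracked residues between test and control",
         call. = FALSE)
  per <- function(profile, j) {
    tr <- profile$tracked[, j]
    data.frame(residue = profile$residues[tr],
               delta_H = profile$delta_H[tr, j],
               delta_combined = profile$delta_combined[tr, j])
  }
  st <- significance(test, jt); sc <- significance(control, jc)
  dt <- per(test, jt); dc <- per(control, jc)
  structure(
    list(point_conc = point_conc,
         test = dt, control = dc,
         mean_delta_H = c(test = mean(dt$delta_H),
                          control = mean(dc$delta_H)),
         sd_delta_H = c(test = stats::sd(dt$delta_H),
                        control = stats::sd(dc$delta_H)),
         flagged_test = st$flagged, flagged_control = sc$flagged,
         specific = setdiff(st$flagged, sc$flagged),
         overlap = sort(overlap)),
    class = "salt_comparison")
}

#' @export
print.salt_comparison <- function(x, ...) {
  cat(sprintf("salt comparison at %g mM (%d overlapping residues)\n",
              x$point_conc, length(x$overlap)))
  cat(sprintf("  test:    mean delta_H = %+.4f +/- %.4f ppm, flagged: %s\n",
              x$mean_delta_H["test"], x$sd_delta_H["test"],
              if (length(x$flagged_test)) paste(x$flagged_test, collapse = ", ")
              else "none"))
  cat(sprintf("  control: mean delta_H = %+.4f +/- %.4f ppm, flagged: %s\n",
              x$mean_delta_H["control"], x$sd_delta_H["control"],
              if (length(x$flagged_control))
                paste(x$flagged_control, collapse = ", ") else "none"))
  cat("  cation-specific residues:",
      if (length(x$specific)) paste(x$specific, collapse = ", ") else "none",
      "\n")
  invisible(x)
}
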