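#' Exact 1:1 binding isotherm for the observed CSP
#'
#' Evaluates the quadratic-root solution of single-site mass balance,
#' \deqn{\Delta\delta_{obs} = \Delta\delta_{max}\,
#'   \frac{T_0 + L_0 + K_d - \sqrt{(T_0 + L_0 + K_d)^2 - 4 T_0 L_0}}{2 T_0},}
#' valid without the ligand-excess approximation. The bracketed term is the
#' bound fraction of protein sites and lies in \eqn{[0, \min(1, L_0/T_0)]}.
#'
#' @param T0 Total monomeric protein concentration, mM (> 0).
#' @param L0 Total ligand concentration, mM (>= 0). Vectorised.
#' @param kd Dissociation constant, mM (>= 0).
#' @param dmax CSP amplitude at saturation, ppm. Default 1 returns the
#'   bound fraction itself.
#' @return Predicted CSP (ppm), same length as `L0`.
#' @examples
#' isotherm(0.1, 10, kd = 10, dmax = 0.2)   # 0.099750
#' isotherm(0.1, c(0, 5, 10, 20, 40, 60, 80, 100), kd = 8.7, dmax = 0.15)
#' @export
isotherm <- function(T0, L0, kd, dmax = 1) {
  if (!is.numeric(T0) || length(T0) != 1L || is.na(T0) || T0 <= 0)
    stop("'T0' must be a single positive concentration (mM)", call. = FALSE)
  if (any(L0 < 0)) stop("'L0' must be >= 0", call. = FALSE)
  if (length(kd) != 1L || is.na(kd) || kd < 0)
    stop("'kd' must be a single value >= 0", call. = FALSE)
  s <- T0 + L0 + kd
  # the discriminant is mathematically >= (kd + |T0 - L0|)^2 >= 0; clamp
  # rounding noise so sqrt never sees a tiny negative
  disc <- pmax(s^2 - 4 * T0 * L0, 0)
  dmax * (s - sqrt(disc)) / (2 * T0)
}

#' Ligand-excess occupancy estimate
#'
#' Fraction of protein bound when free ligand is well approximated by total
#' ligand (ligand in vast excess over protein, the physiological situation
#' for a plasma protein at ~uM and an ion at ~mM):
#' \eqn{\chi_{bound} = L / (L + K_d)}.
#'
#' @param ligand_conc Free (~ total) ligand concentration, mM.
#' @param kd Dissociation constant, mM (> 0).
#' @return An object of class `"occupancy_estimate"`: `ligand_conc`, `kd`,
#'   `fraction_bound` in \[0, 1\] and `percent` (rounded half away from
#'   zero to an integer).
#' @examples
#' fraction_bound(2.4, 32.7)   # 6.8% of protein bound -> "7%"
#' @export
fraction_bound <- function(ligand_conc, kd) {
  if (!is.numeric(ligand_conc) || length(ligand_conc) != 1L ||
      is.na(ligand_conc) || ligand_conc < 0)
    stop("'ligand_conc' must be a single value >= 0", call. = FALSE)
  if (!is.numeric(kd) || length(kd) != 1L || is.na(kd) || kd <= 0)
    stop("'kd' must be a single positive value", call. = FALSE)
  fb <- ligand_conc / (ligand_conc + kd)
  structure(
    list(ligand_conc = ligand_conc, kd = kd, fraction_bound = fb,
         percent = round_half_away(100 * fb)),
    class = "occupancy_estimate")
}

#' @export
print.occupancy_estimate <- function(x, ...) {
  cat(sprintf(paste0("occupancy at %g mM ligand (Kd = %g mM): ",
                     "fraction bound %.4f (~%d%%)\n"),
              x$ligand_conc, x$kd, x$fraction_bound, x$percent))
  invisible(x)
}

#' Fold change between two dissociation constants
#'
#' Used to express e.g. the electrostatic-screening weakening of an ionic
#' interaction as "n-fold increase in Kd" between salt conditions.
#'
#' @param kd_a,kd_b Dissociation constants, mM (> 0); the fold is
#'   `kd_a / kd_b`.
#' @return Named numeric vector `c(fold = ..., rounded = ...)`, the rounding
#'   half away from zero.
#' @examples
#' kd_ratio(32.7, 8.7)   # 3.76-fold, reported as 4-fold
#' @export
kd_ratio <- function(kd_a, kd_b) {
  if (!is.numeric(kd_a) || length(kd_a) != 1L || is.na(kd_a) || kd_a <= 0)
    stop("'kd_a' must be a single positive value", call. = FALSE)
  if (!is.numeric(kd_b) || length(kd_b) != 1L || is.na(kd_b) || kd_b <= 0)
    stop("'kd_b' must be a single positive value", call. = FALSE)
  fold <- kd_a / kd_b
  c(fold = fold, rounded = round_half_away(fold))
}

# round half away from zero (round() does banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
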