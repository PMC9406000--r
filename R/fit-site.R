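#' Define a binding site as a residue set
#'
#' @param site_id Short site label.
#' @param residues Non-empty vector of residue numbers reporting on the
#'   site.
#' @return An object of class `"binding_site"`.
#' @seealso [ttr_sites()] for the transthyretin presets.
#' @export
binding_site <- function(site_id, residues) {
  residues <- sort(unique(as.integer(residues)))
  if (length(residues) == 0 || any(is.na(residues)) || any(residues < 1))
    stop("'residues' must be a non-empty set of residue numbers >= 1",
         call. = FALSE)
  structure(list(site_id = as.character(site_id), residues = residues),
            class = "binding_site")
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("binding site '%s': residues %s\n", x$site_id,
              paste(x$residues, collapse = ", ")))
  invisible(x)
}

#' Transthyretin Ca2+ binding-site presets
#'
#' The six candidate Ca2+ sites on the transthyretin monomer (mature-protein
#' numbering 1-127) identified by CSP mapping: site-1 (E66/D99, the
#' crystallographically confirmed carboxylate site), site-2 (C10 plus the
#' indirect reporters R104/K126), site-3 (E51), site-4 (E62), site-5
#' (K76/E89) and site-6 (the V14-K15-A25-G53-E54-L55-A109 hydrogen-bond
#' network).
#'
#' @return Named list of [binding_site()] objects.
#' @export
ttr_sites <- function() {
  defs <- list("site-1" = c(66, 99),
               "site-2" = c(10, 104, 126),
               "site-3" = 51,
               "site-4" = 62,
               "site-5" = c(76, 89),
               "site-6" = c(14, 15, 25, 53, 54, 55, 109))
  stats::setNames(lapply(names(defs), function(n) binding_site(n, defs[[n]])),
                  names(defs))
}

#' Read / write binding-site definitions as YAML
#'
#' The YAML maps site id to a residue-number list, e.g.
#' `site-1: [66, 99]`.
#'
#' @param path YAML file path.
#' @return `read_sites_yaml()`: named list of [binding_site()] objects.
#' @export
read_sites_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)) || any(!nzchar(names(raw))))
    stop("sites YAML must map site ids to residue lists", call. = FALSE)
  stats::setNames(lapply(names(raw), function(n) binding_site(n, raw[[n]])),
                  names(raw))
}

#' @rdname read_sites_yaml
#' @param sites Named list of [binding_site()] objects.
#' @export
write_sites_yaml <- function(sites, path) {
  yaml::write_yaml(lapply(sites, function(s) as.integer(s$residues)), path)
  invisible(path)
}

#' Global 1:1 isotherm fit over the residues of a binding site
#'
#' Fits the exact single-site binding isotherm ([isotherm()]) to the
#' combined CSPs of all residues assigned to a site, as one system of
#' equations: a single shared dissociation constant `kd` and one saturation
#' amplitude `dmax` per residue, by nonlinear least squares
#' (Levenberg-Marquardt with box bounds, multi-start over log-spaced `kd`
#' initial values to avoid local minima).
#'
#' @param profile A [build_profile()] result (or [read_csp_table()]).
#' @param site A [binding_site()], or a bare vector of residue numbers.
#' @param T0 Total monomeric protein concentration, mM. Default: taken from
#'   the profile's reference condition. Use `tetramer = TRUE` if the value
#'   you have is the tetramer concentration.
#' @param tetramer If `TRUE`, `T0` is multiplied by 4 (sites are counted
#'   per monomer).
#' @param kd_bounds,dmax_bounds Box constraints, mM and ppm.
#' @param n_starts Number of log-spaced `kd` initial values (>= 1).
#'
#' @details Starting values: `kd` at the ligand concentration of
#'   half-maximal mean site CSP (log-spaced multi-start around it), each
#'   `dmax` at the residue's largest observed CSP. Zero-ligand points are
#'   included (they pin the baseline at zero). Every site residue must be
#'   tracked at >= 3 titration points. Standard errors come from the
#'   Jacobian-based covariance at the optimum scaled by the residual
#'   variance; `r_squared` is \eqn{1 - SS_{res}/SS_{tot}} pooled over all
#'   residue-point observations, and `p_value` is the F-test of the fitted
#'   model against the all-zero (no-binding) model.
#'
#' @return An object of class `"site_fit"` with components `site_id`, `kd`,
#'   `kd_se`, `dmax` (named per residue), `dmax_se`, `r_squared`,
#'   `p_value`, `n_obs`, `converged`, `T0`, `data` (the stacked
#'   observations with fitted values) and `optim` diagnostics. Methods:
#'   [print()], [summary()], [coef()], [vcov()], [confint()], [predict()],
#'   [fitted()], [residuals()], [plot()], [simulate()].
#' @examples
#' sim <- simulate_titration(titration_sim_spec(seed = 1))
#' prof <- build_profile(sim$tables)
#' fit <- fit_site(prof, binding_site("site-1", c(66, 99)), T0 = 0.1)
#' fit
#' coef(fit)
#' @export
fit_site <- function(profile, site, T0 = NULL, tetramer = FALSE,
                     kd_bounds = c(1e-6, 1e4), dmax_bounds = c(0, 10),
                     n_starts = 3) {
  stopifnot(inherits(profile, "csp_profile"))
  if (!inherits(site, "binding_site")) site <- binding_site("site", site)
  if (is.null(T0)) {
    T0 <- profile$conditions[[profile$reference_index]]$protein_conc_monomer
    if (is.na(T0))
      stop("protein concentration unknown: pass 'T0' (mM monomer)",
           call. = FALSE)
  }
  if (tetramer) T0 <- 4 * T0
  if (T0 <= 0) stop("'T0' must be positive", call. = FALSE)

  miss <- setdiff(site$residues, profile$residues)
  if (length(miss) > 0)
    stop("site residue(s) not in profile: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ri <- match(site$residues, profile$residues)
  npts <- rowSums(profile$tracked[ri, , drop = FALSE])
  if (any(npts < 3))
    stop("site residue(s) tracked at < 3 titration points: ",
         paste(site$residues[npts < 3], collapse = ", "), call. = FALSE)

  # stacked observations (residue, L, observed combined CSP)
  obs <- do.call(rbind, lapply(seq_along(ri), function(k) {
    tr <- profile$tracked[ri[k], ]
    data.frame(residue = site$residues[k],
               ligand_conc = profile$ligand_conc[tr],
               observed = profile$delta_combined[ri[k], tr])
  }))
  nr <- length(site$residues)
  n <- nrow(obs)
  p <- 1L + nr
  if (n < p)
    stop("fewer observations (", n, ") than free parameters (", p, ")",
         call. = FALSE)

  res_idx <- match(obs$residue, site$residues)
  model <- function(par) {
    b <- isotherm(T0, obs$ligand_conc, kd = par[1], dmax = 1)
    par[1 + res_idx] * b
  }
  resid_fn <- function(par) obs$observed - model(par)

  # kd start: ligand concentration of half-maximal mean site CSP
  mean_by_L <- tapply(obs$observed, obs$ligand_conc, mean)
  Ls <- as.numeric(names(mean_by_L))
  half <- max(mean_by_L) / 2
  above <- which(mean_by_L >= half)
  kd0 <- if (length(above) > 0 && max(mean_by_L) > 0) {
    j <- min(above)
    if (j == 1) max(Ls[1], 1) else {
      # linear interpolation between the bracketing points
      L1 <- Ls[j - 1]; L2 <- Ls[j]
      y1 <- mean_by_L[j - 1]; y2 <- mean_by_L[j]
      L1 + (half - y1) / (y2 - y1) * (L2 - L1)
    }
  } else stats::median(Ls[Ls > 0])
  kd0 <- min(max(kd0, kd_bounds[1] * 10), kd_bounds[2] / 10)
  kd_inits <- if (n_starts > 1)
    exp(seq(log(kd0) - log(10), log(kd0) + log(10), length.out = n_starts))
  else kd0
  kd_inits <- pmin(pmax(kd_inits, kd_bounds[1]), kd_bounds[2])

  dmax0 <- vapply(seq_len(nr),
                  function(k) max(obs$observed[res_idx == k], 1e-4),
                  numeric(1))
  dmax0 <- pmin(pmax(dmax0, dmax_bounds[1]), dmax_bounds[2])
  lower <- c(kd_bounds[1], rep(dmax_bounds[1], nr))
  upper <- c(kd_bounds[2], rep(dmax_bounds[2], nr))

  best <- NULL
  for (k0 in kd_inits) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(k0, dmax0), lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best))
    stop("optimizer failed to produce any fit for site ", site$site_id,
         call. = FALSE)

  par <- best$par
  converged <- best$info %in% 1:3
  ss_res <- best$deviance
  ss_tot <- sum((obs$observed - mean(obs$observed))^2)
  r_squared <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else NA_real_
  # F-test against the all-zero (no binding) model
  ss0 <- sum(obs$observed^2)
  rdf <- n - p
  p_value <- if (rdf > 0 && ss_res > 0 && ss0 > ss_res)
    max(stats::pf(((ss0 - ss_res) / p) / (ss_res / rdf), p, rdf,
                  lower.tail = FALSE), 1e-300)
  else if (rdf > 0 && ss0 > ss_res) 1e-300 else 1

  # Jacobian-based covariance at the optimum, scaled by residual variance
  se <- rep(NA_real_, p); vc <- matrix(NA_real_, p, p)
  if (rdf > 0) {
    J <- num_jacobian(model, par)
    vc_try <- tryCatch(solve(crossprod(J)) * ss_res / rdf,
                       error = function(e) NULL)
    if (!is.null(vc_try)) { vc <- vc_try; se <- sqrt(pmax(diag(vc), 0)) }
  }
  nm <- c("kd", paste0("dmax_", site$residues))
  names(par) <- nm; names(se) <- nm; dimnames(vc) <- list(nm, nm)

  obs$fitted <- model(par)
  structure(
    list(site_id = site$site_id, residues = site$residues,
         kd = unname(par[1]), kd_se = unname(se[1]),
         dmax = stats::setNames(unname(par[-1]),
                                paste0("dmax_", site$residues)),
         dmax_se = stats::setNames(unname(se[-1]),
                                   paste0("dmax_", site$residues)),
         r_squared = r_squared, p_value = p_value,
         n_obs = n, converged = converged, T0 = T0,
         data = obs, vcov = vc, sigma = if (rdf > 0) sqrt(ss_res / rdf)
                                        else NA_real_,
         optim = list(info = best$info, message = best$message,
                      deviance = best$deviance, niter = best$niter)),
    class = "site_fit")
}

# central-difference Jacobian of a vector-valued model at par
num_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    up <- par; up[j] <- par[j] + h
    dn <- par; dn[j] <- par[j] - h
    J[, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

#' @export
print.site_fit <- function(x, digits = 4, ...) {
  cat(sprintf("1:1 isotherm fit, site '%s' (%d residue(s), %d observations)\n",
              x$site_id, length(x$residues), x$n_obs))
  cat(sprintf("  Kd = %s +/- %s mM%s\n",
              format(x$kd, digits = digits),
              format(x$kd_se, digits = 3),
              if (!x$converged) "  [NOT converged]" else ""))
  cat(sprintf("  R^2 = %.4g, p = %.3g\n", x$r_squared, x$p_value))
  invisible(x)
}

#' @export
summary.site_fit <- function(object, ...) {
  ct <- cbind(estimate = c(object$kd, object$dmax),
              se = c(object$kd_se, object$dmax_se))
  rownames(ct) <- c("kd", names(object$dmax))
  structure(list(fit = object, coefficients = ct),
            class = "summary.site_fit")
}

#' @export
print.summary.site_fit <- function(x, ...) {
  print(x$fit)
  cat("parameters (mM for kd, ppm for dmax):\n")
  print(round(x$coefficients, 5))
  cat(sprintf("residual sd: %.5f ppm; optimizer: %s (info %d, %d iter)\n",
              x$fit$sigma, x$fit$optim$message, x$fit$optim$info,
              x$fit$optim$niter))
  invisible(x)
}

#' @export
coef.site_fit <- function(object, ...) c(kd = object$kd, object$dmax)

#' @export
vcov.site_fit <- function(object, ...) object$vcov

#' @export
confint.site_fit <- function(object, parm, level = 0.95, ...) {
  cf <- coef(object)
  se <- stats::setNames(c(object$kd_se, object$dmax_se), names(cf))
  if (missing(parm)) parm <- names(cf)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(cf[parm] - z * se[parm], cf[parm] + z * se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' Predict CSPs from a fitted site
#'
#' @param object A [fit_site()] result.
#' @param newdata Ligand concentrations (mM): a numeric vector or a data
#'   frame with a `ligand_conc` column. Default: the fitted concentrations.
#' @param ... Unused.
#' @return Matrix of predicted combined CSPs, residues x concentrations.
#' @export
predict.site_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) sort(unique(object$data$ligand_conc))
       else if (is.data.frame(newdata)) newdata$ligand_conc
       else as.numeric(newdata)
  b <- isotherm(object$T0, L, kd = object$kd, dmax = 1)
  out <- outer(unname(object$dmax), b)
  dimnames(out) <- list(object$residues, L)
  out
}

#' @export
fitted.site_fit <- function(object, ...) object$data$fitted

#' @export
residuals.site_fit <- function(object, ...)
  object$data$observed - object$data$fitted

#' Simulate CSP observations from a fitted site
#'
#' Draws new combined-CSP data sets at the fit's design points by adding
#' Gaussian noise (default: the fit's residual sd) to the fitted curve,
#' truncated at zero since a combined CSP is non-negative.
#'
#' @param object A [fit_site()] result.
#' @param nsim Number of replicate data sets.
#' @param seed Optional integer seed.
#' @param noise_sd Noise standard deviation, ppm.
#' @param ... Unused.
#' @return Data frame with `nsim` columns `sim_1 ...`, rows matching
#'   `object$data`.
#' @export
simulate.site_fit <- function(object, nsim = 1, seed = NULL,
                              noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- object$sigma
  if (is.na(noise_sd)) noise_sd <- 0
  n <- nrow(object$data)
  out <- as.data.frame(
    vapply(seq_len(nsim),
           function(i) pmax(object$data$fitted + stats::rnorm(n, 0, noise_sd), 0),
           numeric(n)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted titration
#'
#' Observed combined CSPs per residue with the fitted isotherm curves.
#'
#' @param x A [fit_site()] result.
#' @param n_curve Number of points for the smooth curve.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.site_fit <- function(x, n_curve = 200, ...) {
  d <- x$data
  Lmax <- max(d$ligand_conc)
  Lgrid <- seq(0, Lmax, length.out = n_curve)
  pred <- predict(x, Lgrid)
  cols <- seq_along(x$residues)
  graphics::plot(NA, xlim = c(0, Lmax), ylim = c(0, max(d$observed, pred)),
                 xlab = "ligand (mM)", ylab = "combined CSP (ppm)",
                 main = sprintf("site '%s': Kd = %.3g mM", x$site_id, x$kd),
                 ...)
  for (k in seq_along(x$residues)) {
    sel <- d$residue == x$residues[k]
    graphics::points(d$ligand_conc[sel], d$observed[sel], col = cols[k],
                     pch = 16)
    graphics::lines(Lgrid, pred[k, ], col = cols[k])
  }
  graphics::legend("bottomright", legend = paste("residue", x$residues),
                   col = cols, pch = 16, lty = 1, bty = "n")
  invisible(x)
}
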