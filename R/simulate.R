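# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# one-letter codes of TTR residues referenced by the site presets, for
# realistic synthetic assignments; anything else is labelled A
.ttr_codes <- c("10" = "C", "14" = "V", "15" = "K", "25" = "A", "51" = "E",
                "53" = "G", "54" = "E", "55" = "L", "56" = "H", "62" = "E",
                "66" = "E", "76" = "K", "89" = "E", "99" = "D", "104" = "R",
                "109" = "A", "126" = "K")

#' Ground-truth specification for a synthetic titration
#'
#' Describes a fast-exchange CSP titration to be generated by
#' [simulate_titration()]. The defaults mirror a weak-binding calcium
#' titration of a ~0.1 mM (monomer) protein: points 0, 5, 10, 20, 40, 60,
#' 80, 100 mM ligand, two binding sites with mM-range dissociation
#' constants (8.7 and 13.5 mM), per-residue saturation amplitudes giving
#' combined CSPs of roughly 0.05-0.3 ppm, and peak-position noise of
#' 0.002 ppm (1H) / 0.01 ppm (15N) — the typical digital resolution of 2D
#' correlation peak positions.
#'
#' @param sites List of site descriptions, each a list with `site_id`,
#'   `kd` (mM) and `residues`: a data frame with columns `residue`,
#'   `dmax_H`, `dmax_N` (ppm at saturation).
#' @param inert_residues Number of additional residues with zero binding
#'   amplitude (they move only by noise).
#' @param protein_conc_monomer Total monomeric protein concentration, mM.
#' @param ligand_points Ligand concentrations, mM; must start at 0 (the
#'   apo reference).
#' @param noise_sd_H,noise_sd_N Gaussian peak-position noise sd, ppm.
#' @param dropout_rate Probability that a residue is untracked at any
#'   given non-reference point (emulates overlap/broadening losses).
#' @param seed Integer seed; identical seeds give identical output.
#' @return An object of class `"titration_sim_spec"`.
#' @export
titration_sim_spec <- function(
    sites = list(
      list(site_id = "site-1", kd = 8.7,
           residues = data.frame(residue = c(66, 99),
                                 dmax_H = c(0.06, 0.10),
                                 dmax_N = c(0.50, 0.90))),
      list(site_id = "site-2", kd = 13.5,
           residues = data.frame(residue = c(10, 104, 126),
                                 dmax_H = c(0.08, 0.05, 0.04),
                                 dmax_N = c(0.70, 0.45, 0.35)))),
    inert_residues = 20,
    protein_conc_monomer = 0.1,
    ligand_points = c(0, 5, 10, 20, 40, 60, 80, 100),
    noise_sd_H = 0.002, noise_sd_N = 0.01,
    dropout_rate = 0, seed = 1) {
  problems <- character(0)
  if (length(ligand_points) < 2 || ligand_points[1] != 0)
    problems <- c(problems, "ligand_points must start at 0 and have >= 2 points")
  if (any(ligand_points < 0)) problems <- c(problems, "ligand_points must be >= 0")
  if (protein_conc_monomer <= 0)
    problems <- c(problems, "protein_conc_monomer must be > 0")
  if (noise_sd_H < 0 || noise_sd_N < 0)
    problems <- c(problems, "noise sds must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1)
    problems <- c(problems, "dropout_rate must be in [0, 1)")
  for (s in sites) {
    if (is.null(s$site_id) || is.null(s$kd) || is.null(s$residues))
      problems <- c(problems, "each site needs site_id, kd and residues")
    else if (s$kd <= 0)
      problems <- c(problems, paste0(s$site_id, ": kd must be > 0"))
  }
  all_res <- unlist(lapply(sites, function(s) s$residues$residue))
  if (anyDuplicated(all_res))
    problems <- c(problems, "a residue may belong to at most one site")
  if (length(problems) > 0)
    stop("invalid titration spec:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(
    list(sites = sites, inert_residues = as.integer(inert_residues),
         protein_conc_monomer = protein_conc_monomer,
         ligand_points = ligand_points,
         noise_sd_H = noise_sd_H, noise_sd_N = noise_sd_N,
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "titration_sim_spec")
}

#' Generate a synthetic fast-exchange titration
#'
#' Under fast exchange each amide peak sits at the population-weighted
#' average of its free and bound positions, so at ligand concentration L
#' the peak of residue r moves by `dmax_r * b(L)` on each axis, where
#' `b(L)` is the exact 1:1 bound fraction ([isotherm()]) for the residue's
#' site Kd (zero for inert residues). Independent Gaussian noise is added
#' to every peak position; all randomness flows from the spec's single
#' seed, so identical specs reproduce identical tables bit for bit.
#'
#' @param spec A [titration_sim_spec()].
#' @return List with `tables` (one [shift_table()] per ligand point, in
#'   spec order), `truth` (data frame of true per-residue parameters:
#'   `residue`, `residue_code`, `site_id`, `kd`, `dmax_H`, `dmax_N`,
#'   `dmax_combined` at scale 6.5) and the `spec`.
#' @examples
#' sim <- simulate_titration(titration_sim_spec(seed = 42))
#' prof <- build_profile(sim$tables)
#' @export
simulate_titration <- function(spec) {
  stopifnot(inherits(spec, "titration_sim_spec"))
  site_tab <- do.call(rbind, lapply(spec$sites, function(s)
    data.frame(residue = s$residues$residue, site_id = s$site_id,
               kd = s$kd, dmax_H = s$residues$dmax_H,
               dmax_N = s$residues$dmax_N)))
  used <- site_tab$residue
  inert <- setdiff(seq_len(length(used) + spec$inert_residues + 130), used)
  inert <- inert[seq_len(spec$inert_residues)]
  truth <- rbind(site_tab,
                 if (spec$inert_residues > 0)
                   data.frame(residue = inert, site_id = "inert", kd = NA,
                              dmax_H = 0, dmax_N = 0))
  truth <- truth[order(truth$residue), ]
  code <- .ttr_codes[as.character(truth$residue)]
  truth$residue_code <- ifelse(is.na(code), "A", code)
  truth$dmax_combined <- combined_csp(truth$dmax_H, truth$dmax_N, 6.5)
  nres <- nrow(truth); np <- length(spec$ligand_points)

  with_seed(spec$seed, {
    base_H <- stats::runif(nres, 7.0, 9.5)
    base_N <- stats::runif(nres, 105, 130)
    eps_H <- matrix(stats::rnorm(nres * np, 0, spec$noise_sd_H), nres, np)
    eps_N <- matrix(stats::rnorm(nres * np, 0, spec$noise_sd_N), nres, np)
    drop <- matrix(stats::runif(nres * np) < spec$dropout_rate, nres, np)
  })
  drop[, 1] <- FALSE   # the apo reference panel stays complete

  b <- matrix(0, nres, np)
  has_site <- truth$site_id != "inert"
  for (j in seq_len(np))
    b[has_site, j] <- vapply(which(has_site), function(i)
      isotherm(spec$protein_conc_monomer, spec$ligand_points[j],
               kd = truth$kd[i], dmax = 1), numeric(1))

  tables <- lapply(seq_len(np), function(j) {
    keep <- !drop[, j]
    shift_table(truth$residue[keep], truth$residue_code[keep],
                shift_N = base_N[keep] + truth$dmax_N[keep] * b[keep, j] +
                  eps_N[keep, j],
                shift_H = base_H[keep] + truth$dmax_H[keep] * b[keep, j] +
                  eps_H[keep, j],
                condition = condition(
                  ligand_conc = spec$ligand_points[j],
                  protein_conc_monomer = spec$protein_conc_monomer,
                  label = sprintf("synthetic %g mM", spec$ligand_points[j])))
  })
  rownames(truth) <- NULL
  list(tables = tables,
       truth = truth[, c("residue", "residue_code", "site_id", "kd",
                         "dmax_H", "dmax_N", "dmax_combined")],
       spec = spec)
}

#' Write a simulated titration to disk
#'
#' One Sparky-style `.list` per titration point, a `conditions.csv`
#' mapping file names to conditions, and a `truth.json` with the true
#' parameters (all clearly synthetic).
#'
#' @param sim A [simulate_titration()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of `.list` paths.
#' @export
write_titration_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(sim$tables), function(j) {
    p <- file.path(dir, sprintf("synthetic_point_%02d.list", j))
    write_sparky_list(sim$tables[[j]], p)
    p
  }, character(1))
  conds <- do.call(rbind, lapply(seq_along(sim$tables), function(j) {
    cd <- sim$tables[[j]]$condition
    data.frame(file = basename(paths[j]), ligand_conc = cd$ligand_conc,
               protein_conc_monomer = cd$protein_conc_monomer,
               ph = cd$ph, nacl_background = cd$nacl_background,
               temperature = cd$temperature, label = cd$label)
  }))
  utils::write.csv(conds, file.path(dir, "conditions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(truth = sim$truth,
                            seed = sim$spec$seed,
                            note = "synthetic ground truth"),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Specification for a contact-patterned toy trajectory
#'
#' Describes a geometric trajectory for exercising [persistence()]:
#' single-atom residues on a 10-Angstrom grid and one ion that visits each
#' residue in a prescribed exact number of frames.
#'
#' @param n_frames Number of frames (>= 1).
#' @param target_fractions Named numeric vector, residue number ->
#'   contact fraction; each fraction must be an exact multiple of
#'   `1/n_frames`.
#' @param cutoff Contact cutoff, Angstrom.
#' @param seed Integer seed (controls which frames are contact frames).
#' @return An object of class `"trajectory_sim_spec"`.
#' @export
trajectory_sim_spec <- function(n_frames, target_fractions, cutoff = 3.5,
                                seed = 1) {
  if (n_frames < 1) stop("need n_frames >= 1", call. = FALSE)
  if (is.null(names(target_fractions)) || any(!nzchar(names(target_fractions))))
    stop("'target_fractions' must be named by residue number",
         call. = FALSE)
  k <- target_fractions * n_frames
  if (any(abs(k - round(k)) > 1e-9))
    stop("each target fraction must be k/n_frames with integer k",
         call. = FALSE)
  if (any(target_fractions < 0 | target_fractions > 1))
    stop("target fractions must be in [0, 1]", call. = FALSE)
  if (cutoff <= 0) stop("'cutoff' must be positive", call. = FALSE)
  structure(
    list(n_frames = as.integer(n_frames),
         residues = as.integer(names(target_fractions)),
         k = as.integer(round(k)), cutoff = cutoff,
         seed = as.integer(seed)),
    class = "trajectory_sim_spec")
}

#' Generate a toy ion trajectory with exact contact fractions
#'
#' Places one atom per residue on a 10-Angstrom grid and a single ion that
#' sits within `0.9 * cutoff` of residue r in exactly the prescribed
#' number of frames (and farther than `3 * cutoff` from every residue in
#' all other frames), so [persistence()] at the spec's cutoff returns the
#' target fractions exactly. At most one residue can be contacted per
#' frame on this geometry (grid spacing 10 A; a midpoint ion would be 5 A
#' from both residues), so if the targets demand more contact frames than
#' exist and the cutoff cannot cover the midpoint the construction fails
#' with an error.
#'
#' @param spec A [trajectory_sim_spec()].
#' @return An [ion_trajectory()].
#' @examples
#' traj <- simulate_trajectory(
#'   trajectory_sim_spec(10, c("99" = 0.6, "12" = 0), seed = 1))
#' persistence(traj, cutoff = 3.5)
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_sim_spec"))
  nres <- length(spec$residues); nf <- spec$n_frames
  spacing <- 10
  # shared frames (ion at the midpoint of two adjacent grid residues) can
  # absorb excess demand, but only when the midpoint lies within cutoff
  remaining <- spec$k
  pairs <- list()
  while (sum(remaining) + length(pairs) > nf) {
    cand <- if (nres > 1) which(remaining[-nres] > 0 & remaining[-1] > 0)
            else integer(0)
    if (spacing / 2 > spec$cutoff || length(cand) == 0)
      stop("conflicting targets: ", sum(spec$k), " contact frames needed ",
           "but only ", nf, " frames exist, and the grid geometry (",
           spacing, " A spacing) forbids one ion contacting two residues ",
           "at cutoff ", spec$cutoff, " A", call. = FALSE)
    i <- cand[1]
    pairs <- c(pairs, list(c(i, i + 1L)))
    remaining[i] <- remaining[i] - 1L
    remaining[i + 1L] <- remaining[i + 1L] - 1L
  }
  pos <- cbind((seq_len(nres) - 1) * spacing, 0, 0)   # residue grid
  far <- c(-50, -50, -50)                        # > 3 * cutoff from all
  owner <- rep(0L, nf)                           # which residue owns a frame
  order_frames <- with_seed(spec$seed, sample.int(nf))
  next_free <- 1L
  pair_frames <- integer(length(pairs))
  for (q in seq_along(pairs)) {
    pair_frames[q] <- order_frames[next_free]
    next_free <- next_free + 1L
  }
  for (r in seq_len(nres)) {
    need <- remaining[r]
    if (need == 0) next
    take <- order_frames[seq(next_free, length.out = need)]
    owner[take] <- r
    next_free <- next_free + need
  }
  ion <- matrix(rep(far, each = nf), nf, 3)
  contact <- owner > 0
  ion[contact, ] <- pos[owner[contact], , drop = FALSE] +
    matrix(rep(c(0, 0.9 * spec$cutoff, 0), each = sum(contact)),
           ncol = 3)
  for (q in seq_along(pairs))
    ion[pair_frames[q], ] <- (pos[pairs[[q]][1], ] + pos[pairs[[q]][2], ]) / 2
  ion_trajectory(
    protein_coords = array(rep(pos, each = nf), dim = c(nf, nres, 3)),
    atom_residue = spec$residues,
    atom_name = rep("CA", nres),
    ion_coords = array(ion, dim = c(nf, 1, 3)),
    ion_labels = "CA9001")
}
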