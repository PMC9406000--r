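# Independent oracles and small fixture builders shared across tests.

# Brute-force single-residue Kd estimator: for each kd on a log grid the
# amplitude is profiled analytically (linear in dmax given the bound
# fraction), then the grid minimum is polished with optimize(). Shares no
# code with fit_site().
grid_fit_kd <- function(L, y, T0, kd_range = c(1e-3, 1e4), n_grid = 400) {
  bound_frac <- function(kd) {
    s <- T0 + L + kd
    (s - sqrt(pmax(s^2 - 4 * T0 * L, 0))) / (2 * T0)
  }
  ss <- function(kd) {
    b <- bound_frac(kd)
    dmax <- if (sum(b^2) > 0) sum(y * b) / sum(b^2) else 0
    sum((y - dmax * b)^2)
  }
  grid <- exp(seq(log(kd_range[1]), log(kd_range[2]), length.out = n_grid))
  vals <- vapply(grid, ss, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(n_grid, i + 1)]
  stats::optimize(ss, c(lo, hi), tol = 1e-12)$minimum
}

# Naive all-pairs contact-persistence oracle: plain double loops over
# frames, residues, atoms and ions.
naive_persistence <- function(traj, cutoff, threshold = 0.5) {
  residues <- sort(unique(traj$atom_residue))
  frac <- numeric(length(residues))
  for (k in seq_along(residues)) {
    hits <- 0L
    for (f in seq_len(traj$n_frames)) {
      dmin <- Inf
      for (a in which(traj$atom_residue == residues[k]))
        for (i in seq_len(dim(traj$ion_coords)[2])) {
          d <- sqrt(sum((traj$protein_coords[f, a, ] -
                         traj$ion_coords[f, i, ])^2))
          if (d < dmin) dmin <- d
        }
      if (dmin <= cutoff) hits <- hits + 1L
    }
    frac[k] <- hits / traj$n_frames
  }
  list(residue = residues, fraction = frac,
       persistent = residues[frac > threshold])
}

# Two-point titration fixture: the reference and one point whose peaks
# moved by the given per-residue deltas.
make_pair_tables <- function(residues, base_H, base_N, delta_H, delta_N,
                             ligand = 100, T0 = 0.1) {
  code <- rep("A", length(residues))
  list(shift_table(residues, code, base_N, base_H, condition(0, T0)),
       shift_table(residues, code, base_N + delta_N, base_H + delta_H,
                   condition(ligand, T0)))
}

# Titration tables where one residue follows an isotherm exactly
# (noiseless), for small fitting fixtures.
make_isotherm_tables <- function(residue_dmax, kd, T0 = 0.1,
                                 points = c(0, 5, 10, 20, 40, 60, 80, 100)) {
  residues <- as.integer(names(residue_dmax))
  lapply(points, function(L) {
    s <- T0 + L + kd
    b <- (s - sqrt(max(s^2 - 4 * T0 * L, 0))) / (2 * T0)
    shift_table(residues, rep("A", length(residues)),
                shift_N = 120 + numeric(length(residues)),
                shift_H = 8 + residue_dmax * b,
                condition = condition(L, T0))
  })
}
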