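#' Construct an ion trajectory container
#'
#' Holds protein atom coordinates grouped by residue plus ion coordinates
#' for an ordered sequence of frames. Usually produced by
#' [read_multimodel_pdb()] or [simulate_trajectory()] rather than by hand.
#'
#' @param protein_coords Array `n_frames x n_atoms x 3` (Angstrom).
#' @param atom_residue Integer vector (length `n_atoms`): residue number of
#'   each protein atom.
#' @param atom_name Character vector (length `n_atoms`): PDB atom names.
#' @param ion_coords Array `n_frames x n_ions x 3`.
#' @param ion_labels Character vector (length `n_ions`).
#' @param box Optional periodic box edge lengths (length 3, Angstrom),
#'   e.g. from a CRYST1 record; used only to sanity-check that the
#'   trajectory was wrapped upstream.
#' @return An object of class `"ion_trajectory"`.
#' @export
ion_trajectory <- function(protein_coords, atom_residue, atom_name,
                           ion_coords, ion_labels = NULL, box = NULL) {
  if (length(dim(protein_coords)) != 3 || dim(protein_coords)[3] != 3)
    stop("'protein_coords' must be an n_frames x n_atoms x 3 array",
         call. = FALSE)
  if (length(dim(ion_coords)) != 3 || dim(ion_coords)[3] != 3)
    stop("'ion_coords' must be an n_frames x n_ions x 3 array",
         call. = FALSE)
  nf <- dim(protein_coords)[1]
  if (nf < 1) stop("need >= 1 frame", call. = FALSE)
  if (dim(ion_coords)[1] != nf)
    stop("protein and ion frame counts differ", call. = FALSE)
  if (dim(protein_coords)[2] != length(atom_residue) ||
      length(atom_residue) != length(atom_name))
    stop("atom metadata length must match atom count", call. = FALSE)
  if (!all(is.finite(protein_coords)) || !all(is.finite(ion_coords)))
    stop("coordinates must be finite", call. = FALSE)
  if (is.null(ion_labels)) ion_labels <- rep("ION", dim(ion_coords)[2])
  if (!is.null(box) && (length(box) != 3 || any(box <= 0)))
    stop("'box' must be 3 positive edge lengths", call. = FALSE)
  structure(
    list(protein_coords = protein_coords,
         atom_residue = as.integer(atom_residue),
         atom_name = as.character(atom_name),
         ion_coords = ion_coords, ion_labels = as.character(ion_labels),
         n_frames = nf, box = box),
    class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf(paste0("ion_trajectory: %d frame(s), %d protein atom(s) in ",
                     "%d residue(s), %d ion(s)\n"),
              x$n_frames, length(x$atom_residue),
              length(unique(x$atom_residue)), dim(x$ion_coords)[2]))
  invisible(x)
}

#' Minimum residue-ion distance
#'
#' Minimum Euclidean distance over all atom-ion pairs, in Angstrom.
#'
#' @param atoms Numeric matrix `n x 3` of residue atom coordinates.
#' @param ions Numeric matrix `m x 3` of ion coordinates.
#' @return Single distance (Angstrom).
#' @examples
#' min_ion_distance(rbind(c(0, 0, 0), c(10, 0, 0)),
#'                  rbind(c(4, 0, 0), c(6, 0, 0)))   # 4
#' @export
min_ion_distance <- function(atoms, ions) {
  atoms <- as.matrix(atoms); ions <- as.matrix(ions)
  if (nrow(atoms) == 0 || nrow(ions) == 0)
    stop("empty coordinate set", call. = FALSE)
  if (ncol(atoms) != 3 || ncol(ions) != 3)
    stop("coordinates must have 3 columns", call. = FALSE)
  d2 <- outer(rowSums(atoms^2), rowSums(ions^2), "+") -
    2 * atoms %*% t(ions)
  sqrt(max(min(d2), 0))
}

# PDB names of backbone atoms (heavy + amide/alpha hydrogens)
.backbone_atoms <- c("N", "CA", "C", "O", "OXT", "H", "HN", "H1", "H2",
                     "H3", "HA", "HA2", "HA3")

#' Per-residue ion-contact persistence over a trajectory
#'
#' For every residue, counts the frames in which some ion lies within
#' `cutoff` of any of the residue's atoms (restricted to `atom_scope`) and
#' reports the contact fraction as an exact frame-count ratio. Residues in
#' contact for strictly more than `threshold` of the frames form the
#' persistent set ("more than 50% of the simulation time" at the
#' defaults).
#'
#' @param traj An [ion_trajectory()].
#' @param cutoff Contact distance cutoff, Angstrom (> 0). Default 3.5, the
#'   conventional first-shell criterion for Ca2+.
#' @param threshold Persistence fraction threshold in \[0, 1). Strict
#'   inequality: a residue at exactly the threshold is not persistent.
#' @param atom_scope Which residue atoms enter the distance search:
#'   `"all"` (default), `"sidechain"` or `"backbone"`.
#' @param include_hydrogens If `FALSE`, atoms whose name starts with H are
#'   excluded (heavy-atom criterion).
#' @return An object of class `"persistence_profile"`: a `table` data frame
#'   (`residue`, `n_contact_frames`, `n_frames`, `fraction`, `persistent`),
#'   the `persistent` residue set, and the parameters used.
#' @export
persistence <- function(traj, cutoff = 3.5, threshold = 0.5,
                        atom_scope = c("all", "sidechain", "backbone"),
                        include_hydrogens = TRUE) {
  stopifnot(inherits(traj, "ion_trajectory"))
  atom_scope <- match.arg(atom_scope)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0)
    stop("'cutoff' must be a positive distance", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold >= 1)
    stop("'threshold' must be in [0, 1)", call. = FALSE)
  if (traj$n_frames < 1) stop("no frames", call. = FALSE)

  sel <- rep(TRUE, length(traj$atom_name))
  nm <- toupper(trimws(traj$atom_name))
  if (atom_scope == "backbone") sel <- nm %in% .backbone_atoms
  if (atom_scope == "sidechain") sel <- !(nm %in% .backbone_atoms)
  if (!include_hydrogens) sel <- sel & !grepl("^[0-9]*H", nm)

  residues <- sort(unique(traj$atom_residue))
  counts <- stats::setNames(integer(length(residues)), residues)
  # PBC is assumed handled upstream; if the periodic box is known, warn
  # when a distance exceeds its diagonal (an unwrapped trajectory)
  box_diag <- if (!is.null(traj$box)) sqrt(sum(traj$box^2)) else Inf
  max_seen <- 0
  for (f in seq_len(traj$n_frames)) {
    ions <- traj$ion_coords[f, , , drop = FALSE]
    dim(ions) <- dim(traj$ion_coords)[2:3]
    for (k in seq_along(residues)) {
      asel <- sel & traj$atom_residue == residues[k]
      if (!any(asel)) next
      atoms <- traj$protein_coords[f, asel, , drop = FALSE]
      dim(atoms) <- c(sum(asel), 3)
      d <- min_ion_distance(atoms, ions)
      max_seen <- max(max_seen, d)
      if (d <= cutoff) counts[k] <- counts[k] + 1L
    }
  }
  if (max_seen > box_diag)
    warning("ion-protein distances exceed the periodic box diagonal; ",
            "trajectory may not be wrapped (no minimum-image correction ",
            "is applied)")
  frac <- counts / traj$n_frames
  tab <- data.frame(residue = residues,
                    n_contact_frames = as.integer(counts),
                    n_frames = traj$n_frames,
                    fraction = as.numeric(frac),
                    persistent = as.numeric(frac) > threshold)
  structure(
    list(table = tab, persistent = residues[tab$persistent],
         cutoff = cutoff, threshold = threshold, atom_scope = atom_scope,
         include_hydrogens = include_hydrogens),
    class = "persistence_profile")
}

#' @export
print.persistence_profile <- function(x, ...) {
  cat(sprintf(paste0("ion-contact persistence (cutoff %.2f A, scope %s, ",
                     "threshold > %g)\n"),
              x$cutoff, x$atom_scope, x$threshold))
  print(x$table, row.names = FALSE)
  cat("persistent residues:",
      if (length(x$persistent)) paste(x$persistent, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Write a persistence table as TSV
#'
#' @param profile A [persistence()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_persistence_table <- function(profile, path) {
  stopifnot(inherits(profile, "persistence_profile"))
  utils::write.table(profile$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a multi-model PDB as an ion trajectory
#'
#' Reads a MODEL/ENDMDL coordinate file (one MODEL per frame) and splits
#' atoms into protein (grouped by residue number) and ions. Ions are
#' selected by residue name, not atom name, to avoid the PDB "CA"
#' collision between calcium ions and alpha carbons; if any atom named CA
#' inside a standard amino-acid residue would also match the selector, a
#' warning explains that only residue-name matches were taken.
#'
#' @param path PDB file path.
#' @param ion_names Residue names identifying ions (default `c("CA",
#'   "CAL")` for calcium).
#' @return An [ion_trajectory()].
#' @export
read_multimodel_pdb <- function(path, ion_names = c("CA", "CAL")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  n_model <- sum(grepl("^MODEL", lines))
  if (n_model == 0)
    warning("no MODEL records: treating '", basename(path),
            "' as a single-frame trajectory")
  else {
    # per-MODEL atom counts must agree or frames are not comparable
    starts <- grep("^MODEL", lines); ends <- grep("^ENDMDL", lines)
    if (length(starts) == length(ends)) {
      counts <- mapply(function(s, e)
        sum(grepl("^(ATOM|HETATM)", lines[s:e])), starts, ends)
      if (length(unique(counts)) > 1)
        stop("mismatched atom counts across MODEL records: ",
             paste(unique(counts), collapse = " vs "), call. = FALSE)
    }
  }
  cryst <- grep("^CRYST1", lines, value = TRUE)
  box <- if (length(cryst) > 0) {
    v <- suppressWarnings(as.numeric(c(substr(cryst[1], 7, 15),
                                       substr(cryst[1], 16, 24),
                                       substr(cryst[1], 25, 33))))
    if (all(is.finite(v)) && all(v > 0)) v else NULL
  } else NULL
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  xyz <- pdb$xyz                       # n_frames x 3*n_atoms
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(atom)
  resid <- toupper(trimws(atom$resid))
  is_ion <- resid %in% toupper(ion_names)
  if (!any(is_ion))
    stop("no ion found with residue name in {",
         paste(ion_names, collapse = ", "), "}", call. = FALSE)
  if (any(toupper(trimws(atom$elety[!is_ion])) %in% toupper(ion_names)))
    warning("protein atoms named like the ion selector exist (e.g. alpha ",
            "carbons 'CA'); ions were matched by residue name only")
  coords <- array(xyz, dim = c(nf, 3, na))   # frames x (x,y,z) x atoms
  coords <- aperm(coords, c(1, 3, 2))        # frames x atoms x 3
  ion_trajectory(
    protein_coords = coords[, !is_ion, , drop = FALSE],
    atom_residue = atom$resno[!is_ion],
    atom_name = atom$elety[!is_ion],
    ion_coords = coords[, is_ion, , drop = FALSE],
    ion_labels = paste0(resid[is_ion], atom$resno[is_ion]),
    box = box)
}

#' Write an ion trajectory as a multi-model PDB
#'
#' Protein atoms are written as ATOM records (ions as HETATM with their
#' label's residue name, default CA). Inverse of [read_multimodel_pdb()]
#' to coordinate precision (3 decimals).
#'
#' @param traj An [ion_trajectory()].
#' @param path Output path.
#' @param ion_resname Residue name for ion HETATM records.
#' @return Invisibly, `path`.
#' @export
write_multimodel_pdb <- function(traj, path, ion_resname = "CA") {
  stopifnot(inherits(traj, "ion_trajectory"))
  na <- length(traj$atom_residue); ni <- dim(traj$ion_coords)[2]
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    for (a in seq_len(na)) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, substr(traj$atom_name[a], 1, 4), "GLY",
        traj$atom_residue[a],
        traj$protein_coords[f, a, 1], traj$protein_coords[f, a, 2],
        traj$protein_coords[f, a, 3]), con)
    }
    for (i in seq_len(ni)) {
      serial <- serial + 1L
      writeLines(sprintf(
        "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, substr(ion_resname, 1, 4), substr(ion_resname, 1, 3),
        9000L + i,
        traj$ion_coords[f, i, 1], traj$ion_coords[f, i, 2],
        traj$ion_coords[f, i, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
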