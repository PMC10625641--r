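#' Save or load a trajectory container
#'
#' Trajectories are stored as a single serialized R container (frames,
#' energies, protocol and seed provenance).
#'
#' @param traj A `dna_trajectory`.
#' @param path File path.
#' @return `load_trajectory` returns the `dna_trajectory`.
#' @export
save_trajectory <- function(traj, path) {
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname save_trajectory
#' @export
load_trajectory <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "dna_trajectory")) stop("not a dnadyn trajectory: ", path)
  x
}

#' Export a trajectory as multi-frame XYZ
#'
#' One pseudo-atom per node, frames concatenated in XYZ convention
#' (coordinates in nm).
#'
#' @param traj A `dna_trajectory`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
export_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(traj$pos)[1]
  for (f in seq_len(n_frames(traj))) {
    writeLines(c(as.character(n), sprintf("t= %.6f ns", traj$time[f])), con)
    p <- traj$pos[, , f]
    writeLines(sprintf("C %12.6f %12.6f %12.6f", p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Export a state or trajectory frame as a pseudo-atom PDB
#'
#' One CA record per node (coordinates converted to Angstrom) for quick
#' visualization.
#'
#' @param x A `dna_state` or `dna_trajectory` (first frame used).
#' @param path Output path.
#' @param frame Frame index when `x` is a trajectory.
#' @return Invisibly `path`.
#' @export
export_pdb <- function(x, path, frame = 1) {
  p <- if (inherits(x, "dna_trajectory")) x$pos[, , frame] else x$pos
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(p))) {
    writeLines(sprintf(
      "ATOM  %5d  CA  NOD A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, i, 10 * p[i, 1], 10 * p[i, 2], 10 * p[i, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}
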