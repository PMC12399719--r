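# MD-trajectory analyses: RMSD time series, per-frame interaction occupancy,
# and stride-based clustering with representative-frame extraction.
#
# Every frame is first superposed onto the reference frame by a Kabsch fit
# over the protein alpha-carbons (bio3d); ligand RMSD uses heavy atoms only.
# The reference is frame 1 of the supplied trajectory (the deviation is
# measured from the initial crystallographic or docked pose), configurable
# to an external reference.

ca_indices <- function(protein) {
  which(protein$atoms$name == "CA" & protein$atoms$element == "C")
}

# superpose all frames onto the reference by CA fit; returns list of fitted
# coordinate matrices
superpose_frames <- function(traj, ref = NULL) {
  ca <- ca_indices(traj$protein)
  if (!length(ca)) stop("no alpha-carbon (CA) atoms in the topology")
  refmat <- if (is.null(ref)) traj$frames[[1L]] else ref
  ref_vec <- as.vector(t(refmat))
  inds <- as.vector(rbind(3 * ca - 2, 3 * ca - 1, 3 * ca))
  lapply(traj$frames, function(f) {
    ft <- bio3d::fit.xyz(ref_vec, as.vector(t(f)),
                         fixed.inds = inds, mobile.inds = inds)
    matrix(ft, ncol = 3L, byrow = TRUE)
  })
}

#' Per-frame RMSD time series of a trajectory
#'
#' Each frame is superposed onto frame 1 by an alpha-carbon Kabsch fit; the
#' RMSD is then computed over the named selection in the fitted frame.
#'
#' @param traj a `trajectory` with >= 2 frames.
#' @param selection `"protein_alpha_carbons"` or `"ligand_heavy_atoms"`.
#' @param reference optional external reference coordinate matrix (same
#'   layout as a frame); default frame 1.
#' @return object of class `rmsd_series`: `selection`, `rmsd` (A per frame),
#'   `mean`, `time_ps`.
#' @export
rmsd_series <- function(traj,
                        selection = c("protein_alpha_carbons",
                                      "ligand_heavy_atoms"),
                        reference = NULL) {
  selection <- match.arg(selection)
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  np <- nrow(traj$protein$atoms)
  sel <- if (selection == "protein_alpha_carbons") {
    ca_indices(traj$protein)
  } else {
    np + heavy_atoms(traj$ligand)
  }
  if (!length(sel))
    stop(if (selection == "protein_alpha_carbons")
      "no alpha-carbon (CA) atoms in the topology" else "empty selection")
  refmat <- if (is.null(reference)) traj$frames[[1L]] else reference
  fitted <- superpose_frames(traj, ref = reference)
  refsel <- refmat[sel, , drop = FALSE]
  vals <- vapply(fitted, function(f)
    sqrt(mean(rowSums((f[sel, , drop = FALSE] - refsel)^2))), 0)
  structure(list(selection = selection, rmsd = vals, mean = mean(vals),
                 time_ps = (seq_along(vals) - 1L) * traj$frame_interval),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("<rmsd_series> %s: %d frames, mean %.2f A\n",
              x$selection, length(x$rmsd), x$mean))
  invisible(x)
}

#' Interaction occupancy over a trajectory
#'
#' Runs the geometric detectors on every frame and reports, per interaction
#' key (kind + protein residue), the fraction of frames in which the
#' interaction is present.  A frame counts once per key even when several
#' atom pairs qualify, matching per-residue occupancy percentages.  Keys
#' never observed are omitted.
#'
#' @param traj a `trajectory`.
#' @param detectors character subset of `c("hbond", "pi_stack",
#'   "hydrophobic", "halogen")`.
#' @param criteria an [hbond_criteria()] for the H-bond detector.
#' @param residue_scope optional residue filter (as in [detect_hbonds()]);
#'   applied to the H-bond detector only.
#' @return object of class `occupancy_report`: data.frame with columns
#'   `key`, `kind`, `chain`, `resno`, `resid`, `fraction`, plus attribute
#'   `n_frames`.
#' @export
occupancy <- function(traj, detectors = "hbond",
                      criteria = hbond_criteria(), residue_scope = NULL) {
  stopifnot(inherits(traj, "trajectory"),
            all(detectors %in% c("hbond", "pi_stack", "hydrophobic",
                                 "halogen")))
  nf <- n_frames(traj)
  counts <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (k in seq_len(nf)) {
    fc <- frame_complex(traj, k)
    recs <- list()
    if ("hbond" %in% detectors)
      recs$hb <- detect_hbonds(fc$pose, fc$protein, criteria,
                               residue_filter = residue_scope)
    if ("pi_stack" %in% detectors)
      recs$pi <- detect_pi_stack(fc$pose, fc$protein)
    if ("hydrophobic" %in% detectors)
      recs$hp <- detect_hydrophobic(fc$pose, fc$protein)
    if ("halogen" %in% detectors)
      recs$hx <- detect_halogen(fc$pose, fc$protein)
    recs <- do.call(rbind, recs)
    if (is.null(recs) || !nrow(recs)) next
    keys <- unique(data.frame(kind = recs$kind, chain = recs$chain,
                              resno = recs$resno, resid = recs$resid,
                              stringsAsFactors = FALSE))
    for (r in seq_len(nrow(keys))) {
      key <- sprintf("%s:%s:%d", keys$kind[r], keys$chain[r], keys$resno[r])
      assign(key, get0(key, envir = counts, ifnotfound = 0L) + 1L,
             envir = counts)
      assign(key, keys[r, ], envir = meta)
    }
  }
  keys <- ls(counts)
  df <- if (length(keys)) {
    data.frame(key = keys,
               do.call(rbind, lapply(keys, function(k) meta[[k]])),
               fraction = vapply(keys, function(k) counts[[k]] / nf, 0),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(key = character(), kind = character(), chain = character(),
               resno = integer(), resid = character(), fraction = numeric(),
               stringsAsFactors = FALSE)
  }
  df <- df[order(-df$fraction, df$key), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("occupancy_report", "data.frame"),
            n_frames = nf)
}

#' Stride-based trajectory clustering with a representative frame
#'
#' Subsamples every `stride`-th frame, builds the pairwise ligand heavy-atom
#' RMSD matrix after alpha-carbon superposition, and clusters it by
#' complete linkage at `cutoff`.  When more than `max_clusters` clusters
#' result, only the `max_clusters` largest are kept and the remaining frames
#' are pooled as unclustered (cluster id 0).  The representative is the
#' member of the most populated cluster minimizing the summed RMSD to its
#' co-members.
#'
#' @param traj a `trajectory`.
#' @param stride keep every `stride`-th frame (in frames; >= 1).
#' @param max_clusters maximum number of clusters to keep.
#' @param cutoff complete-linkage RMSD cutoff in Angstrom (required; the
#'   choice is analysis-dependent and no default is claimed).
#' @return list with `frame_indices` (original indices of the subsample),
#'   `assignments` (cluster id per subsampled frame, 0 = unclustered),
#'   `sizes`, `representative_frame` (original frame index), `matrix`.
#' @export
cluster_trajectory <- function(traj, stride = 10, max_clusters = 5, cutoff) {
  stopifnot(inherits(traj, "trajectory"), stride >= 1, max_clusters >= 1)
  if (missing(cutoff)) stop("cutoff is required")
  idx <- seq(1L, n_frames(traj), by = stride)
  if (length(idx) < 2L)
    stop("fewer than 2 frames after subsampling (stride too large)")
  sub <- subset_trajectory(traj, idx)
  fitted <- superpose_frames(sub)
  np <- nrow(traj$protein$atoms)
  lh <- np + heavy_atoms(traj$ligand)
  lig <- traj$ligand
  poses <- lapply(seq_along(idx), function(k) {
    g <- set_graph_coords(lig, fitted[[k]][np + seq_len(n_atoms(lig)), ,
                                           drop = FALSE])
    pose(g, program = sprintf("frame%d", idx[k]))
  })
  mat <- rmsd_matrix(pose_ensemble(poses))
  cl <- complete_linkage(mat, cutoff = cutoff)
  assignments <- cl$assignments
  if (length(cl$sizes) > max_clusters) {
    assignments[assignments > max_clusters] <- 0L
  }
  main <- which(assignments == 1L)
  m <- mat$values
  rep_local <- main[which.min(rowSums(m[main, main, drop = FALSE]))]
  list(frame_indices = idx,
       assignments = assignments,
       sizes = table(factor(assignments[assignments > 0L])),
       representative_frame = idx[rep_local],
       matrix = mat)
}

#' Recompute a trajectory metric per window
#'
#' Splits the trajectory at the given frame boundaries and recomputes the
#' metric independently on each window (an RMSD series uses the window's own
#' first frame as reference).
#'
#' @param traj a `trajectory`.
#' @param windows list of `c(first, last)` frame index pairs (1-based,
#'   inclusive, within the trajectory).
#' @param metric `"occupancy"` or `"rmsd_series"`.
#' @param ... passed to the metric function.
#' @return named list of per-window reports (`frames a-b`).
#' @export
split_report <- function(traj, windows, metric = c("occupancy",
                                                   "rmsd_series"), ...) {
  metric <- match.arg(metric)
  stopifnot(inherits(traj, "trajectory"), length(windows) >= 1L)
  fn <- switch(metric, occupancy = occupancy, rmsd_series = rmsd_series)
  out <- list()
  for (w in windows) {
    if (length(w) != 2L || w[1L] > w[2L]) stop("empty window")
    if (w[1L] < 1L || w[2L] > n_frames(traj))
      stop("window ", w[1L], "-", w[2L], " outside the trajectory")
    out[[sprintf("frames %d-%d", w[1L], w[2L])]] <-
      fn(subset_trajectory(traj, w[1L]:w[2L]), ...)
  }
  out
}
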