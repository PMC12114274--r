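#' Construct a docking pose
#'
#' @param pose_id integer identifier, unique within a pose set.
#' @param energy binding energy in kcal/mol (lower is better).
#' @param coords n x 3 matrix of ligand coordinates in Angstrom; all poses
#'   of a set share the atom count and ordering (one docking frame).
#' @return a `Pose` object.
#' @export
pose <- function(pose_id, energy, coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)), is.finite(energy))
  structure(list(pose_id = as.integer(pose_id), energy = as.numeric(energy),
                 coords = coords),
            class = "Pose")
}

#' RMSD between two poses in the shared docking frame
#'
#' `sqrt(mean_i |a_i - b_i|^2)` over matched atoms, computed without
#' re-superposition and without symmetry correction: all poses of one
#' ligand live in the one receptor frame with a fixed atom order.
#'
#' @param a,b `Pose` objects with equal atom counts and ordering.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b) {
  if (nrow(a$coords) != nrow(b$coords))
    stop("atom-count mismatch: ", nrow(a$coords), " vs ", nrow(b$coords))
  sqrt(mean(rowSums((a$coords - b$coords)^2)))
}

new_cluster_set <- function(clusters, representatives, rep_energy, coverage,
                            threshold, n_poses) {
  structure(list(clusters = clusters,
                 sizes = lengths(clusters),
                 representatives = representatives,
                 rep_energy = rep_energy,
                 coverage = coverage,
                 threshold = threshold,
                 n_poses = n_poses),
            class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet: %d poses in %d clusters (threshold %g A), sizes: %s\n",
              x$n_poses, length(x$clusters), x$threshold,
              paste(x$sizes, collapse = ", ")))
  cat(sprintf("  representatives: %s (coverage %.2f)\n",
              paste(x$representatives, collapse = ", "), x$coverage))
  invisible(x)
}

#' Cluster docking poses by RMSD similarity
#'
#' Energy-sorted leader algorithm: repeatedly seed a new cluster with the
#' lowest-energy unassigned pose (ties broken by ascending `pose_id`) and
#' assign to it every unassigned pose within `threshold` RMSD of the seed.
#' Each seed is therefore the minimum-energy member of its cluster and
#' doubles as its representative. Clusters are reported in seeding order.
#'
#' @param poses list of `Pose` objects.
#' @param threshold structural homogeneity ceiling in Angstrom RMSD
#'   (default 10).
#' @return a `ClusterSet`: disjoint exhaustive clusters (pose-id lists),
#'   per-cluster representatives and energies, coverage 1 (all clusters
#'   represented until [select_representatives()] prunes them), threshold.
#' @export
cluster_poses <- function(poses, threshold = 10.0) {
  if (length(poses) == 0) stop("at least one pose is required")
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be positive")
  n_atoms <- vapply(poses, function(p) nrow(p$coords), integer(1))
  if (length(unique(n_atoms)) != 1)
    stop("atom-count mismatch: all poses in a set must share atom count and order")
  ids <- vapply(poses, function(p) p$pose_id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate pose_ids")
  energy <- vapply(poses, function(p) p$energy, numeric(1))

  ord <- order(energy, ids)              # deterministic seeding order
  unassigned <- rep(TRUE, length(poses))
  clusters <- list(); reps <- integer(); rep_e <- numeric()
  while (any(unassigned)) {
    seed <- ord[unassigned[ord]][1]
    members <- which(unassigned)
    d <- vapply(members, function(j) pose_rmsd(poses[[seed]], poses[[j]]),
                numeric(1))
    take <- members[d <= threshold]
    clusters[[length(clusters) + 1L]] <- sort(ids[take])
    reps <- c(reps, ids[seed])
    rep_e <- c(rep_e, energy[seed])
    unassigned[take] <- FALSE
  }
  new_cluster_set(clusters, reps, rep_e, coverage = 1.0,
                  threshold = threshold, n_poses = length(poses))
}

#' Select best-energy representatives up to a coverage target
#'
#' Clusters are ranked by size descending (ties by better, i.e. lower,
#' representative energy, then by lower representative pose id) and their
#' representatives accumulated in rank order until the selected clusters
#' hold at least `min_coverage` of all poses. Greedy selection by
#' descending size uses the fewest clusters possible for any coverage
#' target.
#'
#' @param cs a `ClusterSet` from [cluster_poses()].
#' @param min_coverage required fraction of poses represented, in `(0, 1]`
#'   (default 0.70).
#' @return a `ClusterSet` whose `representatives`/`rep_energy` are the
#'   selected ones in rank order, with achieved `coverage` and the indices
#'   of selected clusters in `selected`.
#' @export
select_representatives <- function(cs, min_coverage = 0.70) {
  if (!is.numeric(min_coverage) || min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must lie in (0, 1]")
  rank <- order(-cs$sizes, cs$rep_energy, cs$representatives)
  cum <- cumsum(cs$sizes[rank]) / cs$n_poses
  n_sel <- which(cum >= min_coverage)[1]
  sel <- rank[seq_len(n_sel)]
  out <- new_cluster_set(cs$clusters, cs$representatives[sel],
                         cs$rep_energy[sel], coverage = cum[n_sel],
                         threshold = cs$threshold, n_poses = cs$n_poses)
  out$selected <- sel
  out
}
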