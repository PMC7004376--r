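# Groove pocket model and B/F/O pose assignment: deterministic k-means on
# reference-atom coordinates, nearest-pocket labelling, outside-groove
# thresholding.

#' Default groove pocket residue definitions
#'
#' Mature-numbering residue sets for the six class I groove subsites that
#' this package labels against. The F pocket combines the residues
#' reported to surround it in ligand contacts (77, 80, 81, 84, 123 and
#' 95, 116, 124, 143, 147) with canonical 146; the B pocket uses the
#' canonical literature set. Both are overridable.
#'
#' @return Named list of integer vectors (`B`, `F`).
#' @export
default_pocket_definitions <- function() {
  list(B = c(7L, 9L, 24L, 25L, 34L, 45L, 63L, 66L, 67L, 70L, 99L),
       F = c(77L, 80L, 81L, 84L, 95L, 116L, 123L, 124L, 143L, 146L, 147L))
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Build a groove pocket model from a structure
#'
#' Each requested pocket's centroid is the mean position of the
#' side-chain atoms of its residues that are present in the structure.
#'
#' @param structure A `structure3d` (mature residue numbering assumed).
#' @param definitions Named list of residue-position vectors, e.g. from
#'   [default_pocket_definitions()]. Labels must be among A-F.
#' @param groove_radius Distance threshold (Angstrom) beyond which a pose
#'   counts as outside the groove (label `O`); default 12.
#' @return A `pocket_model`: list of pockets (each with `positions`,
#'   `centroid`) plus `groove_radius`.
#' @export
build_pocket_model <- function(structure,
                               definitions = default_pocket_definitions(),
                               groove_radius = 12) {
  stopifnot(inherits(structure, "structure3d"), groove_radius > 0)
  labels <- names(definitions)
  if (is.null(labels) || !all(labels %in% c("A", "B", "C", "D", "E", "F"))) {
    stop("pocket labels must be named among A-F")
  }
  if (anyDuplicated(labels)) stop("duplicate pocket labels")
  atoms <- structure$atoms
  side <- atoms[!(atoms$name %in% BACKBONE_ATOMS), , drop = FALSE]
  pockets <- lapply(labels, function(lab) {
    pos <- definitions[[lab]]
    sel <- side[side$resno %in% pos, , drop = FALSE]
    if (nrow(sel) == 0L) {
      stop("pocket ", lab, ": no resolvable side-chain atoms among positions ",
           paste(pos, collapse = ", "), " in '", structure$label, "'")
    }
    list(positions = sort(unique(sel$resno)),
         centroid = c(x = mean(sel$x), y = mean(sel$y), z = mean(sel$z)))
  })
  names(pockets) <- labels
  structure(list(pockets = pockets, groove_radius = groove_radius),
            class = "pocket_model")
}

#' @export
print.pocket_model <- function(x, ...) {
  cat("<pocket_model> pockets ", paste(names(x$pockets), collapse = ", "),
      "; groove radius ", x$groove_radius, " A\n", sep = "")
  invisible(x)
}

#' Cluster docking poses on their reference-atom coordinates
#'
#' k-means on the designated reference atom (default `C1`) of each pose,
#' so dissimilar ligands with different atom counts share one clustering.
#' The procedure is deterministic and independent of pose order:
#' initial centres come from farthest-point seeding (restart `r` starts
#' from the r-th most peripheral point, ties broken on coordinates),
#' Lloyd iterations refine each start, and the lowest within-cluster sum
#' of squares wins (ties to the lowest restart index). Cluster ids are
#' relabelled in ascending order of centre coordinates.
#'
#' @param poses List of `ligand_pose` objects.
#' @param k Number of clusters; the groove analysis fixes `k = 2` for the
#'   two visually distinct groups in the B and F pockets.
#' @param seed Accepted for interface stability; the algorithm is fully
#'   deterministic so the seed does not alter results.
#' @param reference_atom Optional override of each pose's reference atom.
#' @param restarts Number of deterministic farthest-point restarts.
#' @return Integer cluster id per pose, with attribute `centers` (k x 3).
#' @export
cluster_poses <- function(poses, k = 2L, seed = 1L, reference_atom = NULL,
                          restarts = 10L) {
  stopifnot(k >= 1L)
  if (length(poses) < k) {
    stop("fewer poses (", length(poses), ") than clusters (", k, ")")
  }
  X <- pose_reference_coords(poses, reference_atom)
  kmeans_deterministic(X, k, restarts)
}

# Deterministic k-means: farthest-point seeding + Lloyd, empty-cluster
# tolerant (an emptied cluster keeps its previous centre).
kmeans_deterministic <- function(X, k, restarts = 10L) {
  n <- nrow(X)
  canon <- order(X[, 1L], X[, 2L], X[, 3L])
  rank_canon <- integer(n)
  rank_canon[canon] <- seq_len(n)
  d_center <- sqrt(rowSums(sweep(X, 2, colMeans(X))^2))
  # peripheral ordering: decreasing distance from the data centroid,
  # coordinate order breaking ties
  periph <- order(-d_center, rank_canon)
  best <- NULL
  for (r in seq_len(min(restarts, n))) {
    centers <- farthest_point_init(X, k, start = periph[r], rank_canon)
    fit <- lloyd(X, centers)
    if (is.null(best) || fit$tot_withinss < best$tot_withinss - 1e-12) {
      best <- fit
    }
  }
  # canonical cluster ids: ascending centre coordinates
  ord <- order(best$centers[, 1L], best$centers[, 2L], best$centers[, 3L])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  ids <- relabel[best$cluster]
  attr(ids, "centers") <- best$centers[ord, , drop = FALSE]
  attr(ids, "tot_withinss") <- best$tot_withinss
  ids
}

farthest_point_init <- function(X, k, start, rank_canon) {
  chosen <- start
  if (k > 1L) {
    d_min <- sqrt(rowSums(sweep(X, 2, X[start, ])^2))
    for (j in seq_len(k - 1L)) {
      nxt <- order(-d_min, rank_canon)[1L]
      chosen <- c(chosen, nxt)
      d_new <- sqrt(rowSums(sweep(X, 2, X[nxt, ])^2))
      d_min <- pmin(d_min, d_new)
    }
  }
  X[chosen, , drop = FALSE]
}

lloyd <- function(X, centers, iter_max = 100L) {
  k <- nrow(centers)
  n <- nrow(X)
  assign_old <- rep(0L, n)
  for (it in seq_len(iter_max)) {
    d2 <- vapply(seq_len(k), function(j) {
      rowSums(sweep(X, 2, centers[j, ])^2)
    }, numeric(n))
    d2 <- matrix(d2, nrow = n)
    cl <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (any(cl == j)) {
        centers[j, ] <- colMeans(X[cl == j, , drop = FALSE])
      } # empty cluster keeps its centre
    }
    if (identical(cl, assign_old)) break
    assign_old <- cl
  }
  tot <- sum(vapply(seq_len(k), function(j) {
    if (!any(cl == j)) return(0)
    sum(sweep(X[cl == j, , drop = FALSE], 2, centers[j, ])^2)
  }, numeric(1L)))
  list(cluster = cl, centers = centers, tot_withinss = tot)
}

#' Label pose clusters as B, F or O
#'
#' Each cluster takes the label of the nearest pocket centroid (among B
#' and F) to its cluster mean; any individual pose whose reference atom
#' lies farther than the model's groove radius from both the B and F
#' centroids is relabelled `O` (outside the binding groove), the
#' reproducible surrogate for visual outside-groove calls.
#'
#' @param poses List of `ligand_pose` objects.
#' @param clusters Integer cluster ids from [cluster_poses()].
#' @param model A `pocket_model` containing `B` and `F` pockets.
#' @param reference_atom Optional reference-atom override.
#' @return Data frame with columns `pose_index`, `cluster_id`, `label`.
#' @export
label_clusters <- function(poses, clusters, model, reference_atom = NULL) {
  stopifnot(inherits(model, "pocket_model"))
  if (!all(c("B", "F") %in% names(model$pockets))) {
    stop("pocket model must contain B and F pockets")
  }
  X <- pose_reference_coords(poses, reference_atom)
  cB <- model$pockets$B$centroid
  cF <- model$pockets$F$centroid
  lab <- character(max(clusters))
  for (j in sort(unique(clusters))) {
    m <- colMeans(X[clusters == j, , drop = FALSE])
    lab[j] <- if (sqrt(sum((m - cB)^2)) <= sqrt(sum((m - cF)^2))) "B" else "F"
  }
  label <- lab[clusters]
  dB <- sqrt(rowSums(sweep(X, 2, cB)^2))
  dF <- sqrt(rowSums(sweep(X, 2, cF)^2))
  label[dB > model$groove_radius & dF > model$groove_radius] <- "O"
  data.frame(pose_index = seq_along(poses),
             cluster_id = as.integer(clusters),
             label = label,
             stringsAsFactors = FALSE)
}

#' Assign docking poses to groove pockets
#'
#' Convenience wrapper: builds the pocket model, clusters the poses on
#' their reference atoms with `k = 2`, labels clusters B/F, applies the
#' outside-groove threshold, and returns one row per pose in the shape
#' used by the pose summary tables.
#'
#' @param structure Allele `structure3d`.
#' @param poses List of `ligand_pose` objects.
#' @param k,seed Passed to [cluster_poses()].
#' @param definitions,groove_radius Passed to [build_pocket_model()].
#' @return Data frame with columns `pose_index`, `run_id`,
#'   `search_space`, `score`, `cluster_id`, `label`.
#' @export
assign_pockets <- function(structure, poses, k = 2L, seed = 1L,
                           definitions = default_pocket_definitions(),
                           groove_radius = 12) {
  model <- build_pocket_model(structure, definitions, groove_radius)
  clusters <- cluster_poses(poses, k = k, seed = seed)
  lab <- label_clusters(poses, clusters, model)
  data.frame(pose_index = lab$pose_index,
             run_id = vapply(poses, `[[`, integer(1L), "run_id"),
             search_space = vapply(poses, `[[`, character(1L), "search_space"),
             score = vapply(poses, `[[`, numeric(1L), "score"),
             cluster_id = lab$cluster_id,
             label = lab$label,
             stringsAsFactors = FALSE)
}
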