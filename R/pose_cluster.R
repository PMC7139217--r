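# Redundancy grouping, centroid clustering and cross-engine consensus of
# docking poses.

pose_ids <- function(poses) vapply(poses, function(p) p$pose_id, character(1))

# "goodness": larger is always better, regardless of engine orientation
.pose_goodness <- function(poses) {
  sc <- vapply(poses, function(p) p$engine_score, numeric(1))
  orient <- vapply(poses, function(p)
    p$score_orientation %||% NA_character_, character(1))
  eng <- vapply(poses, function(p)
    ifelse(is.na(p$engine), "", p$engine), character(1))
  for (e in unique(eng)) {
    o <- unique(orient[eng == e & !is.na(orient)])
    if (length(o) > 1L)
      stop("orientation error: poses of engine '", e,
           "' carry mixed score orientations")
  }
  ifelse(is.na(sc), NA_real_, ifelse(!is.na(orient) & orient == "lower",
                                     -sc, sc))
}

new_pose_cluster <- function(representative, member_poses) {
  cents <- t(vapply(member_poses, pose_centroid, numeric(3)))
  structure(list(representative = representative,
                 members = pose_ids(member_poses),
                 member_poses = member_poses,
                 centroid = colMeans(cents)),
            class = "pose_cluster")
}

#' @export
print.pose_cluster <- function(x, ...) {
  cat(sprintf("pose_cluster: rep '%s', %d member(s), centroid (%.2f, %.2f, %.2f)\n",
              x$representative$pose_id, length(x$members),
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Summarize a list of pose clusters
#'
#' @param clusters list of `pose_cluster` objects.
#' @return data.frame with one row per cluster.
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster = i, representative = cl$representative$pose_id,
               engine = cl$representative$engine,
               score = cl$representative$engine_score,
               n_members = length(cl$members),
               x = cl$centroid[1], y = cl$centroid[2], z = cl$centroid[3],
               stringsAsFactors = FALSE)
  }))
}

#' Group redundant poses and keep the best-scored representatives
#'
#' Greedy deduplication: poses are visited best score first (ties broken by
#' lexicographic pose id); a pose within `threshold` RMSD of an existing
#' representative joins that representative's cluster (the nearest one),
#' otherwise it founds a new cluster. Representatives are the returned unique
#' conformations; by construction no two representatives lie within
#' `threshold` of each other and every pose lies within `threshold` of its
#' representative.
#'
#' @param poses list of [ligand_pose] objects of one ligand species.
#' @param threshold redundancy RMSD threshold in Angstrom (default 2.0).
#' @param use_scores order poses by engine score; when scores are absent the
#'   input order is used as a score proxy with a warning.
#' @param symmetry symmetry-aware RMSD (see [pose_rmsd]).
#' @return list of `pose_cluster` objects, best representative first.
#' @export
deduplicate <- function(poses, threshold = 2.0, use_scores = TRUE,
                        symmetry = TRUE) {
  if (!length(poses)) return(list())
  check_pose_consistency(poses)
  ids <- pose_ids(poses)
  if (use_scores) {
    good <- .pose_goodness(poses)
    if (anyNA(good)) {
      warning("engine scores absent for some poses; using input order ",
              "as score proxy")
      good <- -seq_along(poses)
    }
  } else {
    good <- -seq_along(poses)
  }
  ord <- order(-good, ids)
  autos <- if (symmetry) pose_automorphisms(poses[[1]]) else NULL
  rep_idx <- integer()
  assign_to <- integer(length(poses))
  for (i in ord) {
    if (length(rep_idx)) {
      d <- vapply(rep_idx, function(r)
        pose_rmsd(poses[[r]], poses[[i]], symmetry = symmetry, autos = autos),
        numeric(1))
      j <- which.min(d)
      if (d[j] <= threshold) {
        assign_to[i] <- rep_idx[j]
        next
      }
    }
    rep_idx <- c(rep_idx, i)
    assign_to[i] <- i
  }
  lapply(rep_idx, function(r)
    new_pose_cluster(poses[[r]], poses[assign_to == r]))
}

#' Cluster poses by centroid to identify candidate binding sites
#'
#' Single-linkage clustering of pose centroids with distance cutoff
#' `link_threshold`. Each cluster's centroid is the mean of its member
#' centroids; its representative is the best-scored member (first member when
#' scores are absent).
#'
#' @param poses non-empty list of [ligand_pose] objects (typically unique
#'   conformations from [deduplicate]).
#' @param link_threshold linkage cutoff in Angstrom (default 5).
#' @return list of `pose_cluster` objects, largest cluster first.
#' @export
cluster_by_centroid <- function(poses, link_threshold = 5) {
  if (!length(poses)) stop("`poses` must be non-empty")
  cents <- t(vapply(poses, pose_centroid, numeric(3)))
  groups <- if (length(poses) == 1L || !is.finite(link_threshold))
    rep(1L, length(poses))
  else cutree(hclust(dist(cents), method = "single"), h = link_threshold)
  good <- suppressWarnings(tryCatch(.pose_goodness(poses),
                                    error = function(e) rep(NA_real_,
                                                            length(poses))))
  clusters <- lapply(unique(groups), function(g) {
    sel <- which(groups == g)
    best <- if (all(is.na(good[sel]))) sel[1] else
      sel[order(-good[sel], pose_ids(poses)[sel])[1]]
    new_pose_cluster(poses[[best]], poses[sel])
  })
  clusters[order(-vapply(clusters, function(cl) length(cl$members),
                         integer(1)))]
}

#' Cross-engine consensus poses
#'
#' A pose is a consensus pose when every other engine's set contains a pose
#' within `threshold` RMSD of it. The union of consensus poses over all
#' engines is deduplicated at the same threshold (in a canonical,
#' engine-label-independent order), so the result is invariant to engine
#' relabeling. Engine scores are only ever compared within an engine, never
#' across engines.
#'
#' @param pose_sets named list: engine label -> list of [ligand_pose]
#'   (pre-deduplicated per engine); at least two engines.
#' @param threshold consensus RMSD threshold in Angstrom (default 2.0).
#' @param symmetry symmetry-aware RMSD.
#' @return list of class `consensus_set` with elements `poses` (list of
#'   consensus [ligand_pose]s), `support` (per pose, named map engine ->
#'   matched pose id), and `threshold`. Empty when any engine's set is empty
#'   (with a warning).
#' @export
consensus <- function(pose_sets, threshold = 2.0, symmetry = TRUE) {
  if (is.null(names(pose_sets)) || any(!nzchar(names(pose_sets))))
    stop("`pose_sets` must be a named list (engine labels)")
  if (length(pose_sets) < 2L) stop("consensus needs at least 2 engines")
  empty <- structure(list(poses = list(), support = list(),
                          threshold = threshold), class = "consensus_set")
  if (any(vapply(pose_sets, length, integer(1)) == 0L)) {
    warning("at least one engine has an empty pose list; empty consensus")
    return(empty)
  }
  engines <- names(pose_sets)
  all_poses <- unlist(unname(pose_sets), recursive = FALSE)
  check_pose_consistency(all_poses)
  autos <- if (symmetry) pose_automorphisms(all_poses[[1]]) else NULL

  keep <- list()
  support <- list()
  for (e in engines) {
    for (p in pose_sets[[e]]) {
      sup <- setNames(vector("list", length(engines)), engines)
      sup[[e]] <- p$pose_id
      ok <- TRUE
      for (o in setdiff(engines, e)) {
        d <- vapply(pose_sets[[o]], function(q)
          pose_rmsd(p, q, symmetry = symmetry, autos = autos), numeric(1))
        j <- which.min(d)
        if (d[j] > threshold) { ok <- FALSE; break }
        sup[[o]] <- pose_sets[[o]][[j]]$pose_id
      }
      if (ok) {
        keep[[length(keep) + 1L]] <- p
        support[[length(support) + 1L]] <- sup
      }
    }
  }
  if (!length(keep)) return(empty)

  # canonical, label-free order: pose id then centroid
  cents <- t(vapply(keep, pose_centroid, numeric(3)))
  ord <- order(pose_ids(keep), cents[, 1], cents[, 2], cents[, 3])
  keep <- keep[ord]
  support <- support[ord]
  chosen <- integer()
  for (i in seq_along(keep)) {
    dup <- FALSE
    for (r in chosen) {
      if (pose_rmsd(keep[[r]], keep[[i]], symmetry = symmetry,
                    autos = autos) <= threshold) { dup <- TRUE; break }
    }
    if (!dup) chosen <- c(chosen, i)
  }
  structure(list(poses = keep[chosen], support = support[chosen],
                 threshold = threshold), class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set: %d pose(s) at <= %.2f A across %s\n",
              length(x$poses), x$threshold,
              if (length(x$support))
                paste(names(x$support[[1]]), collapse = ", ")
              else "no engines"))
  invisible(x)
}
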