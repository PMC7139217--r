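# Two-stage density-constrained pose selection: site identification by
# three-way evidence consensus, then pose ranking by average CCC against the
# full and difference maps.

#' Pipeline configuration
#'
#' Thresholds and parameters of [run_protocol]. Defaults follow the docking
#' protocol the pipeline reproduces: 2 Angstrom redundancy/consensus RMSD,
#' a 12 Angstrom site radius for the first (site-focused) docking stage and a
#' tight 6 Angstrom radius for the second stage.
#'
#' @param resolution nominal map resolution in Angstrom (required).
#' @param rmsd_threshold redundancy/consensus RMSD threshold (Angstrom).
#' @param stage1_radius stage-1 site radius (Angstrom).
#' @param stage2_radius stage-2 site radius (Angstrom, <= stage1_radius).
#' @param peak_threshold_sigma difference-peak threshold in sd multiples.
#' @param min_peak_volume minimum difference-peak size in voxels.
#' @param link_threshold centroid-clustering linkage cutoff (Angstrom).
#' @param match_radius evidence-matching radius for site consensus (Angstrom).
#' @param sigma_coeff,cutoff,weighting density-simulation convention, see
#'   [sim_params].
#' @param symmetry symmetry-aware pose RMSD.
#' @param seed optional integer recorded in reports (the pipeline itself is
#'   deterministic; the seed documents upstream generators).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(resolution, rmsd_threshold = 2.0,
                            stage1_radius = 12, stage2_radius = 6,
                            peak_threshold_sigma = 3, min_peak_volume = 5,
                            link_threshold = 5, match_radius = 5,
                            sigma_coeff = 0.356, cutoff = 4,
                            weighting = "atomic-number",
                            symmetry = TRUE, seed = NA_integer_) {
  if (missing(resolution)) stop("configuration error: `resolution` is required")
  if (stage1_radius <= 0 || stage2_radius <= 0)
    stop("configuration error: site radii must be positive")
  if (stage2_radius > stage1_radius)
    stop("configuration error: stage2_radius must be <= stage1_radius")
  structure(list(resolution = resolution, rmsd_threshold = rmsd_threshold,
                 stage1_radius = stage1_radius, stage2_radius = stage2_radius,
                 peak_threshold_sigma = peak_threshold_sigma,
                 min_peak_volume = min_peak_volume,
                 link_threshold = link_threshold, match_radius = match_radius,
                 sigma_coeff = sigma_coeff, cutoff = cutoff,
                 weighting = weighting, symmetry = symmetry, seed = seed),
            class = "pipeline_config")
}

#' Merge blind-docking runs and remove redundant conformations
#'
#' Concatenates the pose lists of repeated blind-docking runs and groups
#' redundant conformations (within `threshold` RMSD), each group represented
#' by its best-scored member.
#'
#' @param run_outputs list of pose lists, one per run.
#' @param threshold redundancy RMSD threshold (Angstrom).
#' @param symmetry symmetry-aware RMSD.
#' @return list of `pose_cluster` objects (see [deduplicate]).
#' @export
merge_blind_runs <- function(run_outputs, threshold = 2.0, symmetry = TRUE) {
  poses <- unlist(run_outputs, recursive = FALSE)
  if (!length(poses)) stop("no poses in any run output")
  # renumber duplicated ids across runs so representatives stay traceable
  ids <- pose_ids(poses)
  if (anyDuplicated(ids)) {
    run_of <- rep(seq_along(run_outputs),
                  vapply(run_outputs, length, integer(1)))
    for (i in seq_along(poses))
      poses[[i]]$pose_id <- sprintf("run%d:%s", run_of[i], ids[i])
  }
  deduplicate(poses, threshold = threshold, symmetry = symmetry)
}

#' Identify binding-site candidates from three evidence sources
#'
#' Links blind-dock pose clusters, difference-density peaks and predicted
#' pockets whose centers fall within `match_radius` of each other (transitive
#' pairwise linking). A candidate supported by all three evidence kinds is a
#' consensus site. Candidates are sorted consensus-first, then by the maximum
#' value of their difference peak.
#'
#' @param clusters list of `pose_cluster` objects (centroid clusters from
#'   blind docking), may be empty.
#' @param peaks data.frame from [find_difference_peaks], may have zero rows.
#' @param pockets numeric matrix (n x 3) of predicted pocket centers, or NULL.
#' @param match_radius linking radius in Angstrom.
#' @return data.frame of class `site_candidates`: `site_id`, `x`, `y`, `z`,
#'   `evidence` (comma-joined kinds), `n_evidence`, `consensus`, `peak_max`,
#'   `radius`, plus linked id columns.
#' @export
identify_sites <- function(clusters, peaks, pockets = NULL, match_radius = 5) {
  items <- list()
  add <- function(kind, id, xyz, weight = NA_real_) {
    items[[length(items) + 1L]] <<- list(kind = kind, id = id,
                                         xyz = as.numeric(xyz),
                                         weight = weight)
  }
  for (i in seq_along(clusters))
    add("dock-cluster", as.character(i), clusters[[i]]$centroid)
  if (!is.null(peaks) && nrow(peaks))
    for (i in seq_len(nrow(peaks)))
      add("diff-peak", as.character(peaks$peak_id[i]),
          c(peaks$x[i], peaks$y[i], peaks$z[i]), peaks$max_value[i])
  if (!is.null(pockets) && NROW(pockets)) {
    pockets <- matrix(as.numeric(pockets), ncol = 3)
    for (i in seq_len(nrow(pockets))) add("pocket", as.character(i),
                                          pockets[i, ])
  }
  if (!length(items))
    stop("at least one evidence source (clusters, peaks, pockets) is required")

  xyz <- t(vapply(items, `[[`, numeric(3), "xyz"))
  groups <- if (length(items) == 1L) 1L else
    cutree(hclust(dist(xyz), method = "single"), h = match_radius)
  rows <- lapply(unique(groups), function(g) {
    sel <- which(groups == g)
    kinds <- vapply(items[sel], `[[`, character(1), "kind")
    ids <- vapply(items[sel], `[[`, character(1), "id")
    ws <- vapply(items[sel], `[[`, numeric(1), "weight")
    center <- colMeans(xyz[sel, , drop = FALSE])
    radius <- max(sqrt(rowSums(sweep(xyz[sel, , drop = FALSE], 2,
                                     center)^2)), 0)
    kindset <- sort(unique(kinds))
    data.frame(
      x = center[1], y = center[2], z = center[3],
      evidence = paste(kindset, collapse = ","),
      n_evidence = length(kindset),
      consensus = setequal(kindset, c("dock-cluster", "diff-peak", "pocket")),
      peak_max = if (any(kinds == "diff-peak"))
        max(ws[kinds == "diff-peak"]) else NA_real_,
      radius = radius,
      cluster_ids = paste(ids[kinds == "dock-cluster"], collapse = ","),
      peak_ids = paste(ids[kinds == "diff-peak"], collapse = ","),
      pocket_ids = paste(ids[kinds == "pocket"], collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$consensus,
               ifelse(is.na(out$peak_max), -Inf, out$peak_max) * -1,
               -out$n_evidence, out$x, out$y, out$z)
  out <- out[ord, , drop = FALSE]
  out <- cbind(site_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("site_candidates", "data.frame")
  out
}

#' Rank ligand poses by average CCC against full and difference maps
#'
#' Each pose is scored with the model-proximity-masked CCC against the full
#' map and against the (positive) difference map, using the same mask; poses
#' are ranked by the average of the two, descending. Ties are broken by the
#' full-map CCC (better determined than a difference map), then lexicographic
#' pose id. A pose extending outside the maps is flagged and ranked last.
#'
#' @param poses list of [ligand_pose] objects.
#' @param full_map full reconstruction [voxel_map].
#' @param diff_map positive difference [voxel_map], congruent with `full_map`.
#' @param params [sim_params].
#' @param mask_radius optional proximity-mask radius override.
#' @return list of class `ranked_poses`: `table` (data.frame with `pose_id`,
#'   `engine`, `ccc_full`, `ccc_diff`, `avg_ccc`, `mask_voxels`, `reliable`,
#'   `flagged`, `rank`) and `poses` (pose list in rank order).
#' @export
select_pose <- function(poses, full_map, diff_map, params,
                        mask_radius = NULL) {
  if (!length(poses)) stop("`poses` must be non-empty")
  stop_if_incongruent(full_map, diff_map, "full and difference maps")
  n <- length(poses)
  cf <- cd <- rep(NA_real_, n)
  mv <- integer(n)
  rel <- flag <- logical(n)
  for (i in seq_len(n)) {
    sim <- tryCatch(simulate_map(poses[[i]], params, grid = full_map),
                    error = function(e) e)
    if (inherits(sim, "error")) {
      flag[i] <- TRUE
      next
    }
    idx <- mask_indices_for_atoms(full_map, .heavy_atoms(poses[[i]]),
                                  .proximity_radius(params, mask_radius))
    s1 <- ccc(full_map, sim, mask = idx)
    s2 <- ccc(diff_map, sim, mask = idx)
    cf[i] <- s1$ccc
    cd[i] <- s2$ccc
    mv[i] <- s1$mask_voxel_count
    rel[i] <- s1$reliable
  }
  avg <- (cf + cd) / 2
  ids <- pose_ids(poses)
  ord <- order(flag, -ifelse(is.na(avg), -Inf, avg),
               -ifelse(is.na(cf), -Inf, cf), ids)
  tab <- data.frame(
    pose_id = ids[ord],
    engine = vapply(poses[ord], function(p)
      ifelse(is.na(p$engine), "", p$engine), character(1)),
    ccc_full = cf[ord], ccc_diff = cd[ord], avg_ccc = avg[ord],
    mask_voxels = mv[ord], reliable = rel[ord], flagged = flag[ord],
    rank = seq_len(n), stringsAsFactors = FALSE)
  structure(list(table = tab, poses = poses[ord]), class = "ranked_poses")
}

#' @export
print.ranked_poses <- function(x, ...) {
  cat("ranked_poses:\n")
  print(utils::head(x$table, 10))
  invisible(x)
}

.restrict_to_site <- function(poses, center, radius) {
  keep <- vapply(poses, function(p)
    sqrt(sum((pose_centroid(p) - center)^2)) <= radius, logical(1))
  poses[keep]
}

.consensus_or_fallback <- function(pose_sets, threshold, symmetry) {
  fallback <- FALSE
  cons <- if (length(pose_sets) >= 2L)
    suppressWarnings(consensus(pose_sets, threshold, symmetry = symmetry))
  else structure(list(poses = list(), support = list(),
                      threshold = threshold), class = "consensus_set")
  cand <- cons$poses
  if (!length(cand)) {
    # no cross-engine agreement: fall back to per-engine representatives
    fallback <- TRUE
    reps <- lapply(pose_sets, function(ps)
      lapply(deduplicate(ps, threshold, symmetry = symmetry),
             `[[`, "representative"))
    cand <- unlist(unname(reps), recursive = FALSE)
  }
  list(poses = cand, consensus_size = length(cons$poses),
       support = cons$support, fallback = fallback)
}

#' Run the two-stage density-constrained docking analysis
#'
#' Executes the full protocol: difference mapping, difference-peak detection,
#' blind-run merging and centroid clustering, three-way site identification,
#' cross-engine consensus filtering, and pose ranking by average CCC against
#' the full and difference maps. When stage-2 (focused) pose sets are
#' supplied, consensus and selection are repeated restricted to poses within
#' the stage-2 radius of the identified site, and that ranking is final.
#'
#' @param config a [pipeline_config].
#' @param map_full reconstruction containing the ligand ([voxel_map]).
#' @param map_ref reference reconstruction without the ligand, congruent with
#'   `map_full` (it is resampled onto `map_full`'s grid if not).
#' @param stage1_sets named list engine -> pose list (stage-1 docking).
#' @param blind_runs optional list of pose lists from repeated blind docking
#'   runs used for site identification; defaults to the stage-1 sets.
#' @param stage2_sets optional named list engine -> pose list (stage-2
#'   focused docking).
#' @param pockets optional n x 3 matrix of predicted pocket centers.
#' @return a list of class `run_report`; see Details. The report echoes every
#'   threshold used, per-stage counts, the site table, the ranked pose tables
#'   and the final selected pose.
#' @export
run_protocol <- function(config, map_full, map_ref, stage1_sets,
                         blind_runs = NULL, stage2_sets = NULL,
                         pockets = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("configuration error: `config` must be pipeline_config()")
  if (missing(map_full) || missing(map_ref) || missing(stage1_sets))
    stop("configuration error: map_full, map_ref and stage1_sets are required")
  if (!is_voxel_map(map_full) || !is_voxel_map(map_ref))
    stop("configuration error: maps must be voxel_map objects")
  if (!length(stage1_sets))
    stop("configuration error: stage1_sets must contain at least one engine")
  if (is.null(names(stage1_sets)))
    stop("configuration error: stage1_sets must be named by engine")
  if (!map_congruent(map_full, map_ref))
    map_ref <- resample_map(map_ref, map_full)

  params <- sim_params(config$resolution, min(map_full$voxel_size),
                       sigma_coeff = config$sigma_coeff,
                       cutoff = config$cutoff, weighting = config$weighting)
  notes <- character()

  dres <- difference_map(map_full, map_ref)
  peaks <- find_difference_peaks(dres$positive,
                                 config$peak_threshold_sigma,
                                 config$min_peak_volume)

  runs <- blind_runs %||% unname(stage1_sets)
  merged <- merge_blind_runs(runs, config$rmsd_threshold,
                             symmetry = config$symmetry)
  reps <- lapply(merged, `[[`, "representative")
  cl <- cluster_by_centroid(reps, config$link_threshold)
  sites <- identify_sites(cl, peaks, pockets, config$match_radius)

  site_center <- if (nrow(sites))
    c(sites$x[1], sites$y[1], sites$z[1]) else NULL
  if (is.null(site_center)) notes <- c(notes, "no site candidate found")

  st1 <- .consensus_or_fallback(stage1_sets, config$rmsd_threshold,
                                config$symmetry)
  if (st1$fallback)
    notes <- c(notes, "stage-1 consensus empty; ranked per-engine representatives")
  cand1 <- st1$poses
  if (!is.null(site_center)) {
    restricted <- .restrict_to_site(cand1, site_center, config$stage1_radius)
    if (length(restricted)) cand1 <- restricted
    else notes <- c(notes, "stage-1 site restriction left no poses; relaxed")
  }
  ranked1 <- select_pose(cand1, map_full, dres$positive, params)

  stage2_used <- !is.null(stage2_sets) && length(stage2_sets) > 0
  ranked2 <- NULL
  st2 <- NULL
  if (stage2_used) {
    anchor <- site_center %||% pose_centroid(ranked1$poses[[1]])
    st2 <- .consensus_or_fallback(stage2_sets, config$rmsd_threshold,
                                  config$symmetry)
    if (st2$fallback)
      notes <- c(notes, "stage-2 consensus empty; ranked per-engine representatives")
    cand2 <- .restrict_to_site(st2$poses, anchor, config$stage2_radius)
    if (!length(cand2)) {
      notes <- c(notes, "stage-2 site restriction left no poses; relaxed")
      cand2 <- st2$poses
    }
    ranked2 <- select_pose(cand2, map_full, dres$positive, params)
  }

  final <- if (stage2_used) ranked2 else ranked1
  report <- structure(list(
    version = .cryodock_version(),
    config = unclass(config),
    stage_counts = list(
      blind_runs = length(runs),
      blind_poses_in = sum(vapply(runs, length, integer(1))),
      unique_conformations = length(merged),
      centroid_clusters = length(cl),
      difference_peaks = nrow(peaks),
      site_candidates = nrow(sites),
      consensus_sites = sum(sites$consensus),
      stage1_poses_in = sum(vapply(stage1_sets, length, integer(1))),
      stage1_consensus = st1$consensus_size,
      stage1_ranked = nrow(ranked1$table),
      stage2_poses_in = if (stage2_used)
        sum(vapply(stage2_sets, length, integer(1))) else 0L,
      stage2_consensus = if (stage2_used) st2$consensus_size else NA_integer_,
      stage2_ranked = if (stage2_used) nrow(ranked2$table) else NA_integer_),
    stage1_fallback = st1$fallback,
    stage2_fallback = if (stage2_used) st2$fallback else NA,
    stage = if (stage2_used) "stage-2" else "stage-1 only",
    sites = sites,
    peaks = peaks,
    ranked_stage1 = ranked1$table,
    ranked_stage2 = if (stage2_used) ranked2$table else NULL,
    final_table = final$table,
    final_pose = final$poses[[1]],
    notes = notes), class = "run_report")
  # by construction: the selected pose maximizes avg_ccc among eligible poses
  stopifnot(which.max(ifelse(final$table$flagged, -Inf,
                             final$table$avg_ccc)) == 1L)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("cryodock run_report (", x$stage, ")\n", sep = "")
  cat("  difference peaks:", x$stage_counts$difference_peaks,
      "| site candidates:", x$stage_counts$site_candidates, "\n")
  cat("  unique blind conformations:", x$stage_counts$unique_conformations,
      "| stage-1 consensus:", x$stage_counts$stage1_consensus, "\n")
  cat(sprintf("  final pose: %s (%s), avg CCC %.3f (full %.3f, diff %.3f)\n",
              x$final_table$pose_id[1], x$final_table$engine[1],
              x$final_table$avg_ccc[1], x$final_table$ccc_full[1],
              x$final_table$ccc_diff[1]))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
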