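# Two-stage pipeline: blind-run merging, site identification, density-based
# pose selection, and the orchestrated protocol.

test_that("merging blind runs collapses duplicates and keeps disjoint sites", {
  one <- lapply(1:100, function(r)
    list(translated_pose("m1", c(0.02 * (r %% 3), 0, 0), engine = "vina",
                         score = -7 - 0.01 * r, orient = "lower")))
  merged <- merge_blind_runs(one, threshold = 2)
  expect_length(merged, 1L)
  expect_length(merged[[1]]$members, 100L)

  two <- list(
    lapply(1:3, function(i) translated_pose(sprintf("a%d", i), c(i * 0.1, 0, 0),
                                            "vina", -5 - i, "lower")),
    lapply(1:2, function(i) translated_pose(sprintf("b%d", i),
                                            c(30 + i * 0.1, 0, 0),
                                            "vina", -4 - i, "lower")))
  merged2 <- merge_blind_runs(two, threshold = 2)
  expect_length(merged2, 2L)

  # planted duplicates across a 20-run ensemble: unique count is recovered
  set.seed(111)
  uniq <- lapply(1:7, function(i)
    translated_pose(sprintf("u%d", i), c(6 * i, 0, 0), "vina",
                    -runif(1, 4, 9), "lower"))
  runs <- lapply(1:20, function(r) {
    picks <- sample(7, sample(2:5, 1), replace = TRUE)
    lapply(seq_along(picks), function(j) {
      p <- uniq[[picks[j]]]
      p$pose_id <- sprintf("r%d_%d", r, j)
      p$atoms$x <- p$atoms$x + runif(1, -0.3, 0.3)
      p$engine_score <- p$engine_score + rnorm(1, 0, 0.1)
      p
    })
  })
  merged3 <- merge_blind_runs(runs, threshold = 2)
  expect_length(merged3, 7L)
})

test_that("site identification links evidence and ranks consensus sites first", {
  cl <- cluster_by_centroid(list(translated_pose("p1", c(0, 0, 0)),
                                 translated_pose("p2", c(1, 0, 0)),
                                 translated_pose("q1", c(40, 0, 0))),
                            link_threshold = 5)
  peaks <- data.frame(peak_id = 1L, x = 1.5, y = 0.5, z = 0.2,
                      volume = 50L, max_value = 12, threshold_used = 3)
  pockets <- matrix(c(0.5, 1.0, 0.0), 1)
  sites <- identify_sites(cl, peaks, pockets, match_radius = 5)
  expect_true(sites$consensus[1])
  expect_identical(sites$n_evidence[1], 3L)
  # the isolated cluster is a single-evidence candidate ranked below
  expect_false(sites$consensus[nrow(sites)])
  expect_identical(sites$evidence[nrow(sites)], "dock-cluster")
  expect_error(identify_sites(list(), peaks[0, ], NULL), "evidence")
})

test_that("pose selection ranks the planted pose first among decoys", {
  sc <- scene_cache(resolution = 4, voxel = 1, noise_sigma = 0.1, seed = 12)
  eng <- make_engine_outputs(sc, n_engines = 2, n_poses = 9,
                             decoy_range = c(6, 18), seed = 13)
  d <- difference_map(sc$map_with, sc$map_without)
  poses <- eng$pose_sets[[1]]
  ranked <- select_pose(poses, sc$map_with, d$positive, sc$params)
  native_id <- eng$native_ids[[1]]
  expect_identical(ranked$table$pose_id[1], native_id)
  expect_true(all(diff(ranked$table$avg_ccc) <= 1e-12))
  expect_identical(ranked$table$rank, seq_along(poses))
})

test_that("identical poses tie and out-of-map poses are flagged last", {
  sc <- scene_cache(resolution = 4, voxel = 1, noise_sigma = 0.1, seed = 12)
  d <- difference_map(sc$map_with, sc$map_without)
  same <- lapply(c("b", "a", "c"), function(id) {
    p <- sc$true_pose
    p$pose_id <- id
    p
  })
  r <- select_pose(same, sc$map_with, d$positive, sc$params)
  expect_lt(diff(range(r$table$avg_ccc)), 1e-12)
  expect_identical(r$table$pose_id, c("a", "b", "c"))  # lexicographic tie rule

  runaway <- sc$true_pose
  runaway$pose_id <- "outside"
  runaway$atoms$x <- runaway$atoms$x + 500
  r2 <- select_pose(c(same, list(runaway)), sc$map_with, d$positive, sc$params)
  expect_identical(r2$table$pose_id[4], "outside")
  expect_true(r2$table$flagged[4])
})

test_that("the full protocol recovers the planted pose and is deterministic", {
  sc <- scene_cache(resolution = 4, voxel = 1, noise_sigma = 0.1, seed = 12)
  eng <- make_engine_outputs(sc, n_engines = 3, n_poses = 12,
                             decoy_range = c(5, 20), seed = 14)
  cfg <- pipeline_config(resolution = 4, seed = 12)
  rep1 <- run_protocol(cfg, sc$map_with, sc$map_without, eng$pose_sets)
  expect_lte(pose_rmsd(sc$true_pose, rep1$final_pose), 2)
  expect_identical(rep1$stage, "stage-1 only")
  expect_gte(rep1$stage_counts$stage1_consensus, 1L)

  rep2 <- run_protocol(cfg, sc$map_with, sc$map_without, eng$pose_sets)
  expect_identical(rep1$final_table, rep2$final_table)
  expect_identical(rep1$sites, rep2$sites)

  # selected pose maximizes avg_ccc among ranked poses (by construction)
  expect_identical(which.max(rep1$final_table$avg_ccc), 1L)
})

test_that("stage-2 focused sets refine the ranking and are reported as final", {
  sc <- scene_cache(resolution = 4, voxel = 1, noise_sigma = 0.1, seed = 12)
  eng1 <- make_engine_outputs(sc, n_engines = 3, n_poses = 10,
                              decoy_range = c(5, 20), seed = 15)
  eng2 <- make_engine_outputs(sc, n_engines = 3, n_poses = 8,
                              decoy_range = c(5, 12), seed = 16)
  cfg <- pipeline_config(resolution = 4)
  rep <- run_protocol(cfg, sc$map_with, sc$map_without, eng1$pose_sets,
                      stage2_sets = eng2$pose_sets)
  expect_identical(rep$stage, "stage-2")
  expect_false(is.null(rep$ranked_stage2))
  expect_lte(pose_rmsd(sc$true_pose, rep$final_pose), 2)
  # stage-2 candidates were restricted to the tight site radius
  site <- c(rep$sites$x[1], rep$sites$y[1], rep$sites$z[1])
  expect_lte(sqrt(sum((pose_centroid(rep$final_pose) - site)^2)),
             cfg$stage2_radius)
})

test_that("empty stage-1 consensus falls back to per-engine representatives", {
  sc <- scene_cache(resolution = 4, voxel = 1, noise_sigma = 0.1, seed = 12)
  # engines that never agree: poses far apart between engines
  sets <- list(
    e1 = list(translated_pose("x1", c(-3, 0, 12), "e1", 10, "higher")),
    e2 = list(translated_pose("y1", c(3, 0, 30), "e2", 20, "higher")))
  cfg <- pipeline_config(resolution = 4)
  rep <- run_protocol(cfg, sc$map_with, sc$map_without, sets)
  expect_true(rep$stage1_fallback)
  expect_true(any(grepl("consensus empty", rep$notes)))
  expect_gte(nrow(rep$final_table), 1L)
})

test_that("configuration errors abort before any computation", {
  expect_error(pipeline_config(), "resolution")
  expect_error(pipeline_config(resolution = 4, stage1_radius = 6,
                               stage2_radius = 12), "stage2_radius")
  cfg <- pipeline_config(resolution = 4)
  expect_error(run_protocol(cfg), "configuration error")
  sc <- scene_cache(resolution = 4, voxel = 1, noise_sigma = 0.1, seed = 12)
  expect_error(run_protocol(cfg, sc$map_with, sc$map_without,
                            list(list(sc$true_pose))),
               "named")
})
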