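# Pose RMSD (with and without symmetry), dedup, centroid clustering,
# cross-engine consensus.

test_that("pose RMSD is zero on identity and exact under rigid translation", {
  p <- translated_pose("a", c(0, 0, 0))
  expect_identical(pose_rmsd(p, p), 0)
  q <- translated_pose("b", c(2, 0, 0))
  expect_equal(pose_rmsd(p, q), 2.0, tolerance = 1e-12)
  bad <- p
  bad$atoms$element[1] <- "S"
  expect_error(pose_rmsd(p, bad), "correspondence")
})

test_that("symmetric ring RMSD matches exhaustive automorphism enumeration", {
  ang <- (0:5) * pi / 3
  ring <- data.frame(atom = paste0("C", 1:6), element = "C",
                     x = 1.4 * cos(ang), y = 1.4 * sin(ang), z = 0,
                     stringsAsFactors = FALSE)
  p <- ligand_pose(ring, "p")
  flipped <- ring
  flipped$y <- -flipped$y           # 180-degree flip about the x axis
  q <- ligand_pose(flipped, "q")
  expect_gt(pose_rmsd(p, q, symmetry = FALSE), 1)
  expect_lt(pose_rmsd(p, q, symmetry = TRUE), 1e-10)
  expect_equal(pose_rmsd(p, q, symmetry = TRUE), brute_sym_rmsd(p, q),
               tolerance = 1e-10)

  # an off-axis rotation: minimum over mappings, verified exhaustively
  th <- 25 * pi / 180
  rot <- ring
  rot$x <- cos(th) * ring$x - sin(th) * ring$y + 0.3
  rot$y <- sin(th) * ring$x + cos(th) * ring$y
  r <- ligand_pose(rot, "r")
  expect_equal(pose_rmsd(p, r, symmetry = TRUE), brute_sym_rmsd(p, r),
               tolerance = 1e-10)
})

test_that("pose RMSD is a pseudometric on sampled triples", {
  set.seed(71)
  poses <- random_pose_set(8, "x")
  for (t in 1:20) {
    ijk <- sample(8, 3)
    a <- poses[[ijk[1]]]; b <- poses[[ijk[2]]]; c_ <- poses[[ijk[3]]]
    dab <- pose_rmsd(a, b, symmetry = FALSE)
    dba <- pose_rmsd(b, a, symmetry = FALSE)
    expect_equal(dab, dba, tolerance = 1e-12)
    dac <- pose_rmsd(a, c_, symmetry = FALSE)
    dcb <- pose_rmsd(c_, b, symmetry = FALSE)
    expect_lte(dab, dac + dcb + 1e-9)
  }
})

test_that("deduplication groups copies, keeps distant poses, and satisfies its guarantees", {
  copies <- lapply(1:10, function(i)
    translated_pose(sprintf("c%02d", i), c(0.01 * i, 0, 0), engine = "vina",
                    score = -5 - i * 0.1, orient = "lower"))
  cl <- deduplicate(copies, threshold = 2)
  expect_length(cl, 1L)
  expect_length(cl[[1]]$members, 10L)
  expect_equal(cl[[1]]$representative$pose_id, "c10")  # best (lowest) score

  spread <- lapply(1:6, function(i)
    translated_pose(sprintf("s%d", i), c(5 * i, 0, 0), engine = "vina",
                    score = -i, orient = "lower"))
  cl2 <- deduplicate(spread, threshold = 2)
  expect_length(cl2, 6L)

  set.seed(81)
  rnd <- random_pose_set(30, "vina", box = 8)
  cl3 <- deduplicate(rnd, threshold = 3)
  expect_true(check_dedup_properties(cl3, rnd, 3))
})

test_that("dedup output is independent of input order under strict score ordering", {
  set.seed(82)
  poses <- random_pose_set(20, "gold", box = 10)
  # strictly distinct scores
  for (i in seq_along(poses)) poses[[i]]$engine_score <- i * 1.37
  cl_a <- deduplicate(poses, threshold = 3)
  set.seed(83)
  cl_b <- deduplicate(sample(poses), threshold = 3)
  ids_a <- sort(vapply(cl_a, function(x) x$representative$pose_id, character(1)))
  ids_b <- sort(vapply(cl_b, function(x) x$representative$pose_id, character(1)))
  expect_identical(ids_a, ids_b)
})

test_that("mixed score orientations within one engine are rejected", {
  p1 <- translated_pose("a", c(0, 0, 0), engine = "e", score = 1,
                        orient = "lower")
  p2 <- translated_pose("b", c(9, 0, 0), engine = "e", score = 2,
                        orient = "higher")
  expect_error(deduplicate(list(p1, p2)), "orientation")
})

test_that("centroid clustering separates sites and collapses under infinite linkage", {
  g1 <- lapply(1:4, function(i) translated_pose(sprintf("a%d", i),
                                                c(runif(1), runif(1), 0)))
  g2 <- lapply(1:3, function(i) translated_pose(sprintf("b%d", i),
                                                c(20 + runif(1), 0, 0)))
  cl <- cluster_by_centroid(c(g1, g2), link_threshold = 5)
  expect_length(cl, 2L)
  expect_identical(sort(vapply(cl, function(x) length(x$members), integer(1))),
                   c(3L, 4L))
  expect_length(cluster_by_centroid(c(g1, g2), link_threshold = Inf), 1L)

  # three planted sites
  set.seed(91)
  sites <- list(c(0, 0, 0), c(25, 0, 0), c(0, 30, 10))
  poses <- unlist(lapply(seq_along(sites), function(s)
    lapply(1:5, function(i)
      translated_pose(sprintf("s%d_%d", s, i),
                      sites[[s]] + runif(3, -1, 1)))), recursive = FALSE)
  cl3 <- cluster_by_centroid(poses, link_threshold = 5)
  expect_length(cl3, 3L)
  cents <- t(vapply(cl3, `[[`, numeric(3), "centroid"))
  base_centroid <- pose_centroid(translated_pose("o", c(0, 0, 0)))
  for (s in sites) {
    d <- sqrt(rowSums(sweep(cents, 2, s + base_centroid)^2))
    expect_lt(min(d), 2)
  }
})

test_that("consensus keeps only poses supported by every engine", {
  shared <- c(0, 0, 0)
  sets <- list(
    vina = list(translated_pose("v1", shared, "vina", -8, "lower"),
                translated_pose("v2", c(15, 0, 0), "vina", -7, "lower")),
    chemscore = list(translated_pose("c1", shared + 0.2, "chemscore", 30,
                                     "higher"),
                     translated_pose("c2", c(0, 18, 0), "chemscore", 25,
                                     "higher")),
    goldscore = list(translated_pose("g1", shared - 0.1, "goldscore", 55,
                                     "higher")))
  cs <- consensus(sets, threshold = 2)
  expect_length(cs$poses, 1L)
  expect_identical(sort(names(cs$support[[1]])),
                   sort(c("vina", "chemscore", "goldscore")))
  expect_true(all(!vapply(cs$support[[1]], is.null, logical(1))))

  # v2 (in one engine only) and c2 (two of three) are excluded
  ids <- vapply(cs$poses, `[[`, character(1), "pose_id")
  expect_false(any(c("v2", "c2") %in% ids))

  expect_warning(out <- consensus(list(a = sets$vina, b = list()), 2),
                 "empty")
  expect_length(out$poses, 0L)
  expect_error(consensus(list(a = sets$vina), 2), "2 engines")
})

test_that("consensus matches exhaustive enumeration and ignores engine labels", {
  set.seed(101)
  for (rep in 1:5) {
    sets <- list(e1 = random_pose_set(6, "e1", box = 6),
                 e2 = random_pose_set(7, "e2", box = 6),
                 e3 = random_pose_set(5, "e3", box = 6))
    thr <- 4
    cs <- consensus(sets, threshold = thr)
    brute <- brute_consensus_ids(sets, thr)
    # every brute consensus pose is within thr of a returned representative,
    # and every returned pose is itself a brute consensus pose
    all_poses <- unlist(unname(sets), recursive = FALSE)
    names(all_poses) <- unlist(lapply(names(sets), function(e)
      paste(e, vapply(sets[[e]], `[[`, character(1), "pose_id"), sep = "/")))
    ret_keys <- vapply(cs$poses, function(p) {
      eng <- p$engine
      paste(eng, p$pose_id, sep = "/")
    }, character(1))
    expect_true(all(ret_keys %in% brute))
    for (key in brute) {
      d <- vapply(cs$poses, function(p)
        pose_rmsd(p, all_poses[[key]], symmetry = FALSE), numeric(1))
      expect_lte(min(d), thr)
    }
    # representatives pairwise separated
    if (length(cs$poses) > 1) {
      for (i in 1:(length(cs$poses) - 1)) for (j in (i + 1):length(cs$poses))
        expect_gt(pose_rmsd(cs$poses[[i]], cs$poses[[j]]), thr)
    }
    # permuting engine labels leaves the consensus geometry unchanged
    perm_sets <- sets[c("e3", "e1", "e2")]
    cs2 <- consensus(perm_sets, threshold = thr)
    cents1 <- sort(vapply(cs$poses, function(p) sum(pose_centroid(p)),
                          numeric(1)))
    cents2 <- sort(vapply(cs2$poses, function(p) sum(pose_centroid(p)),
                          numeric(1)))
    expect_equal(cents1, cents2, tolerance = 1e-9)
  }
})
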