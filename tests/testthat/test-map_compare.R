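# Amplitude scaling, difference maps, CCC, SMOC and peak detection.

rand_map <- function(n, seed, mean = 0, sd = 1, voxel = 1) {
  set.seed(seed)
  voxel_map(array(rnorm(prod(n), mean, sd), n), voxel)
}

test_that("scaling b = 2a recovers a; whole-spectrum shell equals std matching", {
  a <- rand_map(c(12, 12, 12), 21)
  b <- voxel_map(2 * a$data, a$voxel_size)
  s <- scale_amplitudes(b, a)
  expect_lt(max(abs(s$data - a$data)), 1e-8)

  a2 <- rand_map(c(12, 12, 12), 22, mean = 5, sd = 2)
  b2 <- rand_map(c(12, 12, 12), 23, mean = 1, sd = 7)
  s2 <- scale_amplitudes(b2, a2, shell_width = Inf)
  ref <- mean(a2$data) + (b2$data - mean(b2$data)) * sd(a2$data) / sd(b2$data)
  expect_lt(max(abs(s2$data - ref)), 1e-10)
})

test_that("scaled white noise acquires the reference map's radial power profile", {
  # structured reference: a blob of atoms gives a decaying radial spectrum
  params <- sim_params(resolution = 4, voxel_size = 1)
  grid <- voxel_map(array(0, c(24, 24, 24)), 1, origin = c(-12, -12, -12))
  set.seed(31)
  model <- atomic_model(data.frame(
    chain = "A", resno = 1:20, resname = "LIG",
    atom = paste0("C", 1:20), element = "C",
    x = runif(20, -5, 5), y = runif(20, -5, 5), z = runif(20, -5, 5),
    occupancy = 1, b = 0, stringsAsFactors = FALSE))
  a <- simulate_map(model, params, grid = grid)
  set.seed(32)
  b <- voxel_map(array(rnorm(24^3), c(24, 24, 24)), 1,
                 origin = c(-12, -12, -12))
  s <- scale_amplitudes(b, a)

  # oracle: compute per-shell power directly
  shell_power <- function(map) {
    n <- dim(map$data)
    f <- function(len) {
      k <- 0:(len - 1)
      ifelse(k <= len / 2, k, k - len)
    }
    r <- sqrt(outer(outer(f(n[1])^2, f(n[2])^2, "+"), f(n[3])^2, "+"))
    bin <- as.integer(floor(r)) + 2L
    bin[1] <- 1L
    rowsum(as.vector(Mod(fft(map$data))^2), bin)
  }
  pa <- shell_power(a)
  ps <- shell_power(s)
  expect_equal(rownames(pa), rownames(ps))
  keep <- pa > max(pa) * 1e-8
  expect_lt(max(abs(ps[keep] / pa[keep] - 1)), 0.01)
})

test_that("difference of a map with itself is zero; equal-statistics case is antisymmetric", {
  a <- rand_map(c(14, 12, 16), 41)
  d <- difference_map(a, a)
  expect_lt(max(abs(d$difference$data)), 1e-10)
  expect_lt(max(d$positive$data), 1e-10)
  expect_true(all(d$positive$data >= 0))

  # b = value-shuffled a has identical mean/sd: whole-spectrum scaling is
  # identity, so swapping arguments negates the difference
  set.seed(42)
  b <- voxel_map(array(sample(a$data), dim(a$data)), a$voxel_size)
  d_ab <- difference_map(a, b, shell_width = Inf)
  d_ba <- difference_map(b, a, shell_width = Inf)
  expect_lt(max(abs(d_ab$difference$data + d_ba$difference$data)), 1e-8)

  bad <- rand_map(c(10, 10, 10), 43)
  expect_error(difference_map(a, bad), "congruence")
})

test_that("difference map of a planted-ligand scene peaks at the ligand", {
  sc <- scene_cache(resolution = 4, voxel = 1, noise_sigma = 0, seed = 7)
  d <- difference_map(sc$clean_with, sc$clean_without)
  pk <- find_difference_peaks(d$positive, threshold_sigma = 3, min_volume = 5)
  expect_gte(nrow(pk), 1L)
  cen <- pose_centroid(sc$true_pose)
  err <- sqrt(sum((c(pk$x[1], pk$y[1], pk$z[1]) - cen)^2))
  expect_lte(err, max(sc$map_with$voxel_size))
})

test_that("ccc equals a brute-force Pearson loop and honors masks", {
  set.seed(51)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    a <- array(rnorm(n^3), c(n, n, n))
    b <- array(0.4 * a + rnorm(n^3), c(n, n, n))
    idx <- sort(sample(n^3, sample(50:(n^3), 1)))
    got <- ccc(voxel_map(a, 1), voxel_map(b, 1), mask = idx)
    expect_lt(abs(got$ccc - brute_pearson(a, b, idx)), 1e-10)
    expect_identical(got$mask_voxel_count, length(idx))
  }
})

test_that("self-simulated probes score CCC 1, negated maps -1, tiny masks flagged", {
  sc <- scene_cache(resolution = 4, voxel = 1, noise_sigma = 0, seed = 7)
  r <- ccc(sc$clean_without, sc$receptor, sc$params, mask_mode = "whole-map")
  expect_lt(abs(r$ccc - 1), 1e-10)
  neg <- voxel_map(-sc$clean_without$data, sc$clean_without$voxel_size,
                   sc$clean_without$origin)
  r2 <- ccc(neg, sc$receptor, sc$params, mask_mode = "whole-map")
  expect_lt(abs(r2$ccc + 1), 1e-10)

  small <- ccc(sc$clean_without, sc$clean_with, mask = 1:10)
  expect_false(small$reliable)
  expect_true(is.finite(small$ccc) || is.na(small$ccc))
})

test_that("SMOC is invariant to residue renumbering offsets", {
  sc <- scene_cache(resolution = 4, voxel = 1, noise_sigma = 0, seed = 7)
  p1 <- smoc(sc$receptor, sc$clean_without, sc$params)
  shifted <- sc$receptor
  shifted$atoms$resno <- shifted$atoms$resno + 100L
  p2 <- smoc(shifted, sc$clean_without, sc$params)
  expect_equal(p1$smoc, p2$smoc, tolerance = 1e-12)
  expect_error(smoc(sc$receptor, sc$clean_without, sc$params, window = 4),
               "odd")
})

test_that("wider SMOC windows smooth the profile on a uniform-quality map", {
  sc <- scene_cache(resolution = 4, voxel = 1, noise_sigma = 0.1, seed = 7)
  p1 <- smoc(sc$receptor, sc$map_without, sc$params, window = 1)
  p9 <- smoc(sc$receptor, sc$map_without, sc$params, window = 9)
  expect_lt(var(p9$smoc, na.rm = TRUE), var(p1$smoc, na.rm = TRUE))
})

test_that("peak detection finds planted blobs and respects thresholds", {
  z <- voxel_map(array(0, c(20, 20, 20)), 1)
  expect_identical(nrow(find_difference_peaks(z)), 0L)

  # two disjoint Gaussian blobs
  g <- array(0, c(30, 30, 30))
  centers <- list(c(8, 8, 8), c(22, 21, 23))
  for (cn in centers) {
    for (i in -3:3) for (j in -3:3) for (k in -3:3) {
      g[cn[1] + i, cn[2] + j, cn[3] + k] <-
        g[cn[1] + i, cn[2] + j, cn[3] + k] +
        exp(-(i^2 + j^2 + k^2) / 2)
    }
  }
  m <- voxel_map(g, 1, origin = c(0, 0, 0))
  pk <- find_difference_peaks(m, threshold_sigma = 3, min_volume = 3)
  expect_identical(nrow(pk), 2L)
  found <- pk[order(pk$x), c("x", "y", "z")]
  want <- do.call(rbind, centers) - 1      # origin 0, 1-based voxel indices
  expect_lt(max(abs(as.matrix(found) - want[order(want[, 1]), ])), 1)

  expect_identical(nrow(find_difference_peaks(m, threshold_sigma = 1e6)), 0L)

  counts <- vapply(c(2, 3, 4, 5), function(t)
    nrow(find_difference_peaks(m, t, min_volume = 1)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("resampling onto the same grid is the identity and congruence is enforced", {
  a <- rand_map(c(12, 14, 10), 61)
  r <- resample_map(a, a)
  expect_equal(r$data, a$data, tolerance = 1e-12)
  fine <- voxel_map(array(0, c(23, 27, 19)), 0.5, a$origin)
  up <- resample_map(a, fine)
  expect_identical(dim(up$data), dim(fine$data))
  # voxel centers coincident with the coarse grid keep their values
  expect_equal(up$data[1, 1, 1], a$data[1, 1, 1], tolerance = 1e-12)
  expect_equal(up$data[3, 5, 7], a$data[2, 3, 4], tolerance = 1e-12)
})
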