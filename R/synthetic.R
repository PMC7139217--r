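# Fully seeded synthetic scenes: an abstract two-helix receptor with a rigid
# biaryl-like ligand planted in the inter-helix cleft, paired noisy maps, and
# emulated docking-engine outputs. The receptor is deliberately an abstract
# atom arrangement rather than a homology model, so every downstream stage is
# testable without external structures.

# idealized helix-like chain: 100 deg / 1.5 A per residue, 4 pseudo-backbone
# atoms per residue
.build_helix <- function(chain, n_res, cx, phase = 0, rise = 1.5,
                         radius = 2.3) {
  rows <- lapply(seq_len(n_res), function(i) {
    th <- phase + (i - 1) * 100 * pi / 180
    z <- (i - 1) * rise
    pt <- function(ang, rad, dz)
      c(cx + rad * cos(ang), rad * sin(ang), z + dz)
    n_ <- pt(th - 40 * pi / 180, radius, -0.5)
    ca <- pt(th, radius, 0)
    c_ <- pt(th + 40 * pi / 180, radius, 0.5)
    o_ <- pt(th + 40 * pi / 180, radius + 1.2, 0.5)
    data.frame(chain = chain, resno = i, resname = "ALA",
               atom = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               x = c(n_[1], ca[1], c_[1], o_[1]),
               y = c(n_[2], ca[2], c_[2], o_[2]),
               z = c(n_[3], ca[3], c_[3], o_[3]),
               occupancy = 1, b = 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# rigid biaryl-like fragment (19 heavy atoms), point-symmetric about its
# centroid so the centroid coincides with the density maximum: two
# six-membered rings (one ring nitrogen each) bridged by a CF2 carbon, with a
# fluorine cap and a methyl carbon per ring
.build_ligand_atoms <- function() {
  ring <- function(cz, n_at_angle) {
    ang <- (0:5) * 60 * pi / 180
    el <- rep("C", 6)
    el[n_at_angle] <- "N"
    data.frame(element = el, x = 0, y = 1.5 * sin(ang),
               z = cz + 1.5 * cos(ang), stringsAsFactors = FALSE)
  }
  r1 <- ring(-2.9, n_at_angle = 4)          # N at the far (-z) vertex
  r2 <- r1
  r2$z <- -r2$z                             # mirrored partner ring
  extra <- data.frame(
    element = c("C", "F", "F", "F", "F", "C", "C"),
    x = 0,
    y = c(0, 1.25, -1.25, 0, 0, 2.9, -2.9),
    z = c(0, 0, 0, -5.9, 5.9, -2.9, 2.9),
    stringsAsFactors = FALSE)
  at <- rbind(r1, r2, extra)
  at <- data.frame(atom = paste0(at$element, seq_len(nrow(at))),
                   element = at$element, x = at$x, y = at$y, z = at$z,
                   stringsAsFactors = FALSE)
  at
}

.translate_atoms <- function(at, v) {
  at$x <- at$x + v[1]; at$y <- at$y + v[2]; at$z <- at$z + v[3]
  at
}

# uniform random rotation matrix (quaternion method)
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  matrix(c(a[1]^2 * C + c_, a[1] * a[2] * C - a[3] * s_, a[1] * a[3] * C + a[2] * s_,
           a[1] * a[2] * C + a[3] * s_, a[2]^2 * C + c_, a[2] * a[3] * C - a[1] * s_,
           a[1] * a[3] * C - a[2] * s_, a[2] * a[3] * C + a[1] * s_, a[3]^2 * C + c_),
         3, 3, byrow = TRUE)
}

.transform_pose <- function(pose, R, new_centroid) {
  xyz <- as.matrix(pose$atoms[, c("x", "y", "z")])
  cen <- colMeans(xyz)
  xyz <- sweep(xyz, 2, cen) %*% t(R)
  xyz <- sweep(xyz, 2, new_centroid, "+")
  p <- pose
  p$atoms$x <- xyz[, 1]; p$atoms$y <- xyz[, 2]; p$atoms$z <- xyz[, 3]
  p
}

#' Generate a synthetic ligand-binding scene
#'
#' Builds an abstract receptor (two idealized helix-like chains forming a
#' cleft), plants a rigid biaryl-like ligand (19 heavy atoms) in the cleft,
#' and simulates two reconstructions on a shared grid: `map_with` (receptor +
#' ligand) and `map_without` (receptor only), each with independent additive
#' Gaussian voxel noise of standard deviation `noise_sigma` times the
#' noise-free ligand peak height. With `conformational_change = TRUE` a
#' four-residue loop of chain A is displaced between the two states,
#' emulating receptor regions that differ between reconstructions
#' independently of the ligand.
#'
#' @param resolution nominal resolution in Angstrom (>= 2 * voxel).
#' @param voxel voxel size in Angstrom.
#' @param noise_sigma noise level as a fraction of the ligand peak height.
#' @param conformational_change displace a receptor loop between the states.
#' @param seed integer seed; the scene is a pure function of its arguments.
#' @param sigma_coeff,cutoff density-simulation convention, see [sim_params].
#' @return object of class `synthetic_scene` with elements `receptor`,
#'   `receptor_ref`, `true_pose`, `map_with`, `map_without`, `clean_with`,
#'   `clean_without`, `ligand_peak`, `params`, and the generator arguments.
#' @export
make_scene <- function(resolution = 4, voxel = 1, noise_sigma = 0.1,
                       conformational_change = FALSE, seed = 1,
                       sigma_coeff = 0.356, cutoff = 4) {
  if (resolution < 2 * voxel)
    stop("config error: resolution must be >= 2 * voxel")
  if (noise_sigma < 0) stop("config error: noise_sigma must be >= 0")
  with_seed(seed, {
    n_res <- 30L
    helixA <- .build_helix("A", n_res, cx = -6.5, phase = 0)
    helixB <- .build_helix("B", n_res, cx = +6.5, phase = pi)
    receptor_atoms <- rbind(helixA, helixB)
    receptor <- atomic_model(receptor_atoms, source_id = "synthetic-receptor")

    ref_atoms <- receptor_atoms
    if (conformational_change) {
      # loop = last 4 residues of chain A, shifted in the reference state
      sel <- ref_atoms$chain == "A" & ref_atoms$resno >= n_res - 3L
      ref_atoms$x[sel] <- ref_atoms$x[sel] + 1.8
      ref_atoms$y[sel] <- ref_atoms$y[sel] + 0.8
    }
    receptor_ref <- atomic_model(ref_atoms, source_id = "synthetic-receptor-ref")

    z_mid <- (n_res - 1) * 1.5 / 2
    lig_at <- .translate_atoms(.build_ligand_atoms(), c(0, 0, z_mid))
    true_pose <- ligand_pose(lig_at, pose_id = "truth")

    params <- sim_params(resolution, voxel, sigma_coeff = sigma_coeff,
                         cutoff = cutoff)
    pad <- max(3, cutoff) * sigma_coeff * resolution
    allx <- c(receptor_atoms$x, ref_atoms$x, lig_at$x)
    ally <- c(receptor_atoms$y, ref_atoms$y, lig_at$y)
    allz <- c(receptor_atoms$z, ref_atoms$z, lig_at$z)
    lo <- c(min(allx), min(ally), min(allz)) - pad
    n <- as.integer(ceiling((c(max(allx), max(ally), max(allz)) + pad - lo) /
                              voxel)) + 1L
    grid <- voxel_map(array(0, n), voxel, lo, resolution)

    with_model <- atomic_model(rbind(
      receptor_atoms,
      data.frame(chain = "L", resno = 1L, resname = "LIG",
                 atom = lig_at$atom, element = lig_at$element,
                 x = lig_at$x, y = lig_at$y, z = lig_at$z,
                 occupancy = 1, b = 0, stringsAsFactors = FALSE)),
      source_id = "synthetic-complex")

    clean_with <- simulate_map(with_model, params, grid = grid)
    clean_without <- simulate_map(receptor_ref, params, grid = grid)
    ligand_peak <- max(simulate_map(true_pose, params, grid = grid)$data)

    noise_sd <- noise_sigma * ligand_peak
    map_with <- clean_with
    map_without <- clean_without
    if (noise_sd > 0) {
      map_with$data <- map_with$data +
        array(rnorm(length(map_with$data), sd = noise_sd), dim(map_with$data))
      map_without$data <- map_without$data +
        array(rnorm(length(map_without$data), sd = noise_sd),
              dim(map_without$data))
    }
    structure(list(
      receptor = receptor, receptor_ref = receptor_ref,
      true_pose = true_pose,
      map_with = map_with, map_without = map_without,
      clean_with = clean_with, clean_without = clean_without,
      ligand_peak = ligand_peak, params = params,
      resolution = resolution, voxel = voxel, noise_sigma = noise_sigma,
      conformational_change = conformational_change, seed = seed),
      class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "synthetic_scene (seed %s): %s grid, %.1f A resolution, noise %.3g x ligand peak%s\n",
    format(x$seed), paste(dim(x$map_with$data), collapse = "x"),
    x$resolution, x$noise_sigma,
    if (x$conformational_change) ", with conformational change" else ""))
  invisible(x)
}

# sample one rigid decoy with (symmetry-aware) RMSD to truth inside `range`
.sample_decoy <- function(truth, range, box_lo, box_hi, map, autos,
                          max_tries = 4000L) {
  b <- map_bounds(map)
  for (t in seq_len(max_tries)) {
    target <- runif(3, box_lo, box_hi)
    cand <- .transform_pose(truth, .random_rotation(), target)
    r <- pose_rmsd(truth, cand, autos = autos)
    if (r < range[1] || r > range[2]) next
    if (any(cand$atoms$x < b[1, 1] + 1) || any(cand$atoms$x > b[2, 1] - 1) ||
        any(cand$atoms$y < b[1, 2] + 1) || any(cand$atoms$y > b[2, 2] - 1) ||
        any(cand$atoms$z < b[1, 3] + 1) || any(cand$atoms$z > b[2, 3] - 1))
      next
    return(cand)
  }
  stop("could not sample a decoy in the requested RMSD range ",
       "(range too narrow for the scene box?)")
}

# small rigid perturbation of the truth with RMSD in [0.2, 0.8] A
.sample_near_native <- function(truth, autos, max_tries = 2000L) {
  for (t in seq_len(max_tries)) {
    ang <- runif(1, 1, 8) * pi / 180
    R <- .rotation_about_axis(rnorm(3), ang)
    shift <- rnorm(3)
    shift <- shift / sqrt(sum(shift^2)) * runif(1, 0.05, 0.5)
    cand <- .transform_pose(truth, R, pose_centroid(truth) + shift)
    r <- pose_rmsd(truth, cand, autos = autos)
    if (r >= 0.2 && r <= 0.8) return(cand)
  }
  stop("could not sample a near-native perturbation")
}

#' Emulate scored docking-engine outputs for a synthetic scene
#'
#' For each emulated engine the output contains one near-native pose
#' (perturbed at most 1 Angstrom from the planted truth) and rigid-transform
#' decoys whose RMSD to truth lies in `decoy_range`. A fraction of the decoys
#' is shared across engines (lightly jittered), emulating spurious
#' cross-engine agreement. Engine scores are drawn so that the near-native
#' pose is never the best-scored pose of any engine: score alone cannot
#' recover the truth, density constraints must.
#'
#' @param scene a [make_scene] result.
#' @param n_engines number of engines (2-4: vina, chemscore, goldscore,
#'   chemplp).
#' @param n_poses poses per engine (>= 2).
#' @param decoy_range RMSD range of decoys to truth, Angstrom; a lower bound
#'   under 2 triggers a warning (decoys may alias the native cluster).
#' @param consensus_fraction fraction of decoys shared across all engines.
#' @param seed integer seed.
#' @return object of class `engine_emulation` with `pose_sets` (named list
#'   engine -> pose list), `native_ids`, `shared_decoy_ids`, and the
#'   generator arguments.
#' @export
make_engine_outputs <- function(scene, n_engines = 3, n_poses = 20,
                                decoy_range = c(5, 20),
                                consensus_fraction = 0.1, seed = 1) {
  if (!inherits(scene, "synthetic_scene")) stop("`scene` must be make_scene()")
  if (n_engines < 2) stop("n_engines must be >= 2")
  if (n_poses < 2) stop("n_poses must be >= 2")
  if (decoy_range[1] < 2)
    warning("decoy_range lower bound < 2 A: decoys may alias the native cluster")
  labels <- c("vina", "chemscore", "goldscore", "chemplp")[seq_len(n_engines)]
  orient <- ifelse(labels == "vina", "lower", "higher")
  truth <- scene$true_pose
  autos <- pose_automorphisms(truth)
  n_dec <- n_poses - 1L
  k_shared <- max(0L, min(n_dec, round(consensus_fraction * n_dec)))
  box_lo <- c(-5, -3, 5)
  box_hi <- c(5, 3, 38.5)

  with_seed(seed, {
    shared_base <- lapply(seq_len(k_shared), function(i)
      .sample_decoy(truth, c(decoy_range[1] + 1, decoy_range[2] - 1),
                    box_lo, box_hi, scene$map_with, autos))
    pose_sets <- list()
    native_ids <- character(n_engines)
    shared_ids <- list()
    for (e in seq_len(n_engines)) {
      eng <- labels[e]
      native <- .sample_near_native(truth, autos)
      uniq <- lapply(seq_len(n_dec - k_shared), function(i)
        .sample_decoy(truth, decoy_range, box_lo, box_hi, scene$map_with,
                      autos))
      shared <- lapply(shared_base, function(p) {
        R <- .rotation_about_axis(rnorm(3), runif(1, 0, 2) * pi / 180)
        .transform_pose(p, R, pose_centroid(p) + rnorm(3, sd = 0.08))
      })
      poses <- c(list(native), shared, uniq)
      perm <- sample.int(length(poses))
      poses <- poses[perm]
      native_pos <- which(perm == 1L)
      shared_pos <- match(seq_len(k_shared) + 1L, perm)

      # scores drawn best-first, near-native pinned to mid-rank
      raw <- if (orient[e] == "lower") sort(runif(n_poses, -12, -4))
             else sort(runif(n_poses, 20, 90), decreasing = TRUE)
      native_rank <- min(n_poses, floor(n_poses / 2) + 1L)
      decoy_ranks <- sample(setdiff(seq_len(n_poses), native_rank))
      scores <- numeric(n_poses)
      scores[native_pos] <- raw[native_rank]
      scores[setdiff(seq_len(n_poses), native_pos)] <- raw[decoy_ranks]
      for (i in seq_along(poses)) {
        poses[[i]]$pose_id <- sprintf("%s_p%02d", eng, i)
        poses[[i]]$engine <- eng
        poses[[i]]$engine_score <- scores[i]
        poses[[i]]$score_orientation <- orient[e]
      }
      pose_sets[[eng]] <- poses
      native_ids[e] <- poses[[native_pos]]$pose_id
      shared_ids[[eng]] <- vapply(shared_pos, function(i) poses[[i]]$pose_id,
                                  character(1))
    }
    structure(list(engines = labels, pose_sets = pose_sets,
                   native_ids = setNames(native_ids, labels),
                   shared_decoy_ids = shared_ids,
                   decoy_range = decoy_range,
                   consensus_fraction = consensus_fraction, seed = seed),
              class = "engine_emulation")
  })
}

#' Generate a synthetic kinetic titration table
#'
#' Concentration series with multiplicative Gaussian noise around the exact
#' model curve: linear spacing from 0 to 6x K for the Michaelis-Menten model,
#' log spacing over two decades either side of the IC50 for the inhibition
#' model.
#'
#' @param model `"mm"` or `"ic50"`.
#' @param truth named list of true parameters: `vmax`, `k` for `"mm"`;
#'   `a`, `b`, `c` for `"ic50"`.
#' @param n_points number of concentrations (>= 3).
#' @param noise_sigma multiplicative noise SD (fraction of the true value).
#' @param seed integer seed.
#' @return data.frame with columns `conc`, `response`; the generator
#'   arguments are attached as attributes.
#' @export
make_titration <- function(model = c("mm", "ic50"), truth, n_points = 8,
                           noise_sigma = 0.05, seed = 1) {
  model <- match.arg(model)
  if (n_points < 3) stop("n_points must be >= 3")
  with_seed(seed, {
    if (model == "mm") {
      if (is.null(truth$vmax) || is.null(truth$k))
        stop("mm truth needs `vmax` and `k`")
      if (truth$vmax <= 0 || truth$k <= 0) stop("mm truth must be positive")
      conc <- seq(0, 6 * truth$k, length.out = n_points)
      y <- truth$vmax * conc / (truth$k + conc)
    } else {
      if (is.null(truth$a) || is.null(truth$b) || is.null(truth$c))
        stop("ic50 truth needs `a`, `b` and `c`")
      if (truth$a <= 0 || truth$b <= 0 || truth$c <= 0)
        stop("ic50 truth must be positive")
      conc <- 10^seq(log10(truth$b) - 2, log10(truth$b) + 2,
                     length.out = n_points)
      y <- truth$a / (1 + (conc / truth$b)^truth$c)
    }
    resp <- y * (1 + rnorm(n_points, sd = noise_sigma))
    out <- data.frame(conc = conc, response = pmax(resp, 0))
    attr(out, "model") <- model
    attr(out, "truth") <- truth
    attr(out, "seed") <- seed
    out
  })
}
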