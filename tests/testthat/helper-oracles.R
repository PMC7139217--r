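# Shared fixtures (built in code) and independent brute-force oracles.

# brute-force Pearson over masked voxels: explicit accumulation loop,
# independent of the vectorized implementation
brute_pearson <- function(a, b, idx) {
  sx <- sy <- sxx <- syy <- sxy <- 0
  n <- 0L
  for (i in idx) {
    x <- a[i]
    y <- b[i]
    sx <- sx + x; sy <- sy + y
    sxx <- sxx + x * x; syy <- syy + y * y; sxy <- sxy + x * y
    n <- n + 1L
  }
  (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

# all permutations of 1..n (n small), recursively
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# exhaustive symmetry-aware RMSD: minimum over every permutation that
# preserves elements and bond adjacency
brute_sym_rmsd <- function(p, q, bond_cut = 1.8) {
  P <- as.matrix(p$atoms[, c("x", "y", "z")])
  Q <- as.matrix(q$atoms[, c("x", "y", "z")])
  el <- p$atoms$element
  n <- nrow(P)
  adj <- as.matrix(dist(P)) < bond_cut & as.matrix(dist(P)) > 0.1
  best <- Inf
  for (perm in all_perms(n)) {
    perm <- unlist(perm)
    if (!all(el[perm] == el)) next
    if (!all(adj[perm, perm] == adj)) next
    r <- sqrt(mean(rowSums((P - Q[perm, , drop = FALSE])^2)))
    if (r < best) best <- r
  }
  best
}

# small asymmetric rigid fragment (trivial automorphism group)
frag_atoms <- function() {
  data.frame(atom = c("C1", "N1", "O1", "F1"),
             element = c("C", "N", "O", "F"),
             x = c(0, 1.4, 2.1, -0.7),
             y = c(0, 0.2, 1.3, 1.1),
             z = c(0, 0, 0.4, -0.3),
             stringsAsFactors = FALSE)
}

translated_pose <- function(id, shift, engine = NA_character_,
                            score = NA_real_, orient = NA_character_) {
  at <- frag_atoms()
  at$x <- at$x + shift[1]
  at$y <- at$y + shift[2]
  at$z <- at$z + shift[3]
  ligand_pose(at, pose_id = id, engine = engine, engine_score = score,
              score_orientation = orient)
}

random_pose_set <- function(n, engine, box = 15, seed_shift = 0) {
  lapply(seq_len(n), function(i)
    translated_pose(sprintf("%s_%02d", engine, i),
                    runif(3, -box, box), engine = engine,
                    score = runif(1, 0, 100), orient = "higher"))
}

# verify the two dedup guarantees by exhaustive checking
check_dedup_properties <- function(clusters, poses, threshold) {
  reps <- lapply(clusters, `[[`, "representative")
  n_rep <- length(reps)
  if (n_rep > 1) {
    for (i in seq_len(n_rep - 1)) {
      for (j in (i + 1):n_rep) {
        if (pose_rmsd(reps[[i]], reps[[j]]) <= threshold) return(FALSE)
      }
    }
  }
  covered <- unlist(lapply(clusters, `[[`, "members"))
  if (!setequal(covered, vapply(poses, function(p) p$pose_id, character(1))))
    return(FALSE)
  for (cl in clusters) {
    for (m in cl$member_poses) {
      if (pose_rmsd(cl$representative, m) > threshold) return(FALSE)
    }
  }
  TRUE
}

# independent exhaustive consensus enumeration: the (engine, pose_id) pairs
# for which every other engine holds a pose within threshold
brute_consensus_ids <- function(sets, threshold) {
  engines <- names(sets)
  out <- character()
  for (e in engines) {
    for (p in sets[[e]]) {
      ok <- TRUE
      for (o in engines[engines != e]) {
        dmin <- min(vapply(sets[[o]], function(q)
          pose_rmsd(p, q, symmetry = FALSE), numeric(1)))
        if (dmin > threshold) {
          ok <- FALSE
          break
        }
      }
      if (ok) out <- c(out, paste(e, p$pose_id, sep = "/"))
    }
  }
  out
}

scene_cache <- local({
  cache <- list()
  function(...) {
    key <- paste(deparse(list(...)), collapse = "")
    if (is.null(cache[[key]])) cache[[key]] <<- make_scene(...)
    cache[[key]]
  }
})
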