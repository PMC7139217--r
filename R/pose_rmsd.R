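# In-frame ligand pose RMSD, optionally minimized over chemically equivalent
# atom mappings (bond-graph automorphisms). No superposition is performed:
# docking poses share the receptor frame, and translation differences between
# sites are meaningful.

.match_pose_atoms <- function(p, q) {
  pa <- p$atoms[!(p$atoms$element %in% c("H", "D")), , drop = FALSE]
  qa <- q$atoms[!(q$atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(pa) != nrow(qa))
    stop("correspondence error: poses have different heavy-atom counts (",
         nrow(pa), " vs ", nrow(qa), ")")
  if (!identical(sort(pa$element), sort(qa$element)))
    stop("correspondence error: poses have different element compositions")
  if (!anyDuplicated(pa$atom) && !anyDuplicated(qa$atom) &&
      setequal(pa$atom, qa$atom)) {
    qa <- qa[match(pa$atom, qa$atom), , drop = FALSE]
  } else if (!identical(pa$element, qa$element)) {
    stop("correspondence error: atom names are not unique and atom order ",
         "does not give a consistent element correspondence")
  }
  list(P = as.matrix(pa[, c("x", "y", "z")]),
       Q = as.matrix(qa[, c("x", "y", "z")]),
       elements = pa$element)
}

.rmsd_mat <- function(P, Q) sqrt(mean(rowSums((P - Q)^2)))

# distance-based bond inference: bonded if closer than the sum of covalent
# radii plus 0.45 A slack
.infer_bonds <- function(coords, elements) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  rc <- covalent_radius(elements)
  cut <- outer(rc, rc, "+") + 0.45
  adj <- d <= cut & d > 0.1
  diag(adj) <- FALSE
  adj
}

# All element-preserving bond-graph automorphisms (as permutation vectors),
# or NULL when the group exceeds `cap` mappings.
pose_automorphisms <- function(pose, cap = 10000L) {
  at <- pose$atoms[!(pose$atoms$element %in% c("H", "D")), , drop = FALSE]
  n <- nrow(at)
  adj <- .infer_bonds(as.matrix(at[, c("x", "y", "z")]), at$element)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  colors <- as.integer(factor(at$element))
  gens <- tryCatch(igraph::automorphism_group(g, colors = colors),
                   error = function(e) NULL)
  if (is.null(gens)) return(list(seq_len(n)))
  gens <- lapply(gens, as.integer)
  # closure of the generator set under composition, capped
  seen <- new.env(parent = emptyenv())
  id <- seq_len(n)
  key <- function(p) paste(p, collapse = ",")
  assign(key(id), TRUE, envir = seen)
  out <- list(id)
  queue <- list(id)
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (gp in gens) {
      nxt <- cur[gp]
      k <- key(nxt)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        if (length(out) >= cap) {
          warning("automorphism enumeration exceeded ", cap,
                  " mappings; falling back to fixed correspondence")
          return(NULL)
        }
        assign(k, TRUE, envir = seen)
        out[[length(out) + 1L]] <- nxt
        queue[[length(queue) + 1L]] <- nxt
      }
    }
  }
  out
}

#' RMSD between two ligand poses
#'
#' Heavy-atom root-mean-square deviation under atom-name correspondence, in
#' the shared receptor frame (no superposition). With `symmetry = TRUE` the
#' minimum over all chemically equivalent atom mappings is returned; the
#' mappings are the automorphisms of the element-colored bond graph
#' (distance-inferred bonds), with enumeration capped at 10,000 mappings
#' beyond which the fixed-correspondence value is used with a warning.
#'
#' @param p,q [ligand_pose] objects with identical atom count and element
#'   multiset.
#' @param symmetry minimize over equivalent atom mappings (default TRUE).
#' @param autos pre-computed result of an automorphism enumeration (internal
#'   use; avoids recomputation in all-pairs loops).
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(p, q, symmetry = TRUE, autos = NULL) {
  m <- .match_pose_atoms(p, q)
  base <- .rmsd_mat(m$P, m$Q)
  if (!symmetry) return(base)
  if (is.null(autos)) autos <- pose_automorphisms(p)
  if (is.null(autos) || length(autos) <= 1L) return(base)
  best <- base
  for (perm in autos) {
    r <- .rmsd_mat(m$P, m$Q[perm, , drop = FALSE])
    if (r < best) best <- r
  }
  best
}

# Pairwise RMSD with a shared automorphism enumeration (all poses of one
# ligand species).
pose_rmsd_matrix <- function(poses, symmetry = TRUE) {
  n <- length(poses)
  autos <- if (symmetry && n) pose_automorphisms(poses[[1]]) else NULL
  m <- matrix(0, n, n)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- pose_rmsd(poses[[i]], poses[[j]],
                                      symmetry = symmetry, autos = autos)
    }
  }
  m
}
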