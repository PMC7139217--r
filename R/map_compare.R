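# Difference mapping, amplitude scaling, CCC and SMOC scoring.

#' Scale one map's Fourier amplitudes to match another's
#'
#' Multiplies each Fourier shell of `b` by a constant so that its radially
#' averaged power matches that of `a`; phases are unchanged. The DC term is
#' always its own shell, so with a single shell spanning the whole spectrum
#' the operation reduces to global mean/std matching. This amplitude matching
#' is the normalization step applied before subtracting two reconstructions
#' of the same specimen.
#'
#' @param b map to rescale.
#' @param a reference map (congruent grid; resample first if not).
#' @param shell_width shell width in reciprocal Angstrom; default one Fourier
#'   pixel, `1 / max(box length)`.
#' @return a [voxel_map] congruent with `a`.
#' @export
scale_amplitudes <- function(b, a, shell_width = NULL) {
  stop_if_incongruent(a, b)
  n <- dim(a$data)
  Fa <- fft(a$data)
  Fb <- fft(b$data)
  wrapped <- function(len) {
    k <- 0:(len - 1)
    ifelse(k <= len / 2, k, k - len)
  }
  kx <- wrapped(n[1]) / (n[1] * a$voxel_size[1])
  ky <- wrapped(n[2]) / (n[2] * a$voxel_size[2])
  kz <- wrapped(n[3]) / (n[3] * a$voxel_size[3])
  r <- sqrt(outer(outer(kx^2, ky^2, "+"), kz^2, "+"))
  if (is.null(shell_width)) shell_width <- 1 / max(n * a$voxel_size)
  bin <- as.integer(floor(r / shell_width)) + 2L
  bin[1L] <- 1L                       # DC term is always its own shell
  pa <- rowsum(as.vector(Mod(Fa)^2), bin)
  pb <- rowsum(as.vector(Mod(Fb)^2), bin)
  fac <- sqrt(pa / pb)
  fac[!is.finite(fac)] <- 1           # empty shells in b: nothing to scale
  Fb <- Fb * array(fac[match(bin, as.integer(rownames(pa)))], n)
  voxel_map(Re(fft(Fb, inverse = TRUE)) / prod(n),
            a$voxel_size, a$origin, b$nominal_resolution)
}

#' Difference map between two reconstructions
#'
#' Scales `b`'s shell amplitudes to `a` (see [scale_amplitudes]) and subtracts.
#' Positive difference density localizes features present in `a` only, e.g. a
#' bound ligand or a shifted loop.
#'
#' @param a,b congruent [voxel_map]s (`a` minus `b`).
#' @param shell_width passed to [scale_amplitudes].
#' @return list of class `difference_result` with elements `scaled_b`,
#'   `difference` (`a - scaled_b`) and `positive` (difference clamped at 0).
#' @export
difference_map <- function(a, b, shell_width = NULL) {
  stop_if_incongruent(a, b)
  sb <- scale_amplitudes(b, a, shell_width)
  diff <- voxel_map(a$data - sb$data, a$voxel_size, a$origin,
                    a$nominal_resolution)
  pos <- voxel_map(pmax(diff$data, 0), a$voxel_size, a$origin,
                   a$nominal_resolution)
  structure(list(scaled_b = sb, difference = diff, positive = pos),
            class = "difference_result")
}

#' @export
print.difference_result <- function(x, ...) {
  cat(sprintf("difference_result: %s voxels, positive density max %.4g\n",
              paste(dim(x$difference$data), collapse = " x "),
              max(x$positive$data)))
  invisible(x)
}

.proximity_radius <- function(params, mask_radius = NULL) {
  mask_radius %||% max(2.5, params$resolution / 2)
}

#' Model-to-map cross-correlation coefficient
#'
#' Pearson correlation between an experimental map and a density simulated
#' from an atomic probe, over a voxel mask. The default mask keeps voxels
#' within `max(2.5, resolution/2)` Angstrom of any probe atom, which makes the
#' score sensitive to local fit rather than to the bulk of the reconstruction.
#' Scores over masks smaller than 30 voxels are flagged unreliable but still
#' returned.
#'
#' @param map experimental [voxel_map].
#' @param probe an [atomic_model], [ligand_pose], or a pre-simulated
#'   [voxel_map] congruent with `map`.
#' @param params [sim_params]; required when `probe` is atomic.
#' @param mask_mode `"model-proximity"` (default), `"sim-contour"` (voxels
#'   where the simulated density is nonzero), or `"whole-map"`.
#' @param mask_radius override the proximity radius (Angstrom).
#' @param mask optional logical array or integer voxel index vector used
#'   verbatim instead of `mask_mode`.
#' @return list with `ccc`, `mask_voxel_count`, `reliable`.
#' @export
ccc <- function(map, probe, params = NULL,
                mask_mode = c("model-proximity", "sim-contour", "whole-map"),
                mask_radius = NULL, mask = NULL) {
  mask_mode <- match.arg(mask_mode)
  if (is_voxel_map(probe)) {
    stop_if_incongruent(map, probe, "map and probe map")
    sim <- probe
    atoms <- NULL
  } else {
    if (is.null(params)) stop("`params` is required for an atomic probe")
    sim <- simulate_map(probe, params, grid = map)
    atoms <- .heavy_atoms(probe)
  }
  if (is.null(mask)) {
    idx <- switch(mask_mode,
      "model-proximity" = {
        if (is.null(atoms))
          stop("model-proximity masking requires an atomic probe")
        mask_indices_for_atoms(map, atoms, .proximity_radius(params, mask_radius))
      },
      "sim-contour" = which(sim$data > max(sim$data) * 1e-6),
      "whole-map" = seq_along(map$data))
  } else {
    idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
  }
  n <- length(idx)
  v1 <- map$data[idx]
  v2 <- sim$data[idx]
  r <- if (n >= 2 && sd(v1) > 0 && sd(v2) > 0) cor(v1, v2) else NA_real_
  list(ccc = r, mask_voxel_count = n, reliable = n >= 30)
}

#' Per-residue local map-model fit (SMOC profile)
#'
#' Assesses the local fit of a model in a map with a sliding window of
#' `window` residues along each chain (truncated at chain ends). The
#' per-residue statistic is the Manders overlap coefficient (uncentered
#' correlation) between the experimental and model-simulated density over the
#' residue's proximity mask -- the segment overlap score commonly used to
#' grade local fit during flexible fitting; Pearson correlation is available
#' via `stat`. With the default `"window-average"` pooling, the score
#' assigned to each residue is the triangularly weighted window mean of the
#' per-residue statistics (weights decay linearly from the central residue),
#' so a single misfit residue produces the profile minimum at that residue
#' while noise is still averaged over the window. The `"window-mask"` variant
#' instead computes one statistic over the pooled proximity mask of all
#' window atoms; it spreads a single-residue error into a flat-bottomed dip.
#' Chains whose residues have no atom inside the map are skipped with a
#' warning.
#'
#' @param model an [atomic_model] with residues ordered along each chain.
#' @param map experimental [voxel_map].
#' @param params [sim_params].
#' @param window odd window length in residues (default 9).
#' @param mask_radius proximity radius; default `max(2.5, resolution/2)`.
#' @param method `"window-average"` (default) or `"window-mask"`, see above.
#' @param stat per-voxel-set statistic: `"manders"` (default) or `"pearson"`.
#' @return data.frame of class `local_fit_profile` with columns `chain`,
#'   `resno`, `smoc`; the window size is attached as attribute `window`.
#' @export
smoc <- function(model, map, params, window = 9, mask_radius = NULL,
                 method = c("window-average", "window-mask"),
                 stat = c("manders", "pearson")) {
  method <- match.arg(method)
  stat <- match.arg(stat)
  statfun <- if (stat == "manders") {
    function(x, y) {
      den <- sqrt(sum(x^2) * sum(y^2))
      if (den > 0) sum(x * y) / den else NA_real_
    }
  } else {
    function(x, y)
      if (sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_
  }
  if (window %% 2 != 1 || window < 1) stop("`window` must be odd and >= 1")
  at <- .heavy_atoms(model)
  radius <- .proximity_radius(params, mask_radius)
  b <- map_bounds(map)
  inside <- at$x >= b[1, 1] & at$x <= b[2, 1] &
    at$y >= b[1, 2] & at$y <= b[2, 2] &
    at$z >= b[1, 3] & at$z <= b[2, 3]
  if (!any(inside)) stop("no model atoms inside the map")
  sim_model <- model
  sim_model$atoms <- model$atoms[
    !(toupper(model$atoms$element) %in% c("H", "D")), , drop = FALSE][inside, ,
                                                                     drop = FALSE]
  sim <- simulate_map(sim_model, params, grid = map)
  out <- list()
  half <- (window - 1) %/% 2
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    ins <- inside[at$chain == ch]
    resnos <- unique(ca$resno)          # order of appearance = chain order
    if (!any(ins)) {
      warning("chain ", ch, " has no atoms inside the map; skipped")
      next
    }
    # proximity voxel indices per residue, computed once
    res_idx <- lapply(resnos, function(rn) {
      sel <- ca$resno == rn & ins
      if (!any(sel)) integer() else
        mask_indices_for_atoms(map, ca[sel, , drop = FALSE], radius)
    })
    nres <- length(resnos)
    sc <- rep(NA_real_, nres)
    if (method == "window-average") {
      rcor <- vapply(res_idx, function(idx) {
        if (length(idx) < 2L) return(NA_real_)
        statfun(map$data[idx], sim$data[idx])
      }, numeric(1))
      for (i in seq_len(nres)) {
        win <- max(1L, i - half):min(nres, i + half)
        w <- half + 1 - abs(win - i)        # triangular window weights
        ok <- is.finite(rcor[win])
        if (any(ok))
          sc[i] <- sum(w[ok] * rcor[win][ok]) / sum(w[ok])
      }
    } else {
      for (i in seq_len(nres)) {
        win <- max(1L, i - half):min(nres, i + half)
        idx <- unique(unlist(res_idx[win]))
        if (length(idx) < 2L) next
        sc[i] <- statfun(map$data[idx], sim$data[idx])
      }
    }
    out[[ch]] <- data.frame(chain = ch, resno = resnos, smoc = sc,
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no chain had atoms inside the map")
  prof <- do.call(rbind, out)
  rownames(prof) <- NULL
  attr(prof, "window") <- window
  class(prof) <- c("local_fit_profile", "data.frame")
  prof
}

# 26-connected neighborhood offsets
.offsets26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

#' Detect peaks in a difference map
#'
#' Thresholds the map at `mean + threshold_sigma * sd` (statistics over the
#' whole grid), groups the surviving voxels by 26-connectivity, and returns
#' the connected components of at least `min_volume` voxels, sorted by peak
#' maximum (descending; ties by larger volume, then lexicographic centroid).
#' Centroids are density-weighted.
#'
#' @param diff a [voxel_map] (typically the positive difference map).
#' @param threshold_sigma threshold in multiples of the map's sd above mean.
#' @param min_volume minimum component size in voxels.
#' @return data.frame with columns `peak_id`, `x`, `y`, `z`, `volume`,
#'   `max_value`, `threshold_used`; zero rows when nothing exceeds threshold.
#' @export
find_difference_peaks <- function(diff, threshold_sigma = 3, min_volume = 5) {
  x <- diff$data
  if (!all(is.finite(x))) stop("difference map contains non-finite values")
  empty <- data.frame(peak_id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), volume = integer(),
                      max_value = numeric(), threshold_used = numeric())
  s <- sd(as.vector(x))
  if (s == 0) return(empty)
  thr <- mean(x) + threshold_sigma * s
  sel <- which(x > thr)
  if (!length(sel)) return(empty)
  dm <- dim(x)
  above <- array(FALSE, dm)
  above[sel] <- TRUE
  labeled <- array(FALSE, dm)
  comps <- list()
  for (s0 in sel) {
    if (labeled[s0]) next
    queue <- s0
    labeled[s0] <- TRUE
    members <- integer()
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      members <- c(members, cur)
      ijk <- arrayInd(cur, dm)
      nb <- .offsets26 + matrix(ijk, nrow(.offsets26), 3, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
        nb[, 2] >= 1 & nb[, 2] <= dm[2] &
        nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + dm[1] * (nb[, 2] - 1L) + dm[1] * dm[2] * (nb[, 3] - 1L)
      lin <- lin[above[lin] & !labeled[lin]]
      if (length(lin)) {
        labeled[lin] <- TRUE
        queue <- c(queue, lin)
      }
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps <- comps[vapply(comps, length, integer(1)) >= min_volume]
  if (!length(comps)) return(empty)
  rows <- lapply(comps, function(vox) {
    vals <- x[vox]
    ar <- arrayInd(vox, dm)
    phys <- sweep(sweep(ar - 1, 2, diff$voxel_size, "*"), 2, diff$origin, "+")
    w <- vals / sum(vals)
    cen <- colSums(phys * w)
    data.frame(x = cen[1], y = cen[2], z = cen[3],
               volume = length(vox), max_value = max(vals))
  })
  pk <- do.call(rbind, rows)
  ord <- order(-pk$max_value, -pk$volume, pk$x, pk$y, pk$z)
  pk <- pk[ord, , drop = FALSE]
  pk <- cbind(peak_id = seq_len(nrow(pk)), pk,
              threshold_used = threshold_sigma)
  rownames(pk) <- NULL
  pk
}
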