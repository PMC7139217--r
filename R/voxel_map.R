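#' Construct a voxel density map
#'
#' A `voxel_map` is a 3-D scalar density grid with a physical origin and voxel
#' size. The physical position of voxel `(i, j, k)` (1-based R indexing) is
#' `origin + (i-1, j-1, k-1) * voxel_size`; coordinates are Angstrom,
#' right-handed, with the first array index running along x.
#'
#' @param data numeric 3-D array of density values (arbitrary units).
#' @param voxel_size Angstrom per voxel along each axis (length 1 or 3, > 0).
#' @param origin physical coordinate of voxel (1,1,1) in Angstrom (length 3).
#' @param nominal_resolution optional nominal resolution in Angstrom.
#' @return an object of class `voxel_map`.
#' @examples
#' m <- voxel_map(array(0, c(8, 8, 8)), voxel_size = 1.09)
#' dim(m$data)
#' @export
voxel_map <- function(data, voxel_size, origin = c(0, 0, 0),
                      nominal_resolution = NA_real_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 2L))
    stop("`data` must have at least 2 voxels along every axis")
  voxel_size <- vec3(voxel_size, "voxel_size")
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be positive and finite on all axes")
  origin <- vec3(origin, "origin")
  if (any(!is.finite(origin))) stop("`origin` must be finite")
  structure(list(data = data, voxel_size = voxel_size, origin = origin,
                 nominal_resolution = as.numeric(nominal_resolution)),
            class = "voxel_map")
}

is_voxel_map <- function(x) inherits(x, "voxel_map")

#' @export
print.voxel_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_map: %d x %d x %d voxels, %.4g x %.4g x %.4g A/voxel\n",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (%.3f, %.3f, %.3f) A; range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

# physical voxel-center coordinates along one axis (1 = x, 2 = y, 3 = z)
voxel_centers <- function(map, axis) {
  map$origin[axis] + (seq_len(dim(map$data)[axis]) - 1) * map$voxel_size[axis]
}

map_bounds <- function(map) {
  lo <- map$origin
  hi <- map$origin + (dim(map$data) - 1) * map$voxel_size
  rbind(lo = lo, hi = hi)
}

#' Test whether two maps share the same grid
#'
#' @param a,b `voxel_map` objects.
#' @param tol absolute tolerance on voxel size and origin (Angstrom).
#' @return logical.
#' @export
map_congruent <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_incongruent <- function(a, b, what = "maps") {
  if (!map_congruent(a, b))
    stop("congruence error: ", what, " must share grid dimensions, ",
         "voxel size and origin (resample first with resample_map())")
  invisible(TRUE)
}

#' Resample a map onto another map's grid
#'
#' Trilinear interpolation of `map` onto the grid of `template`; voxels of the
#' template that fall outside `map` are set to 0.
#'
#' @param map `voxel_map` to resample.
#' @param template `voxel_map` whose grid defines the output.
#' @return a `voxel_map` congruent with `template`.
#' @export
resample_map <- function(map, template) {
  dt <- dim(template$data)
  xs <- voxel_centers(template, 1)
  ys <- voxel_centers(template, 2)
  zs <- voxel_centers(template, 3)
  # fractional (0-based) index of every template voxel center in `map`
  fx <- rep((xs - map$origin[1]) / map$voxel_size[1], times = dt[2] * dt[3])
  fy <- rep(rep((ys - map$origin[2]) / map$voxel_size[2], each = dt[1]),
            times = dt[3])
  fz <- rep((zs - map$origin[3]) / map$voxel_size[3], each = dt[1] * dt[2])
  dm <- dim(map$data)
  eps <- 1e-9
  inside <- fx >= -eps & fx <= dm[1] - 1 + eps &
    fy >= -eps & fy <= dm[2] - 1 + eps &
    fz >= -eps & fz <= dm[3] - 1 + eps
  # clamp so the exact upper boundary interpolates from the last cell
  i0 <- pmin(pmax(floor(fx), 0), dm[1] - 2)
  j0 <- pmin(pmax(floor(fy), 0), dm[2] - 2)
  k0 <- pmin(pmax(floor(fz), 0), dm[3] - 2)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  out <- numeric(length(fx))
  if (any(inside)) {
    i0 <- i0[inside]; j0 <- j0[inside]; k0 <- k0[inside]
    tx <- tx[inside]; ty <- ty[inside]; tz <- tz[inside]
    base <- 1 + i0 + dm[1] * (j0 + dm[2] * k0)
    sx <- 1; sy <- dm[1]; sz <- dm[1] * dm[2]
    v <- map$data
    out[inside] <-
      v[base]                * (1 - tx) * (1 - ty) * (1 - tz) +
      v[base + sx]           * tx       * (1 - ty) * (1 - tz) +
      v[base + sy]           * (1 - tx) * ty       * (1 - tz) +
      v[base + sx + sy]      * tx       * ty       * (1 - tz) +
      v[base + sz]           * (1 - tx) * (1 - ty) * tz +
      v[base + sx + sz]      * tx       * (1 - ty) * tz +
      v[base + sy + sz]      * (1 - tx) * ty       * tz +
      v[base + sx + sy + sz] * tx       * ty       * tz
  }
  voxel_map(array(out, dt), template$voxel_size, template$origin,
            map$nominal_resolution)
}
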