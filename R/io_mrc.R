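# MRC2014 / CCP4 volume reader and writer.
#
# Only orthogonal cells are supported. The 1024-byte header is parsed
# field-by-field; data modes 0 (int8), 1 (int16) and 2 (float32) are read,
# mode 2 is written. Axis order is normalized on read so that the first array
# index always runs along x.

.mrc_header <- function(raw, endian) {
  ints <- function(word, n)
    readBin(raw[(4 * (word - 1) + 1):(4 * (word - 1 + n))], "integer",
            n = n, size = 4, endian = endian)
  flts <- function(word, n)
    readBin(raw[(4 * (word - 1) + 1):(4 * (word - 1 + n))], "double",
            n = n, size = 4, endian = endian)
  list(n = ints(1, 3), mode = ints(4, 1), nstart = ints(5, 3),
       m = ints(8, 3), cella = flts(11, 3), cellb = flts(14, 3),
       mapcrs = ints(17, 3), nsymbt = ints(24, 1), origin = flts(50, 3),
       endian = endian)
}

.mrc_plausible <- function(h) {
  all(is.finite(h$n)) && all(h$n >= 1) && all(h$n <= 100000L) &&
    length(h$mode) == 1L && h$mode %in% 0:2
}

#' Read an MRC/CCP4 density map
#'
#' Parses the 1024-byte MRC2014 header, normalizes axis order to x-fastest,
#' and resolves the grid origin: the ORIGIN header record is used when any of
#' its components is nonzero, otherwise `nstart * voxel_size` (the CCP4
#' convention).
#'
#' @param path path to an MRC/CCP4 file.
#' @param nominal_resolution optional resolution (Angstrom) to attach as
#'   metadata; not stored in the MRC header.
#' @return a [voxel_map].
#' @export
read_density_map <- function(path, nominal_resolution = NA_real_) {
  if (!file.exists(path)) stop("density map file not found: ", path)
  fsize <- file.info(path)$size
  if (is.na(fsize) || fsize < 1024)
    stop("malformed MRC file (header): '", path,
         "' is shorter than the 1024-byte header")
  con <- file(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = 1024L)
  hdr <- .mrc_header(raw_hdr, "little")
  if (!.mrc_plausible(hdr)) {
    hdr <- .mrc_header(raw_hdr, "big")
    if (!.mrc_plausible(hdr))
      stop("malformed MRC header in '", path,
           "': implausible NX/NY/NZ or unsupported MODE field")
  }
  if (!hdr$mode %in% 0:2)
    stop("malformed MRC header in '", path, "': unsupported MODE ", hdr$mode)
  if (any(hdr$m < 1))
    stop("malformed MRC header in '", path, "': MX/MY/MZ must be positive")
  if (any(abs(hdr$cellb - 90) > 1e-3))
    stop("unsupported MRC file '", path, "': non-orthogonal cell (CELLB = ",
         paste(signif(hdr$cellb, 6), collapse = ", "), ")")
  if (!identical(sort(hdr$mapcrs), 1:3))
    stop("malformed MRC header in '", path,
         "': MAPC/MAPR/MAPS is not a permutation of 1,2,3")
  if (any(hdr$nsymbt < 0) || hdr$nsymbt > fsize)
    stop("malformed MRC header in '", path, "': invalid NSYMBT")

  bytes_per <- c(1L, 2L, 4L)[hdr$mode + 1L]
  nvox <- prod(hdr$n)
  need <- 1024 + hdr$nsymbt + nvox * bytes_per
  if (fsize < need)
    stop("malformed MRC file (data block): '", path, "' declares ",
         nvox, " voxels (NX*NY*NZ) but holds only ",
         floor((fsize - 1024 - hdr$nsymbt) / bytes_per), " values")
  if (hdr$nsymbt > 0) invisible(readBin(con, "raw", n = hdr$nsymbt))
  vals <- switch(as.character(hdr$mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1L,
                             signed = TRUE, endian = hdr$endian)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             signed = TRUE, endian = hdr$endian)),
    "2" = readBin(con, "double", n = nvox, size = 4L, endian = hdr$endian))
  if (length(vals) != nvox)
    stop("malformed MRC file (data block): short read in '", path, "'")
  if (!all(is.finite(vals)))
    stop("malformed MRC file '", path, "': non-finite voxel values")

  arr <- array(vals, dim = hdr$n)          # first index = fastest (column) axis
  perm <- match(1:3, hdr$mapcrs)           # dim holding x, y, z respectively
  if (!identical(perm, 1:3)) arr <- aperm(arr, perm)

  voxel <- hdr$cella / hdr$m               # CELLA/M are already in x,y,z order
  if (any(!is.finite(voxel)) || any(voxel <= 0))
    stop("malformed MRC header in '", path, "': CELLA/MX gives invalid voxel size")
  nstart_xyz <- numeric(3)
  nstart_xyz[hdr$mapcrs] <- hdr$nstart     # NSTART follows column/row/section order
  origin <- if (any(hdr$origin != 0)) hdr$origin else nstart_xyz * voxel
  voxel_map(arr, voxel, origin, nominal_resolution)
}

#' Write a map in MRC2014 format
#'
#' Writes mode-2 (float32) little-endian volumes with x as the fastest axis
#' and the physical origin in the ORIGIN header record; files are readable by
#' standard visualization tools.
#'
#' @param map a [voxel_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_map <- function(map, path) {
  if (!is_voxel_map(map)) stop("`map` must be a voxel_map")
  n <- dim(map$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(n); wi(2L)                 # NX NY NZ, MODE
  wi(c(0L, 0L, 0L))             # NXSTART..
  wi(n)                         # MX MY MZ
  wf(n * map$voxel_size)        # CELLA
  wf(c(90, 90, 90))             # CELLB
  wi(1:3)                       # MAPC MAPR MAPS
  wf(c(min(map$data), max(map$data), mean(map$data)))
  wi(c(1L, 0L))                 # ISPG, NSYMBT
  wi(integer(25L))              # EXTRA
  wf(map$origin)                # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(as.vector(map$data)))   # RMS
  wi(0L)                        # NLABL
  writeBin(raw(800L), con)      # labels
  writeBin(as.vector(map$data), con, size = 4L, endian = "little")
  invisible(path)
}
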