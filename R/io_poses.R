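#' Construct a ligand pose
#'
#' One conformation of a ligand in the receptor coordinate frame, optionally
#' tagged with the docking engine that produced it and its engine score.
#'
#' @param atoms data.frame with columns `atom`, `element`, `x`, `y`, `z`.
#' @param pose_id unique pose identifier.
#' @param engine label of the producing engine (e.g. "vina", "chemscore").
#' @param engine_score scalar engine score, `NA` when absent.
#' @param score_orientation `"lower"` or `"higher"` = better; `NA` when no
#'   score is attached.
#' @return an object of class `ligand_pose`.
#' @export
ligand_pose <- function(atoms, pose_id, engine = NA_character_,
                        engine_score = NA_real_,
                        score_orientation = NA_character_) {
  need <- c("atom", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("pose `atoms` missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("pose has no atoms")
  if (!is.na(score_orientation) &&
      !score_orientation %in% c("lower", "higher"))
    stop("`score_orientation` must be \"lower\", \"higher\" or NA")
  atoms$element <- toupper(atoms$element)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms[, need], engine = engine,
                 engine_score = as.numeric(engine_score),
                 score_orientation = score_orientation,
                 pose_id = as.character(pose_id)),
            class = "ligand_pose")
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("ligand_pose '%s' (%s): %d atoms, score %s\n", x$pose_id,
              ifelse(is.na(x$engine), "no engine", x$engine),
              nrow(x$atoms),
              ifelse(is.na(x$engine_score), "NA",
                     format(x$engine_score, digits = 4))))
  invisible(x)
}

pose_coords <- function(p, heavy = TRUE) {
  a <- p$atoms
  if (heavy) a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Centroid of a ligand pose
#'
#' @param p a [ligand_pose].
#' @param heavy restrict to heavy atoms (default).
#' @return numeric length-3 xyz centroid in Angstrom.
#' @export
pose_centroid <- function(p, heavy = TRUE) colMeans(pose_coords(p, heavy))

check_pose_consistency <- function(poses) {
  sig <- vapply(poses, function(p)
    paste(sort(p$atoms$element), collapse = ","), character(1))
  nat <- vapply(poses, function(p) nrow(p$atoms), integer(1))
  if (length(unique(sig)) > 1L || length(unique(nat)) > 1L) {
    ref <- names(which.max(table(sig)))
    bad <- vapply(poses, function(p) p$pose_id, character(1))[sig != ref]
    stop("inconsistency error: poses differ in atom count or element ",
         "composition (offending pose ids: ",
         paste(bad, collapse = ", "), ")")
  }
  invisible(TRUE)
}

# ---- multi-model PDB ----

.parse_pdb_coord_line <- function(lines) {
  data.frame(
    atom = trimws(substr(lines, 13, 16)),
    element = trimws(substr(lines, 77, 78)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    stringsAsFactors = FALSE)
}

.finish_elements <- function(at, path) {
  bad <- !(toupper(at$element) %in% names(.ELEMENT_Z))
  if (any(bad)) {
    guessed <- guess_element(at$atom[bad])
    if (anyNA(guessed))
      stop("could not infer element for atom name(s) in '", path, "': ",
           paste(unique(at$atom[bad][is.na(guessed)]), collapse = ", "))
    at$element[bad] <- guessed
  }
  at$element <- toupper(at$element)
  at
}

.read_poses_pdb_like <- function(path, engine, orientation, score_regex,
                                 default_orientation) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    blocks <- list(lines)
    ids <- "pose_1"
  } else {
    ends <- c(starts[-1] - 1L, length(lines))
    blocks <- Map(function(s, e) lines[s:e], starts, ends)
    ids <- vapply(seq_along(starts), function(i) {
      tok <- suppressWarnings(as.integer(strsplit(trimws(lines[starts[i]]),
                                                  "\\s+")[[1]][2]))
      if (is.na(tok)) sprintf("pose_%d", i) else sprintf("pose_%d", tok)
    }, character(1))
  }
  poses <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    blk <- blocks[[i]]
    coord <- blk[grepl("^(ATOM  |HETATM)", blk)]
    if (length(coord) == 0L)
      stop("no ATOM/HETATM records in pose block ", ids[i], " of '", path, "'")
    at <- .finish_elements(.parse_pdb_coord_line(coord), path)
    score <- NA_real_
    orient <- NA_character_
    eng <- engine
    sc_line <- grep(score_regex, blk, value = TRUE)
    if (length(sc_line)) {
      rem <- sub(score_regex, "", sc_line[1])
      nums <- regmatches(rem,
                         gregexpr("-?[0-9]+\\.?[0-9]*([eE]-?[0-9]+)?",
                                  rem))[[1]]
      if (length(nums)) {
        score <- as.numeric(nums[1])
        or_m <- regmatches(sc_line[1],
                           regexpr("ORIENT +(lower|higher)", sc_line[1]))
        orient <- orientation %||%
          (if (length(or_m)) sub("ORIENT +", "", or_m) else default_orientation)
      }
      eng_m <- regmatches(sc_line[1], regexpr("ENGINE +[^ ]+", sc_line[1]))
      if (length(eng_m) && is.na(eng)) eng <- sub("ENGINE +", "", eng_m)
    }
    poses[[i]] <- ligand_pose(at, pose_id = ids[i], engine = eng,
                              engine_score = score,
                              score_orientation = orient)
  }
  poses
}

# ---- SDF (via ChemmineR) ----

.KNOWN_SDF_SCORE_FIELDS <- c(
  "SCORE", "Score", "score", "Gold.Chemscore.Fitness",
  "Gold.Goldscore.Fitness", "Gold.PLP.Fitness", "Gold.Score",
  "minimizedAffinity", "docking_score")

.read_poses_sdf <- function(path, engine, orientation, score_field) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF pose sets requires the ChemmineR package")
  sdf <- suppressWarnings(suppressMessages(ChemmineR::read.SDFset(path)))
  n <- length(sdf)
  if (n == 0L) stop("no molecules found in SDF file '", path, "'")
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    one <- sdf[[i]]
    ab <- ChemmineR::atomblock(one)
    elem <- toupper(sub("_.*$", "", rownames(ab)))
    at <- data.frame(
      atom = paste0(elem, seq_along(elem)),
      element = elem, x = ab[, 1], y = ab[, 2], z = ab[, 3],
      stringsAsFactors = FALSE)
    at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
    db <- tryCatch(ChemmineR::datablock(one), error = function(e) character())
    fields <- if (is.null(score_field)) .KNOWN_SDF_SCORE_FIELDS else score_field
    hit <- fields[fields %in% names(db)]
    score <- if (length(hit)) suppressWarnings(as.numeric(db[[hit[1]]])) else NA_real_
    hdr <- tryCatch(ChemmineR::header(one)[["Molecule_Name"]],
                    error = function(e) "")
    id <- if (!is.null(hdr) && nzchar(trimws(hdr))) trimws(hdr)
          else sprintf("pose_%d", i)
    poses[[i]] <- ligand_pose(
      at, pose_id = id, engine = engine, engine_score = score,
      score_orientation = if (is.na(score)) NA_character_
                          else (orientation %||% "higher"))
  }
  poses
}

#' Read a set of ligand poses
#'
#' Parses all conformers of one ligand species from a multi-model PDB, a
#' PDBQT (AutoDock Vina dialect: coordinates plus the `REMARK VINA RESULT`
#' score; charges and atom types are ignored), or an SDF file. Engine scores
#' are attached when the dialect carries them, together with their
#' orientation ("lower" is better for Vina, "higher" for GOLD-style fitness
#' scores).
#'
#' @param path input file.
#' @param dialect one of `"auto"`, `"pdb"`, `"pdbqt"`, `"sdf"`; `"auto"`
#'   decides from the file extension.
#' @param engine engine label to attach to every pose (default: parsed from
#'   the file where possible, else `NA`).
#' @param score_orientation override the dialect's default orientation.
#' @param score_field for SDF input, the data field holding the score; by
#'   default a list of common engine field names is tried.
#' @return list of [ligand_pose] objects, in file order.
#' @export
read_pose_set <- function(path, dialect = c("auto", "pdb", "pdbqt", "sdf"),
                          engine = NA_character_, score_orientation = NULL,
                          score_field = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pose file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, pdbqt = "pdbqt", sdf = "sdf", sd = "sdf", "pdb")
  }
  poses <- switch(dialect,
    pdb = .read_poses_pdb_like(path, engine, score_orientation,
                               score_regex = "^REMARK +\\d* *CRYODOCK SCORE",
                               default_orientation = "higher"),
    pdbqt = .read_poses_pdb_like(path, engine, score_orientation,
                                 score_regex = "^REMARK VINA RESULT:",
                                 default_orientation = "lower"),
    sdf = .read_poses_sdf(path, engine, score_orientation, score_field))
  check_pose_consistency(poses)
  poses
}

#' Write a pose set as a multi-model PDB file
#'
#' Each pose becomes one MODEL block of HETATM records; engine scores are
#' preserved in `REMARK 3 CRYODOCK SCORE` lines so that
#' `read_pose_set(..., dialect = "pdb")` round-trips them.
#'
#' @param poses list of [ligand_pose] objects.
#' @param path output path.
#' @param resname residue name for the ligand records.
#' @return `path`, invisibly.
#' @export
write_pose_set <- function(poses, path, resname = "LIG") {
  out <- character()
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    out <- c(out, sprintf("MODEL     %4d", i))
    if (!is.na(p$engine_score))
      out <- c(out, sprintf(
        "REMARK   3 CRYODOCK SCORE %.6f ORIENT %s ENGINE %s",
        p$engine_score, p$score_orientation %||% "higher",
        ifelse(is.na(p$engine), "unknown", p$engine)))
    a <- p$atoms
    out <- c(out, vapply(seq_len(nrow(a)), function(j)
      .pdb_atom_line(j, a$atom[j], resname, "X", 1L, a$x[j], a$y[j], a$z[j],
                     1, 0, a$element[j], hetatm = TRUE), character(1)),
      "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
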