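#' Construct an atomic model
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z`, `occupancy`, `b`.
#' @param source_id free-text provenance label (e.g. a PDB accession or file
#'   name).
#' @return an object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, source_id = "model") {
  need <- c("chain", "resno", "resname", "atom", "element",
            "x", "y", "z", "occupancy", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("`atoms` is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty-model error: no atoms")
  bad <- is.na(atoms$element) | !(toupper(atoms$element) %in% names(.ELEMENT_Z))
  if (any(bad))
    stop("unrecognized element(s) in model: ",
         paste(unique(atoms$element[bad]), collapse = ", "))
  atoms$element <- toupper(atoms$element)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms[, need], source_id = source_id),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model '%s': %d atoms, %d chain(s), %d residue(s)\n",
              x$source_id, nrow(x$atoms), length(unique(x$atoms$chain)),
              nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

# Generic coordinate-table accessor shared by models and ligand poses.
as_atom_table <- function(x) UseMethod("as_atom_table")

#' @export
as_atom_table.atomic_model <- function(x) x$atoms

#' @export
as_atom_table.ligand_pose <- function(x) {
  data.frame(atom = x$atoms$atom, element = x$atoms$element,
             x = x$atoms$x, y = x$atoms$y, z = x$atoms$z,
             stringsAsFactors = FALSE)
}

#' Read an atomic model from a PDB file
#'
#' ATOM and HETATM records are parsed (via bio3d). Alternate locations are
#' resolved by keeping the highest-occupancy altloc of each atom, first in
#' file on ties. Elements come from columns 77-78 when present; otherwise they
#' are inferred from the atom name (see [guess_element]) with a warning.
#'
#' @param path path to a PDB file.
#' @param source_id provenance label; defaults to the file name.
#' @return an [atomic_model].
#' @export
read_model <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) stop("model file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                                   rm.alt = FALSE)),
                  error = function(e)
                    stop("empty-model error: could not parse any atoms from '",
                         path, "' (", conditionMessage(e), ")"))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("empty-model error: no ATOM/HETATM records in '", path, "'")

  # altloc resolution: highest occupancy wins, ties -> first in file
  at$occupancy <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -at$occupancy,
               seq_len(nrow(at)))
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), ]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r"), key)), ]

  elem <- toupper(trimws(at$elesy))
  known <- !is.na(elem) & elem %in% names(.ELEMENT_Z)
  if (!all(known)) {
    guessed <- guess_element(at$elety[!known])
    if (anyNA(guessed))
      stop("could not infer element for atom name(s): ",
           paste(unique(at$elety[!known][is.na(guessed)]), collapse = ", "))
    warning(sum(!known), " atom(s) in '", path,
            "' lacked a recognized element column; inferred from atom names")
    elem[!known] <- guessed
  }
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  atomic_model(data.frame(
    chain = chain, resno = at$resno, resname = trimws(at$resid),
    atom = trimws(at$elety), element = elem,
    x = at$x, y = at$y, z = at$z,
    occupancy = at$occupancy, b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE), source_id = source_id)
}

.pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                           occ, b, element, hetatm = FALSE) {
  nm <- if (nchar(name) < 4L && nchar(element) == 1L)
    sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (hetatm) "HETATM" else "ATOM", serial %% 100000L, nm,
          substr(resname, 1, 3), substr(chain, 1, 1), resno %% 10000L,
          x, y, z, occ, b, element)
}

#' Write an atomic model as PDB
#'
#' @param model an [atomic_model].
#' @param path output path.
#' @param hetatm write HETATM instead of ATOM records.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, hetatm = FALSE) {
  a <- model$atoms
  lines <- vapply(seq_len(nrow(a)), function(i)
    .pdb_atom_line(i, a$atom[i], a$resname[i], a$chain[i], a$resno[i],
                   a$x[i], a$y[i], a$z[i], a$occupancy[i], a$b[i],
                   a$element[i], hetatm = hetatm), character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
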