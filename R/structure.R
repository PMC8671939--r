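# Coordinate-file handling: a light structure model over an atom table,
# PDB reading via bio3d and a minimal mmCIF _atom_site reader, altloc
# resolution, atom selection and distance measurement.

#' Build a structure model from an atom table
#'
#' The model is an atom data frame plus an identifier.  Required columns:
#' `chain`, `resno` (author numbering), `insert`, `resid` (3-letter
#' residue name), `elety` (atom name), `element`, `x`, `y`, `z` (Angstrom),
#' `occ`, `altloc`, `het` (logical, HETATM record).  Waters are ordinary
#' `HOH` heteroatoms.
#'
#' @param atoms Atom data frame.
#' @param identifier Model label.
#' @return Object of class `"structure_model"`.
#' @export
structure_model <- function(atoms, identifier = "model") {
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z", "occ", "altloc", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop("atom table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table", call. = FALSE)
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(identifier = identifier, atoms = atoms),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure_model '%s': %d atoms, %d residues, chains %s (%d het atoms)\n",
              x$identifier, nrow(a),
              nrow(unique(a[, c("chain", "resno", "insert")])),
              paste(sort(unique(a$chain)), collapse = ","), sum(a$het)))
  invisible(x)
}

# keep one conformer per (residue, atom name): highest occupancy, ties -> "A"
# (or first in file order)
.resolve_altlocs <- function(atoms) {
  if (all(atoms$altloc %in% c("", " "))) return(atoms)
  idx <- seq_len(nrow(atoms))
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  pref <- order(key,
                -atoms$occ,
                atoms$altloc != "A",  # FALSE (i.e. "A") sorts first
                atoms$altloc,
                idx)
  keep_idx <- idx[pref][!duplicated(key[pref])]
  atoms[sort(keep_idx), , drop = FALSE]
}

.element_from_name <- function(elety) {
  lead <- sub("^[0-9']*", "", elety)
  two <- toupper(substr(lead, 1, 2))
  one <- toupper(substr(lead, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA") &
           nchar(lead) == 2, two, one)
}

#' Read a coordinate file
#'
#' Reads PDB (via bio3d) or mmCIF (`_atom_site` loop) into a
#' [structure_model()].  Author residue numbering and insertion codes are
#' preserved; waters and ligands are kept; alternate locations are
#' resolved to the highest-occupancy conformer (ties prefer altloc "A").
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param identifier Model label; defaults to the file stem.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           identifier = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  if (is.null(identifier)) {
    identifier <- sub("\\.[^.]*$", "", basename(path))
  }
  atoms <- if (format == "pdb") .read_pdb_atoms(path) else
    .read_cif_atoms(path)
  atoms <- .resolve_altlocs(atoms)
  structure_model(atoms, identifier)
}

.read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e)
                    stop(sprintf("PDB parse error in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  a <- pdb$atom
  elem <- a$elesy
  bad <- is.na(elem) | trimws(elem) == ""
  elem[bad] <- .element_from_name(a$elety[bad])
  data.frame(chain = ifelse(is.na(a$chain), "A", a$chain),
             resno = a$resno,
             insert = ifelse(is.na(a$insert), "", a$insert),
             resid = a$resid, elety = a$elety,
             element = toupper(trimws(elem)),
             x = a$x, y = a$y, z = a$z,
             occ = ifelse(is.na(a$o), 1, a$o),
             altloc = ifelse(is.na(a$alt), "", a$alt),
             het = a$type == "HETATM", stringsAsFactors = FALSE)
}

# Minimal mmCIF reader restricted to the _atom_site loop, which is all the
# geometry code needs.  Handles quoted values; does not handle multi-line
# semicolon text fields inside _atom_site (they do not occur there).
.read_cif_atoms <- function(path) {
  lines <- readLines(path)
  tags_idx <- grep("^_atom_site\\.", lines)
  if (length(tags_idx) == 0L) {
    stop(sprintf("mmCIF parse error in '%s': no _atom_site loop found", path),
         call. = FALSE)
  }
  tags <- sub("^_atom_site\\.", "", trimws(lines[tags_idx]))
  start <- max(tags_idx) + 1L
  rows <- list()
  for (i in start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" ) next
    if (grepl("^(#|loop_|_|data_)", ln)) break
    toks <- .cif_tokens(ln)
    if (length(toks) != length(tags)) {
      stop(sprintf("mmCIF parse error in '%s' at line %d: %d values for %d tags",
                   path, i, length(toks), length(tags)), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- toks
  }
  if (length(rows) == 0L) {
    stop(sprintf("mmCIF parse error in '%s': empty _atom_site loop", path),
         call. = FALSE)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  get <- function(name, default = NA_character_) {
    if (name %in% tags) return(m[, name])
    if (length(default) > 1L) default else rep(default, nrow(m))
  }
  dot_na <- function(x) ifelse(x %in% c(".", "?"), NA_character_, x)
  resno <- suppressWarnings(as.integer(dot_na(get("auth_seq_id",
                                                  get("label_seq_id")))))
  data.frame(
    chain = ifelse(is.na(dot_na(get("auth_asym_id", get("label_asym_id")))),
                   "A", dot_na(get("auth_asym_id", get("label_asym_id")))),
    resno = resno,
    insert = ifelse(is.na(dot_na(get("pdbx_PDB_ins_code"))), "",
                    dot_na(get("pdbx_PDB_ins_code"))),
    resid = get("auth_comp_id", get("label_comp_id")),
    elety = get("auth_atom_id", get("label_atom_id")),
    element = toupper(ifelse(is.na(dot_na(get("type_symbol"))),
                             .element_from_name(get("auth_atom_id",
                                                    get("label_atom_id"))),
                             dot_na(get("type_symbol")))),
    x = as.numeric(get("Cartn_x")), y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    occ = ifelse(is.na(suppressWarnings(as.numeric(dot_na(get("occupancy"))))),
                 1, suppressWarnings(as.numeric(dot_na(get("occupancy"))))),
    altloc = ifelse(is.na(dot_na(get("label_alt_id"))), "",
                    dot_na(get("label_alt_id"))),
    het = get("group_PDB", "ATOM") == "HETATM",
    stringsAsFactors = FALSE)
}

.cif_tokens <- function(line) {
  toks <- character(0)
  rest <- line
  while (nchar(rest) > 0) {
    rest <- sub("^[[:space:]]+", "", rest)
    if (nchar(rest) == 0) break
    first <- substr(rest, 1, 1)
    if (first %in% c("'", '"')) {
      m <- regexpr(paste0("^", first, "([^", first, "]*)", first), rest)
      val <- sub(paste0("^", first, "([^", first, "]*)", first, ".*$"),
                 "\\1", rest)
      toks <- c(toks, val)
      rest <- substr(rest, attr(m, "match.length") + 1L, nchar(rest))
    } else {
      val <- sub("[[:space:]].*$", "", rest)
      toks <- c(toks, val)
      rest <- substr(rest, nchar(val) + 1L, nchar(rest))
    }
  }
  toks
}

#' Write a structure model as PDB
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = ifelse(a$het, "HETATM",
                                                         "ATOM"),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = a$chain, insert = a$insert,
                   o = rep_len(a$occ, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Select atoms from a model
#'
#' All filters are optional and combine with AND.
#'
#' @param model A `structure_model`.
#' @param chain,resno,resid,elety,element Vectors of accepted values.
#' @param het `TRUE`/`FALSE` to restrict to HETATM/ATOM records.
#' @return Atom data frame subset.
#' @export
get_atoms <- function(model, chain = NULL, resno = NULL, resid = NULL,
                      elety = NULL, element = NULL, het = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(het)) keep <- keep & a$het == het
  a[keep, , drop = FALSE]
}

# resolve an atom reference "chain:resno:atom" or "resno:atom" to one row
.resolve_atom <- function(model, ref) {
  parts <- strsplit(ref, ":")[[1]]
  a <- if (length(parts) == 3L) {
    get_atoms(model, chain = parts[1], resno = as.integer(parts[2]),
              elety = parts[3])
  } else if (length(parts) == 2L) {
    get_atoms(model, resno = as.integer(parts[1]), elety = parts[2])
  } else {
    stop(sprintf("atom reference '%s' not in 'chain:resno:atom' or 'resno:atom' form",
                 ref), call. = FALSE)
  }
  if (nrow(a) == 0L) {
    resno <- as.integer(parts[length(parts) - 1L])
    cand <- get_atoms(model, resno = resno)
    stop(sprintf("atom '%s' not found; atoms at residue %d: %s", ref, resno,
                 if (nrow(cand)) paste(cand$elety, collapse = ", ")
                 else "(no such residue)"), call. = FALSE)
  }
  if (nrow(a) > 1L) {
    stop(sprintf("atom reference '%s' is ambiguous (%d matches; add a chain)",
                 ref, nrow(a)), call. = FALSE)
  }
  a
}

#' Distance between two referenced atoms
#'
#' @param model A `structure_model`.
#' @param ref_a,ref_b Atom references, `"chain:resno:atom"` or
#'   `"resno:atom"`.
#' @return Euclidean distance in Angstrom.
#' @export
measure_distance <- function(model, ref_a, ref_b) {
  a <- .resolve_atom(model, ref_a)
  b <- .resolve_atom(model, ref_b)
  sqrt(sum((c(a$x, a$y, a$z) - c(b$x, b$y, b$z))^2))
}
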