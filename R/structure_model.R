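# Atomic model: parsing, the zinc-relevant residue/atom dictionary, and
# binding-point computation.  Structures are stored as a flat atom table plus
# a het-ion table; residues are materialised on demand.

#' Residue types and side-chain atoms that mediate zinc coordination
#'
#' Maps each of the eight zinc-coordinating residue types to the side-chain
#' atom name(s) through which the ion is bound.  His, Asp and Glu list two
#' candidate atoms; the remaining types one.
#'
#' @return Named list of character vectors (atom names per residue type).
#' @export
binding_atom_dictionary <- function() {
  list(
    HIS = c("ND1", "NE2"),
    CYS = "SG",
    ASP = c("OD1", "OD2"),
    GLU = c("OE1", "OE2"),
    ASN = "OD1",
    SER = "OG",
    THR = "OG1",
    TYR = "OH"
  )
}

# Element symbols treated as bindable metal het-ions when seen as HETATM.
METAL_ELEMENTS <- c("ZN", "CO", "CU", "FE", "MN", "NI", "CA", "MG", "NA", "K",
                    "CD", "HG")

.empty_atom_table <- function() {
  data.frame(
    chain = character(), seq_id = integer(), icode = character(),
    res_type = character(), atom = character(), element = character(),
    x = double(), y = double(), z = double(),
    occ = double(), altloc = character(), bfactor = double(),
    stringsAsFactors = FALSE
  )
}

.empty_het_table <- function() {
  data.frame(element = character(), x = double(), y = double(), z = double(),
             occ = double(), stringsAsFactors = FALSE)
}

new_protein_structure <- function(structure_id, atoms, het_ions) {
  structure(list(structure_id = structure_id, atoms = atoms,
                 het_ions = het_ions),
            class = "ProteinStructure")
}

#' @export
print.ProteinStructure <- function(x, ...) {
  cat(sprintf("<ProteinStructure %s: %d atoms, %d residues, %d het ions>\n",
              x$structure_id, nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "seq_id", "icode")])),
              nrow(x$het_ions)))
  invisible(x)
}

.residue_key <- function(chain, seq_id, icode) {
  paste(chain, seq_id, icode, sep = ":")
}

#' Parse a protein structure file
#'
#' Reads a PDB or mmCIF coordinate file into the internal atomic model.
#' Only the first model of multi-model files is kept; hydrogens are dropped;
#' alternate locations are resolved to the highest-occupancy conformer
#' (ties to altloc 'A'); missing occupancies default to 1.0.  Metal
#' heteroatoms (Zn and the other common di-/monovalent metals) are collected
#' into the `het_ions` table.
#'
#' @param source Path to a file, or a character vector of file lines.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`.
#' @param structure_id Identifier stored on the structure; defaults to the
#'   file base name.
#' @return A `ProteinStructure`: list with `structure_id`, `atoms`
#'   (data frame with chain, seq_id, icode, res_type, atom, element, x, y, z,
#'   occ, altloc, bfactor) and `het_ions` (element, x, y, z, occ).
#' @export
parse_structure <- function(source, format = c("auto", "pdb", "mmcif"),
                            structure_id = NULL) {
  format <- match.arg(format)
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(structure_id)) {
      structure_id <- sub("\\.(pdb|ent|cif|mmcif)$", "",
                          basename(source), ignore.case = TRUE)
    }
    if (format == "auto") {
      format <- if (grepl("\\.(cif|mmcif)$", source, ignore.case = TRUE))
        "mmcif" else "pdb"
    }
  } else {
    lines <- if (length(source) == 1L) strsplit(source, "\n")[[1]] else source
    if (is.null(structure_id)) structure_id <- "structure"
  }
  if (format == "auto") {
    format <- if (any(grepl("^_atom_site\\.", lines))) "mmcif" else "pdb"
  }
  parsed <- switch(format,
    pdb = .parse_pdb_lines(lines),
    mmcif = .parse_mmcif_lines(lines)
  )
  atoms <- .resolve_altlocs(parsed$atoms)
  if (nrow(atoms) == 0L && nrow(parsed$het) == 0L) {
    stop("empty structure: no atom records found in '", structure_id, "'")
  }
  new_protein_structure(structure_id, atoms, parsed$het)
}

.parse_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  # first model only
  endmdl <- which(rec == "ENDMDL")
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- substr(lines, 1, 6)
  sel <- rec == "ATOM  " | rec == "HETATM"
  lines <- lines[sel]
  rec <- rec[sel]
  if (length(lines) == 0L) {
    return(list(atoms = .empty_atom_table(), het = .empty_het_table()))
  }
  num <- function(s, default = NA_real_) {
    v <- suppressWarnings(as.numeric(s))
    v[is.na(v)] <- default
    v
  }
  atom <- trimws(substr(lines, 13, 16))
  altloc <- trimws(substr(lines, 17, 17))
  res_type <- toupper(trimws(substr(lines, 18, 20)))
  chain <- trimws(substr(lines, 22, 22))
  seq_id <- suppressWarnings(as.integer(trimws(substr(lines, 23, 26))))
  icode <- trimws(substr(lines, 27, 27))
  x <- num(substr(lines, 31, 38))
  y <- num(substr(lines, 39, 46))
  z <- num(substr(lines, 47, 54))
  occ <- num(substr(lines, 55, 60), default = 1.0)
  occ[!is.finite(occ)] <- 1.0
  bf <- num(substr(lines, 61, 66), default = 0.0)
  element <- toupper(trimws(substr(lines, 77, 78)))
  element[element == ""] <- toupper(substr(atom[element == ""], 1, 1))
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(seq_id)
  if (any(bad)) {
    stop("unparseable coordinate record: ",
         lines[which(bad)[1]])
  }
  df <- data.frame(chain = chain, seq_id = seq_id, icode = icode,
                   res_type = res_type, atom = atom, element = element,
                   x = x, y = y, z = z, occ = occ, altloc = altloc,
                   bfactor = bf, stringsAsFactors = FALSE)
  .split_het(df, rec == "HETATM")
}

# Minimal mmCIF reader: extracts the atom_site loop.
.parse_mmcif_lines <- function(lines) {
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0L) stop("mmCIF parse error: no _atom_site loop")
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1L
  body <- character()
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "data_")) break
    body <- c(body, ln)
  }
  if (length(body) == 0L) stop("mmCIF parse error: empty _atom_site loop")
  toks <- strsplit(body, "[[:space:]]+")
  nf <- length(fields)
  ok <- vapply(toks, length, 1L) == nf
  if (!all(ok)) {
    stop("mmCIF parse error: malformed atom_site row: ", body[which(!ok)[1]])
  }
  m <- do.call(rbind, toks)
  colnames(m) <- fields
  get <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% fields) return(m[, nm])
    if (!is.null(alt) && alt %in% fields) return(m[, alt])
    rep(default, nrow(m))
  }
  q <- function(v) gsub('^"|"$', "", v)  # strip quoting on atom names
  model_num <- get("pdbx_PDB_model_num", default = "1")
  keep <- model_num == model_num[1]
  grp <- get("group_PDB", default = "ATOM")
  seq_auth <- get("auth_seq_id", alt = "label_seq_id")
  df <- data.frame(
    chain = get("auth_asym_id", alt = "label_asym_id", default = "A"),
    seq_id = suppressWarnings(as.integer(seq_auth)),
    icode = ifelse(get("pdbx_PDB_ins_code", default = "?") %in% c("?", "."),
                   "", get("pdbx_PDB_ins_code", default = "?")),
    res_type = toupper(get("auth_comp_id", alt = "label_comp_id")),
    atom = q(get("auth_atom_id", alt = "label_atom_id")),
    element = toupper(get("type_symbol", default = "")),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    occ = suppressWarnings(as.numeric(get("occupancy", default = "1"))),
    altloc = ifelse(get("label_alt_id", default = ".") %in% c(".", "?"),
                    "", get("label_alt_id", default = ".")),
    bfactor = suppressWarnings(
      as.numeric(get("B_iso_or_equiv", default = "0"))),
    stringsAsFactors = FALSE
  )
  df <- df[keep, , drop = FALSE]
  grp <- grp[keep]
  df$occ[!is.finite(df$occ)] <- 1.0
  df$bfactor[!is.finite(df$bfactor)] <- 0.0
  df$seq_id[is.na(df$seq_id)] <- 0L
  .split_het(df, grp == "HETATM")
}

# Drop hydrogens, then split metal HETATMs into the het-ion table.
.split_het <- function(df, is_het) {
  keep <- df$element != "H" & df$element != "D"
  df <- df[keep, , drop = FALSE]
  is_het <- is_het[keep]
  metal <- is_het & (df$element %in% METAL_ELEMENTS |
                       df$res_type %in% METAL_ELEMENTS)
  het <- data.frame(element = ifelse(df$element[metal] %in% METAL_ELEMENTS,
                                     df$element[metal], df$res_type[metal]),
                    x = df$x[metal], y = df$y[metal], z = df$z[metal],
                    occ = df$occ[metal], stringsAsFactors = FALSE)
  atoms <- df[!is_het, , drop = FALSE]
  rownames(atoms) <- NULL
  list(atoms = atoms, het = het)
}

# Altloc resolution: per (residue, atom name) keep the conformer with the
# highest occupancy; ties go to the lexicographically first altloc label,
# with '' (no altloc) and 'A' ranking first.
.resolve_altlocs <- function(atoms) {
  if (nrow(atoms) == 0L) return(atoms)
  key <- paste(atoms$chain, atoms$seq_id, atoms$icode, atoms$atom, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  key <- key[ord]
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  # restore file order
  atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' List residues of a structure
#'
#' @param structure A `ProteinStructure`.
#' @return List of residue objects: `list(chain, seq_id, icode, res_type,
#'   key, atoms)` where `atoms` is the per-residue atom data frame, in file
#'   order.
#' @export
structure_residues <- function(structure) {
  atoms <- structure$atoms
  if (nrow(atoms) == 0L) return(list())
  key <- .residue_key(atoms$chain, atoms$seq_id, atoms$icode)
  first <- !duplicated(key)
  idx <- split(seq_len(nrow(atoms)), factor(key, levels = key[first]))
  lapply(idx, function(i) {
    a <- atoms[i, , drop = FALSE]
    list(chain = a$chain[1], seq_id = a$seq_id[1], icode = a$icode[1],
         res_type = a$res_type[1],
         key = .residue_key(a$chain[1], a$seq_id[1], a$icode[1]),
         atoms = a)
  })
}

.atom_coord <- function(residue, name) {
  i <- match(name, residue$atoms$atom)
  if (is.na(i)) return(NULL)
  c(residue$atoms$x[i], residue$atoms$y[i], residue$atoms$z[i])
}

#' Binding point of a zinc-coordinating residue
#'
#' The representative coordinate through which a residue is taken to engage
#' the ion: the single listed side-chain atom, or the mean of the two listed
#' atoms (e.g. OE1/OE2 for Glu) when both are present.  Falls back to the
#' one present atom if the other is missing.
#'
#' @param residue Residue object (see [structure_residues()]).
#' @return Numeric length-3 coordinate (Angstrom).
#' @export
binding_point <- function(residue) {
  dict <- binding_atom_dictionary()
  names_i <- dict[[residue$res_type]]
  if (is.null(names_i)) {
    stop("not a zinc-binding residue type: ", residue$res_type)
  }
  coords <- Filter(Negate(is.null), lapply(names_i, .atom_coord,
                                           residue = residue))
  if (length(coords) == 0L) {
    stop("missing binding atom(s) ", paste(names_i, collapse = "/"),
         " in residue ", residue$key)
  }
  if (length(coords) == 1L) coords[[1]] else (coords[[1]] + coords[[2]]) / 2
}

#' Extract the zinc-coordinating residues of a structure
#'
#' Returns all residues (from every chain) whose type is in
#' [binding_atom_dictionary()] and whose binding point is computable.
#'
#' @param structure A `ProteinStructure`.
#' @return List of residue objects with an added `bp` (binding point) and
#'   `ca`/`cb` coordinates (NULL when absent).
#' @export
extract_binding_residues <- function(structure) {
  dict <- binding_atom_dictionary()
  res <- structure_residues(structure)
  out <- list()
  for (r in res) {
    if (!r$res_type %in% names(dict)) next
    bp <- tryCatch(binding_point(r), error = function(e) NULL)
    if (is.null(bp)) next
    r$bp <- bp
    r$ca <- .atom_coord(r, "CA")
    r$cb <- .atom_coord(r, "CB")
    out[[length(out) + 1L]] <- r
  }
  out
}

#' Write a structure as a PDB file
#'
#' Fixed-column PDB writer used for fixtures and round-tripping.  Het ions
#' are written as HETATM records with residue name equal to the element.
#'
#' @param structure A `ProteinStructure`.
#' @param path Output file path.
#' @param remarks Optional character vector written as REMARK records.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, remarks = NULL) {
  a <- structure$atoms
  lines <- character()
  if (!is.null(remarks)) lines <- sprintf("REMARK   3 %s", remarks)
  fmt_atom <- function(serial, name, alt, res, chain, seq, icode,
                       x, y, z, occ, bf, elem, het = FALSE) {
    nm <- if (nchar(name) >= 4L) substr(name, 1, 4) else
      sprintf(" %-3s", name)
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (het) "HETATM" else "ATOM", serial %% 100000L, nm, alt, res,
            chain, seq %% 10000L, ifelse(icode == "", " ", icode),
            x, y, z, occ, bf, elem)
  }
  serial <- 0L
  if (nrow(a) > 0L) {
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      lines <- c(lines, fmt_atom(serial, a$atom[i], " ", a$res_type[i],
                                 a$chain[i], a$seq_id[i], a$icode[i],
                                 a$x[i], a$y[i], a$z[i], a$occ[i],
                                 a$bfactor[i], a$element[i]))
    }
  }
  h <- structure$het_ions
  if (nrow(h) > 0L) {
    for (i in seq_len(nrow(h))) {
      serial <- serial + 1L
      lines <- c(lines, fmt_atom(serial, h$element[i], " ", h$element[i],
                                 "Z", 900L + i, "", h$x[i], h$y[i], h$z[i],
                                 h$occ[i], 0, h$element[i], het = TRUE))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}
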