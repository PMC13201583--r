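#' @importFrom utils read.table write.table
NULL

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
DNA_CODES <- c("DA", "DC", "DG", "DT")

#' Read an atomic coordinate model
#'
#' Parses a PDB or mmCIF (PDBx) coordinate file into a `StructureModel`:
#' a flat atom table with author chain identifiers, author residue numbers,
#' residue and atom names and Cartesian coordinates in Angstrom.  For
#' multi-model (NMR-style) files only the first model is kept, with a
#' warning.  Alternate locations are reduced to the highest-occupancy
#' conformer (first in file on ties); insertion codes are rejected.
#'
#' @param path file path.
#' @param format one of "auto" (by extension), "pdb", "cif".
#' @param id model identifier; defaults to the file base name.
#' @return a `StructureModel` with fields `id`, `source_format` and `atoms`
#'   (data.frame: chain, resno, resid, elety, x, y, z, het).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "cif" else "pdb"
  }
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  atoms <- if (format == "cif") parse_cif_atoms(path) else parse_pdb_atoms(path)
  if (nrow(atoms) == 0L) stop("read_structure: empty model in ", path)
  atoms <- resolve_altloc(atoms)
  new_structure_model(id, atoms, format)
}

new_structure_model <- function(id, atoms, source_format) {
  rownames(atoms) <- NULL
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("StructureModel: duplicate (chain, residue, atom) triple: ",
         key[duplicated(key)][1])
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("StructureModel: non-finite coordinates")
  structure(list(id = id, atoms = atoms, source_format = source_format),
            class = "StructureModel")
}

parse_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("read_structure: cannot parse PDB file ", path,
                             ": ", conditionMessage(e)))
  n_models <- max(1L, length(grep("^MODEL ", readLines(path, warn = FALSE))))
  if (n_models > 1L)
    warning("read_structure: ", n_models,
            " models present; using the first model")
  a <- pdb$atom
  if (any(nzchar(trimws(a$insert)) & !is.na(a$insert)))
    stop("read_structure: insertion codes are not supported")
  data.frame(chain = as.character(a$chain), resno = as.integer(a$resno),
             resid = as.character(a$resid), elety = as.character(a$elety),
             x = a$x, y = a$y, z = a$z,
             het = a$type == "HETATM",
             o = ifelse(is.na(a$o), 1, a$o),
             alt = ifelse(is.na(a$alt), "", a$alt),
             stringsAsFactors = FALSE)
}

# Focused PDBx/mmCIF reader: extracts the atom_site loop by header name so
# column order in the file is irrelevant.
parse_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  start <- grep("^\\s*_atom_site\\.", lines)
  if (length(start) == 0L)
    stop("read_structure: no _atom_site category in ", path)
  hdr_idx <- start[cumsum(c(TRUE, diff(start) != 1L)) == 1L]
  headers <- sub("^\\s*_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1L
  body <- character(0)
  for (i in seq(body_start, length(lines))) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(#|loop_|_|data_)", ln)) break
    body <- c(body, ln)
  }
  if (length(body) == 0L)
    stop("read_structure: empty atom_site loop in ", path)
  fields <- strsplit(body, "\\s+")
  bad <- which(lengths(fields) != length(headers))
  if (length(bad))
    stop("read_structure: malformed atom_site row at data line ", bad[1],
         " of ", path)
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- headers
  need <- c("label_atom_id", "label_comp_id", "Cartn_x", "Cartn_y", "Cartn_z")
  miss <- setdiff(need, headers)
  if (length(miss))
    stop("read_structure: atom_site loop lacks required items: ",
         paste(miss, collapse = ", "))
  pick <- function(a, b) if (a %in% headers) tab[[a]] else tab[[b]]
  chain <- pick("auth_asym_id", "label_asym_id")
  resno <- pick("auth_seq_id", "label_seq_id")
  if (is.null(chain) || is.null(resno))
    stop("read_structure: atom_site loop lacks chain/residue numbering")
  if ("pdbx_PDB_model_num" %in% headers) {
    models <- unique(tab$pdbx_PDB_model_num)
    if (length(models) > 1L) {
      warning("read_structure: ", length(models),
              " models present; using the first model")
      keep <- tab$pdbx_PDB_model_num == models[1]
      tab <- tab[keep, , drop = FALSE]
      chain <- chain[keep]; resno <- resno[keep]
    }
  }
  if ("pdbx_PDB_ins_code" %in% headers &&
      any(!tab$pdbx_PDB_ins_code %in% c("?", ".", "")))
    stop("read_structure: insertion codes are not supported")
  alt <- if ("label_alt_id" %in% headers)
    ifelse(tab$label_alt_id %in% c(".", "?"), "", tab$label_alt_id) else ""
  occ <- if ("occupancy" %in% headers)
    suppressWarnings(as.numeric(tab$occupancy)) else 1
  occ[is.na(occ)] <- 1
  xyz <- suppressWarnings(cbind(as.numeric(tab$Cartn_x),
                                as.numeric(tab$Cartn_y),
                                as.numeric(tab$Cartn_z)))
  if (any(!is.finite(xyz)))
    stop("read_structure: non-numeric coordinates in atom_site loop of ",
         path)
  group <- if ("group_PDB" %in% headers) tab$group_PDB else "ATOM"
  data.frame(chain = as.character(chain),
             resno = suppressWarnings(as.integer(resno)),
             resid = gsub('"', "", tab$label_comp_id),
             elety = gsub('"', "", tab$label_atom_id),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             het = group == "HETATM", o = occ, alt = alt,
             stringsAsFactors = FALSE)
}

resolve_altloc <- function(atoms) {
  if (!"alt" %in% names(atoms)) return(atoms)
  if (any(nzchar(atoms$alt))) {
    key <- paste(atoms$chain, atoms$resno, atoms$elety)
    ord <- order(factor(key, levels = unique(key)), -atoms$o,
                 seq_len(nrow(atoms)))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$elety)), ,
                   drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  atoms$o <- NULL
  atoms$alt <- NULL
  rownames(atoms) <- NULL
  atoms
}

#' Write a StructureModel as mmCIF
#'
#' Emits a standard-ordered `atom_site` loop (PDBx).  Output is byte
#' deterministic for identical models.
#'
#' @param model a `StructureModel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(model, path) {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms
  hdr <- c(paste0("data_", gsub("[^A-Za-z0-9_-]", "_", model$id)),
           "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_asym_id",
                    "pdbx_PDB_model_num")))
  elem <- substr(gsub("[^A-Za-z].*$", "", a$elety), 1L, 1L)
  rows <- sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s 1",
                  ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), elem,
                  a$elety, a$resid, a$chain, a$resno, a$x, a$y, a$z,
                  a$resno, a$chain)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}

#' Chain inventory of a model
#'
#' @param model a `StructureModel`.
#' @return data.frame with `chain`, `n_residues` and `polymer_kind`
#'   ("protein", "dna" or "other"), polymer atoms only.
#' @export
structure_chains <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms[!model$atoms$het, , drop = FALSE]
  chains <- unique(a$chain)
  kind <- vapply(chains, function(ch) {
    res <- unique(a$resid[a$chain == ch])
    if (mean(res %in% STANDARD_AA) >= 0.5) "protein"
    else if (mean(res %in% DNA_CODES) >= 0.5) "dna"
    else "other"
  }, character(1))
  nres <- vapply(chains, function(ch)
    length(unique(a$resno[a$chain == ch])), integer(1))
  data.frame(chain = chains, n_residues = nres, polymer_kind = unname(kind),
             stringsAsFactors = FALSE)
}

#' Look up one atom coordinate
#'
#' @param model a `StructureModel`.
#' @param chain chain identifier.
#' @param resnum author residue number.
#' @param elety atom name (default "CA").
#' @return xyz vector (length 3).
#' @export
get_atom_xyz <- function(model, chain, resnum, elety = "CA") {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms
  in_chain <- a$chain == chain
  if (!any(in_chain))
    stop("get_atom_xyz: chain '", chain, "' absent from model '",
         model$id, "'")
  hit <- in_chain & a$resno == resnum & a$elety == elety
  if (!any(hit)) {
    if (!any(in_chain & a$resno == resnum))
      stop("get_atom_xyz: residue ", resnum, " of chain '", chain,
           "' not modeled (disordered or absent)")
    stop("get_atom_xyz: atom '", elety, "' missing for residue ", resnum,
         " of chain '", chain, "'")
  }
  as.numeric(unlist(a[which(hit)[1], c("x", "y", "z")]))
}

#' C-alpha coordinate of a residue
#'
#' @inheritParams get_atom_xyz
#' @return xyz vector (length 3).
#' @export
get_calpha <- function(model, chain, resnum) {
  get_atom_xyz(model, chain, resnum, "CA")
}

# All CA coordinates of a chain restricted to residue-number intervals.
# ranges: list of c(lo, hi).  Returns matrix with resno rownames.
chain_ca_in_ranges <- function(model, chain, ranges) {
  a <- model$atoms
  want <- sort(unlist(lapply(ranges, function(r) seq(r[1], r[2]))))
  sel <- a$chain == chain & a$elety == "CA" & a$resno %in% want
  m <- as.matrix(a[sel, c("x", "y", "z")])
  rownames(m) <- a$resno[sel]
  m[order(as.integer(rownames(m))), , drop = FALSE]
}

#' Map construct residue numbers to deposited numbers for the chimeric MCM
#'
#' The archaeal construct fuses an Sso N-terminal domain (residues 1-269)
#' to the Pf AAA+ domain (native numbering 257-361 and 729-966, the intein
#' span removed).  Deposited coordinate files keep Sso numbers and offset Pf
#' numbers by +1000 (1257-1361, 1729-1966).
#'
#' @param resnum integer vector of construct (native) residue numbers.
#' @param protein "Sso" or "Pf" (the two native numberings overlap at
#'   257-269, so the caller must state the protein).
#' @return deposited residue numbers (integer vector).
#' @export
map_chimera_numbering <- function(resnum, protein = c("Sso", "Pf")) {
  protein <- match.arg(protein)
  resnum <- as.integer(resnum)
  if (protein == "Sso") {
    bad <- resnum < 1L | resnum > 269L
    if (any(bad))
      stop("map_chimera_numbering: Sso residue outside span 1-269: ",
           resnum[bad][1])
    resnum
  } else {
    bad <- !((resnum >= 257L & resnum <= 361L) |
               (resnum >= 729L & resnum <= 966L))
    if (any(bad))
      stop("map_chimera_numbering: Pf residue outside spans 257-361/729-966: ",
           resnum[bad][1])
    resnum + 1000L
  }
}

#' @export
print.StructureModel <- function(x, ...) {
  ch <- structure_chains(x)
  cat("StructureModel '", x$id, "' (", x$source_format, "): ",
      nrow(x$atoms), " atoms, ", nrow(ch), " chains (",
      paste0(ch$chain, "/", ch$polymer_kind, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}
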