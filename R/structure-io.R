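## Reading, selecting and writing atomic models (PDB v3.3 and mmCIF
## atom_site).  Only the coordinate records are interpreted: no symmetry
## records, no map handling, no geometry validation.

#' Read an atomic model from PDB or mmCIF
#'
#' Parses all ATOM/HETATM records (all models of a multi-model file) into a
#' \linkS4class{StructureModel}.  Coordinates are in Angstrom.  Where a
#' residue has alternate conformers, the highest-occupancy conformer is kept
#' (ties broken by first occurrence) so that downstream geometry is
#' deterministic.
#'
#' @param path file path.
#' @param format "pdb", "cif", or NULL to auto-detect from the extension and,
#'   failing that, the content.
#' @return a \linkS4class{StructureModel}
#' @export
readStructure <- function(path, format = NULL) {
  if (!file.exists(path)) capsIOError(sprintf("cannot read '%s'", path))
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) capsIOError(conditionMessage(e)))
  if (is.null(format)) format <- detectFormat(path, lines)
  model <- switch(format,
    pdb = parsePdbLines(lines),
    cif = parseCifLines(lines),
    capsParamError(sprintf("unknown structure format '%s'", format)))
  if (nAtoms(model) == 0L)
    capsParseError(sprintf("'%s' contains no atoms", path))
  model@atoms <- resolveAltLocs(model@atoms)
  model@format <- format
  validObject(model)
  model
}

detectFormat <- function(path, lines) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("cif")
  head <- lines[seq_len(min(50L, length(lines)))]
  if (any(grepl("^data_", head)) || any(grepl("_atom_site\\.", lines)))
    return("cif")
  "pdb"
}

## Keep, per (model, chain, residue, atom name), the conformer with the
## highest occupancy; first-seen wins ties.
resolveAltLocs <- function(atoms) {
  if (!any(nzchar(atoms$alt_loc))) return(atoms)
  key <- paste(atoms$model_num, atoms$chain_id, atoms$res_seq, atoms$name)
  ord <- order(factor(key, levels = unique(key)), -atoms$occupancy,
               seq_len(nrow(atoms)))
  a <- atoms[ord, ]
  a <- a[!duplicated(paste(a$model_num, a$chain_id, a$res_seq, a$name)), ]
  a <- a[order(match(a$serial, atoms$serial)), ]
  rownames(a) <- NULL
  a
}

parsePdbLines <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  modelLine <- grepl("^MODEL", rec)
  isAtom <- rec == "ATOM  " | rec == "HETATM"
  modelNum <- integer(length(lines))
  cur <- 1L; seen <- FALSE
  if (any(modelLine)) {
    nums <- suppressWarnings(as.integer(substr(lines[modelLine], 11L, 14L)))
    idx <- which(modelLine)
    modelNum[] <- NA_integer_
    for (k in seq_along(idx)) {
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(lines)
      modelNum[idx[k]:to] <- if (is.na(nums[k])) k else nums[k]
    }
    modelNum[is.na(modelNum)] <- 1L
  } else modelNum[] <- 1L

  li <- which(isAtom)
  if (!length(li)) return(newStructureModel(emptyAtomTable(), format = "pdb"))
  ln <- lines[li]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    if (anyNA(v))
      capsParseError(sprintf("malformed %s in PDB line %d: '%s'", what,
                             li[which(is.na(v))[1L]],
                             ln[which(is.na(v))[1L]]))
    v
  }
  occ <- suppressWarnings(as.numeric(substr(ln, 55L, 60L)))
  occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(substr(ln, 61L, 66L)))
  b[is.na(b)] <- 0
  elem <- trimws(substr(ln, 77L, 78L))
  name <- trimws(substr(ln, 13L, 16L))
  elem[!nzchar(elem)] <- elementFromName(name[!nzchar(elem)])
  atoms <- data.frame(
    serial = as.integer(num(7L, 11L, "serial")),
    name = name,
    alt_loc = trimws(substr(ln, 17L, 17L)),
    res_name = trimws(substr(ln, 18L, 20L)),
    chain_id = trimws(substr(ln, 22L, 22L)),
    res_seq = as.integer(num(23L, 26L, "residue number")),
    x = num(31L, 38L, "x"), y = num(39L, 46L, "y"), z = num(47L, 54L, "z"),
    occupancy = pmin(pmax(occ, 0), 1),
    b_iso = b,
    element = elem,
    model_num = modelNum[li],
    stringsAsFactors = FALSE)
  title <- trimws(paste(substr(lines[rec == "TITLE "], 11L, 80L),
                        collapse = " "))
  newStructureModel(atoms, title = title, format = "pdb")
}

emptyAtomTable <- function() {
  data.frame(serial = integer(), name = character(), alt_loc = character(),
             res_name = character(), chain_id = character(),
             res_seq = integer(), x = numeric(), y = numeric(), z = numeric(),
             occupancy = numeric(), b_iso = numeric(), element = character(),
             model_num = integer(), stringsAsFactors = FALSE)
}

## Minimal mmCIF reader for the atom_site category.
parseCifLines <- function(lines) {
  lines <- lines[!grepl("^#", lines)]
  loopStarts <- which(grepl("^\\s*loop_\\s*$", lines))
  for (ls in loopStarts) {
    i <- ls + 1L
    tags <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1L
    }
    if (!length(tags) || !all(grepl("^_atom_site\\.", tags))) next
    rows <- character()
    while (i <= length(lines)) {
      l <- lines[i]
      if (grepl("^\\s*(loop_|_|data_)", l) || grepl("^\\s*$", l)) break
      rows <- c(rows, l); i <- i + 1L
    }
    return(cifAtomTable(sub("^_atom_site\\.", "", tags), rows))
  }
  newStructureModel(emptyAtomTable(), format = "cif")
}

cifAtomTable <- function(fields, rows) {
  tok <- strsplit(trimws(rows), "\\s+")
  nf <- length(fields)
  bad <- which(vapply(tok, length, 1L) != nf)
  if (length(bad))
    capsParseError(sprintf("mmCIF atom_site row %d has %d fields, expected %d",
                           bad[1L], length(tok[[bad[1L]]]), nf))
  m <- do.call(rbind, tok)
  colnames(m) <- fields
  get <- function(nm, default) if (nm %in% fields) m[, nm] else default
  n <- nrow(m)
  unq <- function(v) gsub("^['\"]|['\"]$", "", v)
  dotNA <- function(v, default) ifelse(v %in% c(".", "?"), default, v)
  chain <- dotNA(get("auth_asym_id", get("label_asym_id", rep("A", n))), "A")
  resSeq <- dotNA(get("auth_seq_id", get("label_seq_id", rep("1", n))), "1")
  altLoc <- dotNA(get("label_alt_id", rep("", n)), "")
  numc <- function(nm, what) {
    v <- suppressWarnings(as.numeric(m[, nm]))
    if (anyNA(v)) capsParseError(sprintf("malformed %s in mmCIF row %d",
                                         what, which(is.na(v))[1L]))
    v
  }
  atoms <- data.frame(
    serial = seq_len(n),
    name = unq(get("label_atom_id", get("auth_atom_id", rep("X", n)))),
    alt_loc = altLoc,
    res_name = unq(get("label_comp_id", rep("UNK", n))),
    chain_id = unq(chain),
    res_seq = as.integer(suppressWarnings(as.numeric(resSeq))),
    x = numc("Cartn_x", "x"), y = numc("Cartn_y", "y"),
    z = numc("Cartn_z", "z"),
    occupancy = if ("occupancy" %in% fields)
      pmin(pmax(suppressWarnings(as.numeric(dotNA(m[, "occupancy"], "1"))), 0), 1)
      else rep(1, n),
    b_iso = if ("B_iso_or_equiv" %in% fields)
      suppressWarnings(as.numeric(dotNA(m[, "B_iso_or_equiv"], "0")))
      else rep(0, n),
    element = toupper(dotNA(get("type_symbol", rep("", n)), "")),
    model_num = as.integer(dotNA(get("pdbx_PDB_model_num", rep("1", n)), "1")),
    stringsAsFactors = FALSE)
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- elementFromName(atoms$name[blank])
  if (anyNA(atoms$res_seq)) atoms$res_seq[is.na(atoms$res_seq)] <- 1L
  newStructureModel(atoms, format = "cif")
}

#' Select a sub-structure
#'
#' Returns the atoms matching all given filters, preserving order.  Use
#' \code{domainScheme()} intervals to slice NTD/CTD.  An empty selection is an
#' error by default so that analysis paths never continue silently on nothing.
#'
#' @param x a \linkS4class{StructureModel}.
#' @param chains chain ids to keep (NULL = all).
#' @param residues inclusive residue interval c(lo, hi) (NULL = all).
#' @param atoms atom names to keep (NULL = all).
#' @param model model number to keep (NULL = all).
#' @param allowEmpty return an empty model instead of erroring.
#' @return a \linkS4class{StructureModel}
#' @export
selectAtoms <- function(x, chains = NULL, residues = NULL, atoms = NULL,
                        model = NULL, allowEmpty = FALSE) {
  a <- x@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains))   keep <- keep & a$chain_id %in% chains
  if (!is.null(residues)) keep <- keep & a$res_seq >= residues[1L] &
                                          a$res_seq <= residues[2L]
  if (!is.null(atoms))    keep <- keep & a$name %in% atoms
  if (!is.null(model))    keep <- keep & a$model_num %in% model
  out <- a[keep, ]
  if (!nrow(out) && !allowEmpty)
    capsAnalysisError("selection matched no atoms")
  rownames(out) <- NULL
  new("StructureModel", atoms = out, title = x@title, format = x@format)
}

## Heavy (non-hydrogen, non-water) atoms: the default basis for centroid and
## contact computations, since hydrogen presence is deposition-dependent.
heavyAtoms <- function(x) {
  a <- x@atoms
  keep <- toupper(a$element) != "H" & !(a$res_name %in% c("HOH", "WAT", "DOD"))
  out <- a[keep, ]
  rownames(out) <- NULL
  new("StructureModel", atoms = out, title = x@title, format = x@format)
}

#' Write an atomic model to PDB or mmCIF
#'
#' Strict PDB mode requires single-character chain identifiers and at most
#' 99,999 atoms; large assemblies (e.g. a 180-chain T=3 shell) should be
#' written as mmCIF, which this function advises in its error message.
#'
#' @param x a \linkS4class{StructureModel}.
#' @param path output path.
#' @param format "pdb" or "cif"; NULL auto-detects from the extension
#'   (default "pdb").
#' @return invisibly, \code{path}
#' @export
writeStructure <- function(x, path, format = NULL) {
  if (nAtoms(x) == 0L) capsParamError("refusing to write an empty model")
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  switch(format,
    pdb = writePdb(x, path),
    cif = writeCif(x, path),
    capsParamError(sprintf("unknown format '%s'", format)))
  invisible(path)
}

writePdb <- function(x, path) {
  a <- x@atoms
  if (nrow(a) > 99999L)
    capsParamError(">99,999 atoms cannot be written in strict PDB; use mmCIF")
  if (any(nchar(a$chain_id) > 1L))
    capsParamError(paste("multi-character chain ids cannot be written in",
                         "strict PDB; use mmCIF"))
  con <- file(path, "w"); on.exit(close(con))
  if (nzchar(x@title))
    writeLines(sprintf("TITLE     %s", x@title), con)
  multi <- length(unique(a$model_num)) > 1L
  for (mn in sort(unique(a$model_num))) {
    am <- a[a$model_num == mn, ]
    if (multi) writeLines(sprintf("MODEL     %4d", mn), con)
    nm <- ifelse(nchar(am$name) < 4L, paste0(" ", am$name), am$name)
    writeLines(sprintf(
      "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      am$serial %% 100000L, nm, substr(am$alt_loc, 1L, 1L), am$res_name,
      am$chain_id, am$res_seq, am$x, am$y, am$z, am$occupancy, am$b_iso,
      am$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

writeCif <- function(x, path) {
  a <- x@atoms
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("data_capsgeom", "#", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.label_asym_id", "_atom_site.label_seq_id",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
               "_atom_site.auth_seq_id", "_atom_site.auth_asym_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  alt <- ifelse(nzchar(a$alt_loc), a$alt_loc, ".")
  writeLines(sprintf(
    "ATOM %d %s %s %s %s %s %d %.3f %.3f %.3f %.2f %.2f %d %s %d",
    seq_len(nrow(a)), a$element, a$name, alt, a$res_name, a$chain_id,
    a$res_seq, a$x, a$y, a$z, a$occupancy, a$b_iso, a$res_seq, a$chain_id,
    a$model_num), con)
  writeLines("#", con)
}
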