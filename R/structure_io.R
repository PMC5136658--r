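# Atomic-structure container and readers.
#
# A `tmd_structure` is a light S3 wrapper around an atom table in author
# numbering. Only model 1 of multi-model files is kept, and alternate
# locations are resolved to the highest-occupancy conformer, so downstream
# geometry never has to reason about duplicated atoms.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Build a structure model from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer author
#'   number), `icode` (insertion code, "" when absent), `resname`
#'   (three-letter residue name), `elety` (atom name), `element` (element
#'   symbol), `x`,`y`,`z` (coordinates, Angstrom), `altloc`, `occupancy`.
#' @param id accession or label.
#' @param source_format one of "pdb", "mmcif", "synthetic".
#' @return object of class `tmd_structure`.
#' @export
as_tmd_structure <- function(atoms, id = "structure", source_format = "synthetic") {
  needed <- c("chain", "resno", "icode", "resname", "elety", "element",
              "x", "y", "z", "altloc", "occupancy")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  bad_occ <- !is.na(atoms$occupancy) & (atoms$occupancy < 0 | atoms$occupancy > 1)
  if (any(bad_occ)) stop("occupancy outside [0,1]")
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$icode), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms$is_backbone <- atoms$elety %in% BACKBONE_ATOMS
  structure(list(id = id, atoms = atoms, source_format = source_format),
            class = "tmd_structure")
}

#' @export
print.tmd_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  nres <- nrow(unique(x$atoms[, c("chain", "resno", "icode")]))
  cat(sprintf("<tmd_structure %s> %d chain(s) [%s], %d residues, %d atoms (%s)\n",
              x$id, length(ch), paste(ch, collapse = ","), nres,
              nrow(x$atoms), x$source_format))
  invisible(x)
}

# Resolve alternate locations: keep the highest-occupancy altloc per
# (chain, resno, icode, elety); ties broken by alphabetical altloc id.
resolve_altloc <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$elety, sep = "\r")
  occ <- ifelse(is.na(atoms$occupancy), 1, atoms$occupancy)
  ord <- order(key, -occ, atoms$altloc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

#' Read a PDB or mmCIF structure file
#'
#' Parses with bio3d, keeps the first model only, resolves alternate
#' locations to the highest-occupancy conformer and (by default) drops
#' waters and other heteroatoms. Fusion partners present in crystal entries
#' are not removed here; transmembrane annotation ranges select the receptor
#' residues downstream.
#'
#' @param path file path.
#' @param format "auto" (detect from extension/content), "pdb" or "cif".
#' @param keep_het keep HETATM records (waters always identified by residue
#'   name HOH/WAT and dropped unless `keep_het`).
#' @return a `tmd_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), keep_het = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty structure: zero-length file ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else {
      head_lines <- readLines(path, n = 20L, warn = FALSE)
      if (any(grepl("^data_|^_atom_site", head_lines))) "cif" else "pdb"
    }
  }
  pdb <- tryCatch(
    if (format == "cif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("empty structure: no coordinates in ", path)
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = as.integer(a$resno),
    icode = ifelse(is.na(a$insert), "", a$insert),
    resname = a$resid,
    elety = a$elety,
    element = if (!is.null(a$elesy)) ifelse(is.na(a$elesy), guess_element(a$elety), a$elesy)
              else guess_element(a$elety),
    x = a$x, y = a$y, z = a$z,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    stringsAsFactors = FALSE
  )
  is_water <- atoms$resname %in% c("HOH", "WAT", "DOD")
  atoms <- atoms[!is_water, , drop = FALSE]
  if (!keep_het) {
    het <- a$type[!is_water] == "HETATM"
    atoms <- atoms[!het, , drop = FALSE]
  }
  if (nrow(atoms) == 0) stop("empty structure: no qualifying atoms in ", path)
  atoms <- resolve_altloc(atoms)
  atoms$altloc <- ""
  as_tmd_structure(atoms, id = sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                                   ignore.case = TRUE),
                   source_format = if (format == "cif") "mmcif" else "pdb")
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  substr(e, 1, 1)
}

#' Write a structure model to a PDB file
#'
#' @param model a `tmd_structure`.
#' @param path output path.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  n <- nrow(a)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", n), eleno = seq_len(n),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   elety = a$elety, o = a$occupancy, b = rep(0, n),
                   elesy = a$element)
  invisible(path)
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

#' One-letter sequence of a chain
#'
#' @param model a `tmd_structure`.
#' @param chain_id chain identifier.
#' @return list with `sequence` (string; 'X' for nonstandard residues) and
#'   `numbering` (integer author numbers aligned index-by-index).
#' @export
chain_sequence <- function(model, chain_id) {
  a <- model$atoms[model$atoms$chain == chain_id, , drop = FALSE]
  if (nrow(a) == 0) stop("unknown chain: ", chain_id)
  res <- unique(a[, c("resno", "icode", "resname")])
  res <- res[order(res$resno, res$icode), , drop = FALSE]
  one <- AA3TO1[res$resname]
  one[is.na(one)] <- "X"
  list(sequence = paste(one, collapse = ""), numbering = res$resno)
}

# residue atom subtable; returns zero-row frame when absent
get_residue <- function(model, chain_id, resno, icode = "") {
  a <- model$atoms
  a[a$chain == chain_id & a$resno == resno & a$icode == icode, , drop = FALSE]
}

#' Transmembrane-helix annotation
#'
#' @param ranges named list `TM1`..`TM7` (optionally `H8`) of inclusive
#'   `c(start, end)` author-number ranges.
#' @param chain chain the annotation refers to.
#' @param ec_end_tm1 which end of TM1 faces the extracellular side: "first"
#'   (N-terminal, the usual class A orientation) or "last". Even-numbered
#'   helices run antiparallel to odd ones.
#' @return object of class `tm_annotation`.
#' @export
tm_annotation <- function(ranges, chain = "A", ec_end_tm1 = c("first", "last")) {
  ec_end_tm1 <- match.arg(ec_end_tm1)
  need <- paste0("TM", 1:7)
  if (!all(need %in% names(ranges))) {
    stop("annotation must cover TM1..TM7; missing: ",
         paste(setdiff(need, names(ranges)), collapse = ", "))
  }
  for (h in names(ranges)) {
    r <- ranges[[h]]
    if (length(r) != 2 || r[2] < r[1]) stop("bad range for ", h)
    if (r[2] - r[1] + 1 < 8) stop(h, " range shorter than 8 residues")
  }
  spans <- do.call(rbind, lapply(ranges, function(r) r))
  ord <- order(spans[, 1])
  if (any(spans[ord, 1][-1] <= spans[ord, 2][-length(ranges)])) {
    stop("annotation ranges overlap")
  }
  structure(list(ranges = ranges, chain = chain, ec_end_tm1 = ec_end_tm1),
            class = "tm_annotation")
}

#' Read a TM annotation from a YAML config
#'
#' Expected layout: `chain:`, `extracellular_end_of_TM1:` and a `helices:`
#' mapping of helix name to `[start, end]`.
#' @param path YAML file.
#' @export
read_tm_annotation <- function(path) {
  cfg <- yaml::read_yaml(path)
  tm_annotation(cfg$helices,
                chain = if (is.null(cfg$chain)) "A" else as.character(cfg$chain),
                ec_end_tm1 = if (is.null(cfg$extracellular_end_of_TM1)) "first"
                             else cfg$extracellular_end_of_TM1)
}

# helix name ("TM1"...) containing an author number, or NA
helix_of <- function(tm, resno) {
  for (h in names(tm$ranges)) {
    r <- tm$ranges[[h]]
    if (resno >= r[1] && resno <= r[2]) return(h)
  }
  NA_character_
}

#' Report annotated residues missing from the coordinates
#'
#' Lists every author number inside an annotated helix range that has no
#' residue in the model, or a residue without a CA atom (flagged incomplete).
#'
#' @param model a `tmd_structure`.
#' @param tm a `tm_annotation`.
#' @return data.frame with columns `helix`, `resno`, `status`
#'   ("absent" or "incomplete"); zero rows when nothing is missing.
#' @export
missing_report <- function(model, tm) {
  a <- model$atoms[model$atoms$chain == tm$chain, , drop = FALSE]
  if (nrow(a) == 0) stop("annotation chain ", tm$chain, " not in structure")
  out <- list()
  for (h in names(tm$ranges)) {
    r <- tm$ranges[[h]]
    for (n in seq(r[1], r[2])) {
      res <- a[a$resno == n, , drop = FALSE]
      if (nrow(res) == 0) {
        out[[length(out) + 1]] <- data.frame(helix = h, resno = n,
                                             status = "absent")
      } else if (!any(res$elety == "CA")) {
        out[[length(out) + 1]] <- data.frame(helix = h, resno = n,
                                             status = "incomplete")
      }
    }
  }
  if (length(out) == 0) {
    data.frame(helix = character(), resno = integer(), status = character())
  } else {
    do.call(rbind, out)
  }
}

#' Download a PDB entry from the public archive
#'
#' Convenience helper; never invoked by the core test path when offline
#' fixtures suffice.
#' @param accession four-character PDB id.
#' @param dir destination directory.
#' @param timeout seconds before giving up.
#' @return path to the downloaded file.
#' @export
fetch_pdb <- function(accession, dir = ".", timeout = 60) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dir, paste0(tolower(accession), ".pdb"))
  if (file.exists(dest) && file.size(dest) > 0) return(dest)
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(accession))
  old <- options(timeout = timeout)
  on.exit(options(old))
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                     error = function(e) -1L, warning = function(w) -1L)
  if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("could not download ", accession, " from ", url)
  }
  dest
}
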