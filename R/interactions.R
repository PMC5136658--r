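# Distance-based classification of inter-residue contacts.
#
# Tiers and default heavy-atom cutoffs (Angstrom):
#   salt_bridge        opposite charged-group N/O atoms   <= 4.0
#   hbond              donor-acceptor                     <= 3.5
#   weak_polar         donor-acceptor                      3.5 - 4.0
#   aromatic           ring atom - ring atom              <= 4.5
#   hydrophobic_strong apolar C - apolar C                <= 4.0
#   hydrophobic_weak   apolar C - apolar C                 4.0 - 4.5
#   induced_dipole     charged/polar atom - apolar C      <= 4.5
#   water_mediated_possible  donor/acceptor pair           4.0 - 6.0
# The water-mediated band is reported alongside a contact (or alone with
# is_contact = FALSE); it never counts as a direct contact by itself. No
# hydrogen positions or donor-acceptor angles are used: the calibration is
# meant for crystal structures and models deposited without hydrogens.

#' Default interaction distance cutoffs (Angstrom)
#' @return named list of cutoffs; override entries and pass to
#'   [classify_pair()] / [interaction_map()].
#' @export
interaction_cutoffs <- function() {
  list(salt_bridge = 4.0, hbond = 3.5, weak_polar = 4.0, aromatic = 4.5,
       hydrophobic_strong = 4.0, hydrophobic_weak = 4.5,
       induced_dipole = 4.5, water_mediated = 6.0)
}

# Atom-role tables for the 20 standard residues. An atom may hold several
# roles. His is treated as donor+acceptor and aromatic, not charged.
ATOM_TYPING <- list(
  positive = list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ"),
  negative = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
  donor = list(ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
               HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
               TRP = "NE1", TYR = "OH"),
  acceptor = list(ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1",
                  GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), SER = "OG",
                  THR = "OG1", TYR = "OH"),
  aromatic = list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                          "CZ2", "CZ3", "CH2"),
                  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")),
  # side-chain carbons with no attached N/O (Met thioether carbons included)
  apolar = list(ALA = "CB", ARG = c("CB", "CG"), ASN = "CB", ASP = "CB",
                CYS = c("CB", "SG"), GLN = c("CB", "CG"), GLU = c("CB", "CG"),
                HIS = "CB", ILE = c("CB", "CG1", "CG2", "CD1"),
                LEU = c("CB", "CG", "CD1", "CD2"),
                LYS = c("CB", "CG", "CD"), MET = c("CB", "CG", "SD", "CE"),
                PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                PRO = c("CB", "CG"), THR = "CG2",
                TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
                TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
                VAL = c("CB", "CG1", "CG2"))
)

#' Atom role table
#'
#' @param include_backbone include backbone amide N as donor and carbonyl O
#'   as acceptor (prolines have no amide donor).
#' @return the role table used by [classify_pair()].
#' @export
atom_typing <- function(include_backbone = TRUE) {
  t <- ATOM_TYPING
  attr(t, "include_backbone") <- include_backbone
  t
}

role_atoms <- function(res, role, typing) {
  if (nrow(res) == 0) return(res[0, , drop = FALSE])
  name3 <- res$resname[1]
  keep <- res$elety %in% (typing[[role]][[name3]] %||% character(0))
  if (isTRUE(attr(typing, "include_backbone"))) {
    if (role == "donor" && name3 != "PRO") keep <- keep | res$elety == "N"
    if (role == "acceptor") keep <- keep | res$elety == "O"
  }
  res[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

min_cross_distance <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(d = Inf, atom_a = NA_character_, atom_b = NA_character_))
  }
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  i <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
  list(d = sqrt(d2[i[1], i[2]]), atom_a = a$elety[i[1]], atom_b = b$elety[i[2]])
}

#' Distance between two residues
#'
#' @param res_a,res_b atom tables of the two residues (see `get_residue`
#'   via [interaction_map()]/[wt_interaction_profile()] for the usual entry
#'   points).
#' @param mode "ca" (CA-CA), "min_sidechain_heavy" (minimum over side-chain
#'   heavy atoms; glycine falls back to CA with a warning), "min_heavy"
#'   (all heavy atoms), or "named_atoms" with `atoms = c(name_a, name_b)`.
#' @param atoms atom-name pair for mode "named_atoms".
#' @return distance in Angstrom.
#' @export
pair_distance <- function(res_a, res_b,
                          mode = c("ca", "min_sidechain_heavy", "min_heavy",
                                   "named_atoms"),
                          atoms = NULL) {
  mode <- match.arg(mode)
  pick <- function(res, what) {
    out <- switch(what,
      ca = res[res$elety == "CA", , drop = FALSE],
      sidechain = {
        sc <- res[!res$elety %in% BACKBONE_ATOMS & res$element != "H", , drop = FALSE]
        if (nrow(sc) == 0) {
          warning("no side-chain atoms for ", res$resname[1], res$resno[1],
                  "; falling back to CA", call. = FALSE)
          sc <- res[res$elety == "CA", , drop = FALSE]
        }
        sc
      },
      heavy = res[res$element != "H", , drop = FALSE])
    out
  }
  if (mode == "named_atoms") {
    if (is.null(atoms) || length(atoms) != 2) stop("mode 'named_atoms' needs atoms = c(a, b)")
    a <- res_a[res_a$elety == atoms[1], , drop = FALSE]
    b <- res_b[res_b$elety == atoms[2], , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) {
      stop("missing atoms for measurement: ",
           paste(atoms[c(nrow(a) == 0, nrow(b) == 0)], collapse = ", "))
    }
    return(min_cross_distance(a, b)$d)
  }
  what <- switch(mode, ca = "ca", min_sidechain_heavy = "sidechain",
                 min_heavy = "heavy")
  a <- pick(res_a, what); b <- pick(res_b, what)
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("missing atoms for mode ", mode)
  }
  min_cross_distance(a, b)$d
}

#' Classify the interaction between two residues
#'
#' Applies the tier ladder (see file header) with the first matching rule
#' winning; the water-mediated 4-6 A donor/acceptor band is carried as a
#' flag and, when nothing else matches, as a non-contact tier of its own.
#'
#' @param res_a,res_b atom tables of the two residues.
#' @param typing role table from [atom_typing()].
#' @param cutoffs list from [interaction_cutoffs()] (entries overridable).
#' @return one-row data.frame of class `interaction_record`: `tier`,
#'   `distance_A`, `atom_a`, `atom_b`, `water_mediated_possible`,
#'   `is_contact`.
#' @export
classify_pair <- function(res_a, res_b, typing = atom_typing(),
                          cutoffs = interaction_cutoffs()) {
  heavy_a <- res_a$element != "H"; heavy_b <- res_b$element != "H"
  res_a <- res_a[heavy_a, , drop = FALSE]; res_b <- res_b[heavy_b, , drop = FALSE]
  A <- as.matrix(res_a[, c("x", "y", "z")])
  B <- as.matrix(res_b[, c("x", "y", "z")])
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  idx <- function(res, role) {
    name3 <- res$resname[1]
    keep <- res$elety %in% (typing[[role]][[name3]] %||% character(0))
    if (isTRUE(attr(typing, "include_backbone"))) {
      if (role == "donor" && name3 != "PRO") keep <- keep | res$elety == "N"
      if (role == "acceptor") keep <- keep | res$elety == "O"
    }
    which(keep)
  }
  mind <- function(ia, ib) {
    if (length(ia) == 0 || length(ib) == 0) {
      return(list(d = Inf, atom_a = NA_character_, atom_b = NA_character_))
    }
    sub <- D[ia, ib, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)[1, ]
    list(d = sub[k[1], k[2]], atom_a = res_a$elety[ia[k[1]]],
         atom_b = res_b$elety[ib[k[2]]])
  }
  best2 <- function(m1, m2) if (m2$d < m1$d) m2 else m1
  ia <- lapply(c("positive", "negative", "donor", "acceptor", "aromatic",
                 "apolar"), function(r) idx(res_a, r))
  ib <- lapply(c("positive", "negative", "donor", "acceptor", "aromatic",
                 "apolar"), function(r) idx(res_b, r))
  names(ia) <- names(ib) <- c("positive", "negative", "donor", "acceptor",
                              "aromatic", "apolar")
  sb <- best2(mind(ia$positive, ib$negative), mind(ia$negative, ib$positive))
  da <- best2(mind(ia$donor, ib$acceptor), mind(ia$acceptor, ib$donor))
  ar <- mind(ia$aromatic, ib$aromatic)
  ap <- mind(ia$apolar, ib$apolar)
  polar_ia <- unique(unlist(ia[c("positive", "negative", "donor", "acceptor")]))
  polar_ib <- unique(unlist(ib[c("positive", "negative", "donor", "acceptor")]))
  id <- best2(mind(polar_ia, ib$apolar), mind(ia$apolar, polar_ib))

  water <- is.finite(da$d) && da$d > cutoffs$weak_polar && da$d <= cutoffs$water_mediated

  rec <- function(tier, m, is_contact = TRUE) {
    structure(data.frame(tier = tier, distance_A = m$d, atom_a = m$atom_a,
                         atom_b = m$atom_b, water_mediated_possible = water,
                         is_contact = is_contact),
              class = c("interaction_record", "data.frame"))
  }
  if (sb$d <= cutoffs$salt_bridge) return(rec("salt_bridge", sb))
  if (da$d <= cutoffs$hbond) return(rec("hbond", da))
  if (da$d <= cutoffs$weak_polar) return(rec("weak_polar", da))
  if (ar$d <= cutoffs$aromatic) return(rec("aromatic", ar))
  if (ap$d <= cutoffs$hydrophobic_strong) return(rec("hydrophobic_strong", ap))
  if (ap$d <= cutoffs$hydrophobic_weak) return(rec("hydrophobic_weak", ap))
  if (id$d <= cutoffs$induced_dipole) return(rec("induced_dipole", id))
  if (water) return(rec("water_mediated_possible", da, is_contact = FALSE))
  rec("none", mind(seq_len(nrow(res_a)), seq_len(nrow(res_b))),
      is_contact = FALSE)
}

#' Contact map over a structure
#'
#' Classifies every qualifying residue pair covered by the BW map:
#' inter-helix pairs, plus intra-helix pairs more than 4 residues apart.
#' Pairs whose CA atoms are farther than `ca_prefilter` are skipped.
#'
#' @param model a `tmd_structure`.
#' @param map a `bw_map`.
#' @param typing,cutoffs see [classify_pair()].
#' @param ca_prefilter CA-CA screening distance (Angstrom).
#' @param keep_water_only also keep records that are only in the
#'   water-mediated band (default drops them: they are not direct contacts).
#' @return data.frame sorted by distance: `resno_a`, `bw_a`, `resno_b`,
#'   `bw_b`, `resname_a`, `resname_b`, `tier`, `distance_A`, `atom_a`,
#'   `atom_b`, `water_mediated_possible`.
#' @export
interaction_map <- function(model, map, typing = atom_typing(),
                            cutoffs = interaction_cutoffs(),
                            ca_prefilter = 16, keep_water_only = FALSE) {
  chain <- map$chain[1]
  a <- model$atoms[model$atoms$chain == chain & model$atoms$icode == "", ,
                   drop = FALSE]
  a <- a[a$resno %in% map$resno, , drop = FALSE]
  res_tab <- split(a, a$resno)
  ca <- a[a$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(ca)
  helix <- map$helix[match(ca$resno, map$resno)]
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  cand <- which(upper.tri(d2) & d2 <= ca_prefilter^2, arr.ind = TRUE)
  rows <- list()
  for (p in seq_len(nrow(cand))) {
    i <- cand[p, 1]; j <- cand[p, 2]
    if (helix[i] == helix[j] && abs(ca$resno[j] - ca$resno[i]) <= 4) next
    ri <- ca$resno[i]; rj <- ca$resno[j]
    res_i <- res_tab[[as.character(ri)]]
    res_j <- res_tab[[as.character(rj)]]
    rec <- classify_pair(res_i, res_j, typing, cutoffs)
    if (rec$tier == "none") next
    if (!rec$is_contact && !keep_water_only) next
    rows[[length(rows) + 1]] <- data.frame(
      resno_a = ri, bw_a = bw_label(map, ri),
      resno_b = rj, bw_b = bw_label(map, rj),
      resname_a = res_i$resname[1], resname_b = res_j$resname[1],
      tier = rec$tier, distance_A = rec$distance_A,
      atom_a = rec$atom_a, atom_b = rec$atom_b,
      water_mediated_possible = rec$water_mediated_possible)
  }
  if (length(rows) == 0) {
    return(data.frame(resno_a = integer(), bw_a = character(),
                      resno_b = integer(), bw_b = character(),
                      resname_a = character(), resname_b = character(),
                      tier = character(), distance_A = numeric(),
                      atom_a = character(), atom_b = character(),
                      water_mediated_possible = logical()))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$distance_A), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an interaction map as TSV
#' @param im output of [interaction_map()].
#' @param path output file.
#' @export
write_interaction_map <- function(im, path) {
  utils::write.table(im, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
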