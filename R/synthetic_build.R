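# Low-level builders for synthetic helices: NeRF atom placement, ideal
# alpha-helix backbones, and idealized one-rotamer side-chain templates.
#
# CA atoms of an ideal helix are placed parametrically (rise 1.5 A, twist
# 100 deg, radius 2.3 A); N, C and O are attached through local CA-frame
# offsets calibrated once from a torsion-built reference helix
# (phi = -57, psi = -47), so the hydrogen-bond registry of a canonical
# alpha helix (O_i ... N_i+4 about 3 A) is preserved while the CA trace
# follows the requested parameters exactly. Side chains use one idealized
# extended rotamer per residue type: enough fidelity for distance-tier
# tests, with no rotamer-library dependency.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# NeRF: place atom D given A, B, C, the C-D bond length, the B-C-D angle
# and the A-B-C-D torsion (degrees)
place_atom <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  b1 <- unit(B - A)
  b2 <- unit(C - B)
  n <- unit(cross3(b1, b2))
  m <- cross3(n, b2)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  as.numeric(C + cbind(b2, m, n) %*% d2)
}

# torsion-driven backbone builder (N, CA, C, O per residue)
build_nerf_backbone <- function(n, phi = rep(-57, n), psi = rep(-47, n)) {
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- place_atom(c(0, 1, 0), N[1, ], CA[1, ], 1.525, 111.2, 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2,
                         psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi[i])
  }
  for (i in 1:n) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# orthonormal local frame at CA_i from the flanking CA positions
ca_frame <- function(prev, this, nxt) {
  v1 <- nxt - this
  v2 <- prev - this
  e1 <- unit(v1)
  e3 <- unit(cross3(v1, v2))
  e2 <- cross3(e3, e1)
  list(origin = this, basis = cbind(e1, e2, e3))
}

# backbone N/C/O offsets in the CA frame, calibrated from the reference
# torsion-built helix (computed once, cached)
.build_env <- new.env(parent = emptyenv())
backbone_offsets <- function() {
  if (!is.null(.build_env$offsets)) return(.build_env$offsets)
  bb <- build_nerf_backbone(11)
  acc <- list(N = NULL, C = NULL, O = NULL)
  for (i in 4:8) {
    f <- ca_frame(bb$CA[i - 1, ], bb$CA[i, ], bb$CA[i + 1, ])
    for (at in names(acc)) {
      loc <- as.numeric(t(f$basis) %*% (bb[[at]][i, ] - f$origin))
      acc[[at]] <- rbind(acc[[at]], loc)
    }
  }
  .build_env$offsets <- lapply(acc, colMeans)
  .build_env$offsets
}

# tetrahedral CB from backbone N, CA, C (L-configuration)
place_cb <- function(N, CA, C, bond = 1.53) {
  u_n <- unit(N - CA)
  u_c <- unit(C - CA)
  bis <- unit(u_n + u_c)
  nrm <- unit(cross3(u_n, u_c))
  a <- -cos(110.5 * pi / 180) / sqrt((1 + sum(u_n * u_c)) / 2)
  b <- sqrt(max(0, 1 - a^2))
  CA + bond * unit(-bis * a + nrm * b)
}

# Side-chain internal-coordinate templates: one extended rotamer per
# residue. Each row: atom, three reference atoms, bond (A), angle (deg),
# torsion (deg). References may be backbone (N, CA, C) or earlier
# side-chain atoms.
zrow <- function(atom, refs, bond, angle, torsion) {
  list(atom = atom, refs = refs, bond = bond, angle = angle, torsion = torsion)
}

SIDECHAIN_Z <- list(
  GLY = list(),
  ALA = list(),
  SER = list(zrow("OG", c("N", "CA", "CB"), 1.42, 110.5, 180)),
  CYS = list(zrow("SG", c("N", "CA", "CB"), 1.81, 114.0, 180)),
  THR = list(zrow("OG1", c("N", "CA", "CB"), 1.43, 109.5, 180),
             zrow("CG2", c("N", "CA", "CB"), 1.52, 109.5, 60)),
  VAL = list(zrow("CG1", c("N", "CA", "CB"), 1.52, 110.5, 180),
             zrow("CG2", c("N", "CA", "CB"), 1.52, 110.5, -60)),
  LEU = list(zrow("CG", c("N", "CA", "CB"), 1.53, 116.0, 180),
             zrow("CD1", c("CA", "CB", "CG"), 1.52, 110.0, 180),
             zrow("CD2", c("CA", "CB", "CG"), 1.52, 110.0, 60)),
  ILE = list(zrow("CG1", c("N", "CA", "CB"), 1.53, 110.5, 180),
             zrow("CG2", c("N", "CA", "CB"), 1.52, 110.5, -60),
             zrow("CD1", c("CA", "CB", "CG1"), 1.52, 113.0, 180)),
  MET = list(zrow("CG", c("N", "CA", "CB"), 1.52, 114.0, 180),
             zrow("SD", c("CA", "CB", "CG"), 1.81, 112.0, 180),
             zrow("CE", c("CB", "CG", "SD"), 1.79, 100.0, 180)),
  PRO = list(zrow("CG", c("N", "CA", "CB"), 1.49, 104.0, 30),
             zrow("CD", c("CA", "CB", "CG"), 1.50, 106.0, -35)),
  ASP = list(zrow("CG", c("N", "CA", "CB"), 1.52, 113.0, 180),
             zrow("OD1", c("CA", "CB", "CG"), 1.25, 118.0, 0),
             zrow("OD2", c("CA", "CB", "CG"), 1.25, 118.0, 180)),
  ASN = list(zrow("CG", c("N", "CA", "CB"), 1.52, 113.0, 180),
             zrow("OD1", c("CA", "CB", "CG"), 1.23, 121.0, 0),
             zrow("ND2", c("CA", "CB", "CG"), 1.33, 117.0, 180)),
  GLU = list(zrow("CG", c("N", "CA", "CB"), 1.52, 114.0, 180),
             zrow("CD", c("CA", "CB", "CG"), 1.52, 113.0, 180),
             zrow("OE1", c("CB", "CG", "CD"), 1.25, 118.0, 0),
             zrow("OE2", c("CB", "CG", "CD"), 1.25, 118.0, 180)),
  GLN = list(zrow("CG", c("N", "CA", "CB"), 1.52, 114.0, 180),
             zrow("CD", c("CA", "CB", "CG"), 1.52, 113.0, 180),
             zrow("OE1", c("CB", "CG", "CD"), 1.23, 121.0, 0),
             zrow("NE2", c("CB", "CG", "CD"), 1.33, 117.0, 180)),
  LYS = list(zrow("CG", c("N", "CA", "CB"), 1.52, 114.0, 180),
             zrow("CD", c("CA", "CB", "CG"), 1.52, 111.0, 180),
             zrow("CE", c("CB", "CG", "CD"), 1.52, 111.0, 180),
             zrow("NZ", c("CG", "CD", "CE"), 1.49, 112.0, 180)),
  ARG = list(zrow("CG", c("N", "CA", "CB"), 1.52, 114.0, 180),
             zrow("CD", c("CA", "CB", "CG"), 1.52, 111.0, 180),
             zrow("NE", c("CB", "CG", "CD"), 1.46, 112.0, 180),
             zrow("CZ", c("CG", "CD", "NE"), 1.33, 124.0, 180),
             zrow("NH1", c("CD", "NE", "CZ"), 1.33, 120.0, 0),
             zrow("NH2", c("CD", "NE", "CZ"), 1.33, 120.0, 180)),
  PHE = list(zrow("CG", c("N", "CA", "CB"), 1.50, 114.0, 180),
             zrow("CD1", c("CA", "CB", "CG"), 1.39, 120.8, 90),
             zrow("CE1", c("CB", "CG", "CD1"), 1.39, 120.0, 180),
             zrow("CZ", c("CG", "CD1", "CE1"), 1.39, 120.0, 0),
             zrow("CE2", c("CD1", "CE1", "CZ"), 1.39, 120.0, 0),
             zrow("CD2", c("CE1", "CZ", "CE2"), 1.39, 120.0, 0)),
  TYR = list(zrow("CG", c("N", "CA", "CB"), 1.50, 114.0, 180),
             zrow("CD1", c("CA", "CB", "CG"), 1.39, 120.8, 90),
             zrow("CE1", c("CB", "CG", "CD1"), 1.39, 120.0, 180),
             zrow("CZ", c("CG", "CD1", "CE1"), 1.39, 120.0, 0),
             zrow("CE2", c("CD1", "CE1", "CZ"), 1.39, 120.0, 0),
             zrow("CD2", c("CE1", "CZ", "CE2"), 1.39, 120.0, 0),
             zrow("OH", c("CD1", "CE1", "CZ"), 1.38, 120.0, 180)),
  TRP = list(zrow("CG", c("N", "CA", "CB"), 1.50, 114.0, 180),
             zrow("CD1", c("CA", "CB", "CG"), 1.37, 127.0, 90),
             zrow("CD2", c("CA", "CB", "CG"), 1.43, 126.0, -90),
             zrow("NE1", c("CB", "CG", "CD1"), 1.38, 110.0, 180),
             zrow("CE2", c("CG", "CD1", "NE1"), 1.37, 109.0, 0),
             zrow("CE3", c("CB", "CG", "CD2"), 1.40, 127.0, 180),
             zrow("CZ2", c("CD1", "NE1", "CE2"), 1.40, 130.0, 180),
             zrow("CZ3", c("CG", "CD2", "CE3"), 1.39, 118.0, 0),
             zrow("CH2", c("CD2", "CE3", "CZ3"), 1.39, 121.0, 0)),
  HIS = list(zrow("CG", c("N", "CA", "CB"), 1.49, 114.0, 180),
             zrow("ND1", c("CA", "CB", "CG"), 1.38, 122.0, 90),
             zrow("CD2", c("CA", "CB", "CG"), 1.36, 131.0, -90),
             zrow("CE1", c("CB", "CG", "ND1"), 1.32, 109.0, 180),
             zrow("NE2", c("CG", "ND1", "CE1"), 1.32, 108.0, 0))
)

element_of <- function(elety) substr(sub("^[0-9]*", "", elety), 1, 1)

# full-atom residue: backbone coordinates supplied, side chain from template
residue_atoms <- function(resname, resno, N, CA, C, O, chain = "A") {
  coords <- list(N = N, CA = CA, C = C, O = O)
  if (resname != "GLY") coords$CB <- place_cb(N, CA, C)
  for (z in SIDECHAIN_Z[[resname]] %||% list()) {
    coords[[z$atom]] <- place_atom(coords[[z$refs[1]]], coords[[z$refs[2]]],
                                   coords[[z$refs[3]]], z$bond, z$angle,
                                   z$torsion)
  }
  nm <- names(coords)
  xyz <- do.call(rbind, coords)
  data.frame(chain = chain, resno = resno, icode = "", resname = resname,
             elety = nm, element = element_of(nm),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             altloc = "", occupancy = 1, stringsAsFactors = FALSE)
}

#' Build an ideal alpha helix with full backbone, CB and side chains
#'
#' CA atoms follow the parametric helix exactly (axis = z, residue 1 at
#' z = 0); N, C, O are attached via calibrated CA-frame offsets and side
#' chains from idealized extended rotamer templates.
#'
#' @param n_res number of residues (>= 4).
#' @param rise rise per residue (Angstrom).
#' @param twist twist per residue (degrees).
#' @param ca_radius CA helix radius (Angstrom).
#' @param sequence one-letter string (recycled "A" when NULL) of length
#'   `n_res`.
#' @param resno_start first author number.
#' @param chain chain id.
#' @return atom data.frame (as used by [as_tmd_structure()]).
#' @export
build_ideal_helix <- function(n_res, rise = 1.5, twist = 100, ca_radius = 2.3,
                              sequence = NULL, resno_start = 1, chain = "A") {
  if (n_res < 4) stop("need at least 4 residues")
  if (is.null(sequence)) sequence <- strrep("A", n_res)
  if (nchar(sequence) != n_res) stop("sequence length != n_res")
  aa <- strsplit(sequence, "")[[1]]
  ca_at <- function(i) {
    th <- (i - 1) * twist * pi / 180
    c(ca_radius * cos(th), ca_radius * sin(th), (i - 1) * rise)
  }
  off <- backbone_offsets()
  rows <- list()
  for (i in seq_len(n_res)) {
    f <- ca_frame(ca_at(i - 1), ca_at(i), ca_at(i + 1))
    at <- function(o) as.numeric(f$origin + f$basis %*% o)
    name3 <- AA1TO3[[aa[i]]]
    if (is.null(name3) || is.na(name3)) stop("unknown residue code ", aa[i])
    rows[[i]] <- residue_atoms(name3, resno_start + i - 1,
                               N = at(off$N), CA = f$origin, C = at(off$C),
                               O = at(off$O), chain = chain)
  }
  do.call(rbind, rows)
}

# helix with an alpha->pi registry shift (bulge) planted at `bulge_idx`:
# built from torsions, CA trace then aligned to the z axis
build_bulge_helix <- function(n_res, bulge_idx, sequence = NULL,
                              resno_start = 1, chain = "A") {
  if (is.null(sequence)) sequence <- strrep("A", n_res)
  aa <- strsplit(sequence, "")[[1]]
  phi <- rep(-57, n_res); psi <- rep(-47, n_res)
  # widen one turn: pi-helix-like torsions over three residues, placed so
  # the first registry-shifted carbonyl is at `bulge_idx`
  span <- intersect(seq(bulge_idx + 2, bulge_idx + 4), seq_len(n_res))
  phi[span] <- -80; psi[span] <- -80
  bb <- build_nerf_backbone(n_res, phi, psi)
  # align CA principal axis to +z, residue 1 at low z
  ax <- principal_axis(bb$CA, ref_dir = bb$CA[n_res, ] - bb$CA[1, ])
  R <- rotation_between(ax$dir, c(0, 0, 1))
  shift <- -as.numeric(R %*% ax$centre)
  tx <- function(m) t(R %*% t(m)) + matrix(shift, nrow(m), 3, byrow = TRUE)
  bb <- lapply(bb, tx)
  rows <- list()
  for (i in seq_len(n_res)) {
    rows[[i]] <- residue_atoms(AA1TO3[[aa[i]]], resno_start + i - 1,
                               N = bb$N[i, ], CA = bb$CA[i, ], C = bb$C[i, ],
                               O = bb$O[i, ], chain = chain)
  }
  do.call(rbind, rows)
}

# minimal rotation carrying unit vector u onto unit vector v
rotation_between <- function(u, v) {
  u <- unit(u); v <- unit(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees about any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(cross3(u, p))
    return(rot_axis_angle(ax, 180))
  }
  ax <- cross3(u, v)
  s <- sqrt(sum(ax^2))
  ax <- ax / s
  rot_axis_angle(ax, atan2(s, c_) * 180 / pi)
}

# Rodrigues rotation matrix: `deg` about unit `axis`
rot_axis_angle <- function(axis, deg) {
  a <- unit(axis); th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
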