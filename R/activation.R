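# Activation-state fingerprinting and inactive/active comparison.
#
# Two features decide the state call, mirroring how class A receptor
# structures are read in practice:
#   * the ionic lock: Arg3.50 to Asp/Glu6.30 charged-group distance
#     (present at <= 4 A stabilises the inactive state);
#   * the tyrosine toggle: Tyr7.53 (NPxxY) to Tyr5.58 side-chain distance
#     (direct bond <= 4 A, water-mediated 4-6 A in the active state,
#     > 6 A apart in the inactive state).
# Hydrophobic-core and receptor-family-specific panels are reported but do
# not vote: no published distance thresholds exist for them.

panel_residue <- function(model, map, label) {
  resno <- bw_residue(map, label)
  if (is.na(resno)) return(NULL)
  res <- get_residue(model, map$chain[1], resno)
  if (nrow(res) == 0) NULL else res
}

#' Ionic-lock status of one structure
#'
#' @param model a `tmd_structure`.
#' @param map a `bw_map`.
#' @param cutoff salt-bridge distance cutoff (Angstrom).
#' @return list with `distance_A`, `present`, `regime` ("salt_bridge",
#'   "apart", "not_applicable" when the residue types cannot form the lock,
#'   or "unavailable" when a residue is missing).
#' @export
ionic_lock_status <- function(model, map, cutoff = 4.0) {
  r350 <- panel_residue(model, map, "3.50")
  r630 <- panel_residue(model, map, "6.30")
  if (is.null(r350) || is.null(r630)) {
    return(list(distance_A = NA_real_, present = NA, regime = "unavailable"))
  }
  if (!r350$resname[1] %in% c("ARG", "LYS") ||
      !r630$resname[1] %in% c("ASP", "GLU")) {
    return(list(distance_A = NA_real_, present = NA, regime = "not_applicable"))
  }
  typing <- atom_typing(include_backbone = FALSE)
  d <- min_cross_distance(role_atoms(r350, "positive", typing),
                          role_atoms(r630, "negative", typing))$d
  list(distance_A = d, present = d <= cutoff,
       regime = if (d <= cutoff) "salt_bridge" else "apart")
}

#' Activation fingerprint of one structure
#'
#' Panels: ionic lock (3.50-6.30); tyrosine toggle (7.53-5.58, regimes
#' bonded <= 4 A / water_mediated_possible 4-6 A / apart > 6 A); hydrogen
#' bond partners of 2.50 among 7.49, 7.46, 3.39; hydrophobic-core tiers
#' (3.43-6.40, 3.43-6.41, 3.43-2.46, 5.50-3.40, 5.50-3.44); the
#' glycoprotein-hormone-receptor-specific 3.30-4.58 contact. The state call
#' uses only the lock and the toggle: inactive_like when the lock is
#' present; active_like when the lock is absent and the toggle regime is
#' not "apart"; indeterminate otherwise. Missing panel entries degrade
#' gracefully to "unavailable".
#'
#' @param model a `tmd_structure`.
#' @param map a `bw_map`.
#' @param cutoffs interaction cutoffs (see [interaction_cutoffs()]).
#' @return object of class `activation_fingerprint` (a list).
#' @export
activation_fingerprint <- function(model, map, cutoffs = interaction_cutoffs()) {
  lock <- ionic_lock_status(model, map, cutoffs$salt_bridge)
  typing <- atom_typing()

  toggle <- {
    a <- panel_residue(model, map, "7.53")
    b <- panel_residue(model, map, "5.58")
    if (is.null(a) || is.null(b)) {
      list(distance_A = NA_real_, regime = "unavailable")
    } else {
      d <- tryCatch(pair_distance(a, b, "min_sidechain_heavy"),
                    warning = function(w) suppressWarnings(
                      pair_distance(a, b, "min_sidechain_heavy")))
      regime <- if (d <= 4.0) "bonded"
                else if (d <= cutoffs$water_mediated) "water_mediated_possible"
                else "apart"
      list(distance_A = d, regime = regime)
    }
  }

  hb_partner <- function(lab_b) {
    a <- panel_residue(model, map, "2.50")
    b <- panel_residue(model, map, lab_b)
    if (is.null(a) || is.null(b)) return(NA)
    rec <- classify_pair(a, b, typing, cutoffs)
    rec$tier %in% c("hbond", "salt_bridge")
  }
  d250 <- c(`7.49` = hb_partner("7.49"), `7.46` = hb_partner("7.46"),
            `3.39` = hb_partner("3.39"))

  tier_of <- function(lab_a, lab_b) {
    a <- panel_residue(model, map, lab_a)
    b <- panel_residue(model, map, lab_b)
    if (is.null(a) || is.null(b)) return("unavailable")
    classify_pair(a, b, typing, cutoffs)$tier
  }
  core <- c(`3.43-6.40` = tier_of("3.43", "6.40"),
            `3.43-6.41` = tier_of("3.43", "6.41"),
            `3.43-2.46` = tier_of("3.43", "2.46"),
            `5.50-3.40` = tier_of("5.50", "3.40"),
            `5.50-3.44` = tier_of("5.50", "3.44"))
  gphr <- tier_of("3.30", "4.58")

  state <- if (isTRUE(lock$present)) "inactive_like"
           else if (identical(lock$present, FALSE) &&
                    toggle$regime %in% c("bonded", "water_mediated_possible"))
             "active_like"
           else "indeterminate"

  structure(list(ionic_lock = lock, tyrosine_toggle = toggle,
                 d250_network = d250, core_contacts = core,
                 gphr_contact = gphr, state_call = state),
            class = "activation_fingerprint")
}

#' @export
print.activation_fingerprint <- function(x, ...) {
  cat(sprintf("ionic lock    : %.2f A (%s)\n", x$ionic_lock$distance_A,
              x$ionic_lock$regime))
  cat(sprintf("Y7.53 - Y5.58 : %.2f A (%s)\n", x$tyrosine_toggle$distance_A,
              x$tyrosine_toggle$regime))
  cat("2.50 H-bonds  :", paste(names(x$d250_network)[x$d250_network %in% TRUE],
                               collapse = " "), "\n")
  cat("state call    :", x$state_call, "\n")
  invisible(x)
}

# Kabsch closed-form least-squares rigid superposition (reflection-free)
kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  translation <- cf - as.numeric(R %*% cm)
  moved <- t(R %*% t(moving)) + matrix(translation, nrow(moving), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

apply_rigid <- function(xyz, R, tvec) {
  t(R %*% t(as.matrix(xyz))) + matrix(tvec, nrow(xyz), 3, byrow = TRUE)
}

# matched CA coordinate pairs by identical BW label
matched_ca <- function(model_a, model_b, map_a, map_b, core_selection = 1:7) {
  sel_a <- map_a[map_a$helix %in% core_selection, , drop = FALSE]
  shared <- intersect(sel_a$label, map_b$label)
  get_ca <- function(model, map, labels) {
    res <- map$resno[match(labels, map$label)]
    a <- model$atoms
    ca <- a[a$chain == map$chain[1] & a$elety == "CA" & a$resno %in% res, , drop = FALSE]
    ca[match(res, ca$resno), , drop = FALSE]
  }
  ca_a <- get_ca(model_a, map_a, shared)
  ca_b <- get_ca(model_b, map_b, shared)
  keep <- !is.na(ca_a$resno) & !is.na(ca_b$resno)
  list(labels = shared[keep],
       helix = map_a$helix[match(shared[keep], map_a$label)],
       xyz_a = as.matrix(ca_a[keep, c("x", "y", "z")]),
       xyz_b = as.matrix(ca_b[keep, c("x", "y", "z")]))
}

#' Superpose two structures on BW-matched CA atoms
#'
#' Least-squares rigid-body (closed-form, reflection-free) superposition of
#' `model_a` onto `model_b` over CA atoms matched by identical BW label.
#'
#' @param model_a,model_b structures to compare (`model_a` is moved).
#' @param map_a,map_b their BW maps.
#' @param core_selection helices (integers 1..7) used for matching.
#' @return list of class `superposition_result`: `rotation` (3x3),
#'   `translation`, `rmsd_A`, `n_pairs`.
#' @export
superpose_by_bw <- function(model_a, model_b, map_a, map_b,
                            core_selection = 1:7) {
  m <- matched_ca(model_a, model_b, map_a, map_b, core_selection)
  if (nrow(m$xyz_a) < 3) stop("insufficient pairs: need >= 3 shared BW-matched CA")
  k <- kabsch(m$xyz_a, m$xyz_b)
  structure(list(rotation = k$rotation, translation = k$translation,
                 rmsd_A = k$rmsd, n_pairs = nrow(m$xyz_a)),
            class = "superposition_result")
}

unit <- function(v) v / sqrt(sum(v^2))

# principal axis of a point cloud, oriented so `ref_dir` projects positively
principal_axis <- function(xyz, ref_dir = NULL) {
  pc <- stats::prcomp(xyz, center = TRUE)
  d <- pc$rotation[, 1]
  if (!is.null(ref_dir) && sum(d * ref_dir) < 0) d <- -d
  list(centre = colMeans(xyz), dir = unit(d))
}

# extracellular direction of the bundle from the TM1 orientation convention
ec_direction <- function(xyz, helix, labels, map, tm) {
  tm1 <- xyz[helix == 1, , drop = FALSE]
  res1 <- map$resno[match(labels[helix == 1], map$label)]
  ord <- order(res1)
  v <- tm1[ord[length(ord)], ] - tm1[ord[1], ]     # N-term -> C-term of TM1
  if (tm$ec_end_tm1 == "first") -v else v
}

#' Per-helix displacement decomposition between two conformations
#'
#' Superposes the pair on BW-matched CA atoms, then reports, for each helix
#' end (extracellular and intracellular), the mean CA displacement of the
#' terminal turn (last 4 matched residues), decomposed into a radial
#' component (positive = outward from the bundle axis), an axial component
#' (positive = toward the extracellular side) and a tangential remainder.
#' The bundle axis is the principal axis of all matched CA of the
#' superposed pair, so both states share one reference frame.
#'
#' @param inactive,active the two structures.
#' @param map_in,map_ac their BW maps.
#' @param tm a `tm_annotation` (orientation convention).
#' @param core_selection helices used for the superposition.
#' @return data.frame of class `helix_movement_report`: helix, end,
#'   displacement components (A) and magnitude.
#' @export
helix_movements <- function(inactive, active, map_in, map_ac, tm,
                            core_selection = 1:7) {
  m <- matched_ca(inactive, active, map_in, map_ac, 1:7)
  sup <- superpose_by_bw(inactive, active, map_in, map_ac, core_selection)
  xyz_in <- apply_rigid(m$xyz_a, sup$rotation, sup$translation)
  xyz_ac <- m$xyz_b

  allxyz <- rbind(xyz_in, xyz_ac)
  ecv <- ec_direction(xyz_in, m$helix, m$labels, map_in, tm)
  axis <- principal_axis(allxyz, ref_dir = ecv)   # axis$dir points extracellular

  rows <- list()
  for (h in 1:7) {
    idx <- which(m$helix == h)
    if (length(idx) < 4) next
    res <- map_in$resno[match(m$labels[idx], map_in$label)]
    idx <- idx[order(res)]
    ends <- list(nterm = idx[1:4], cterm = idx[(length(idx) - 3):length(idx)])
    # which sequence end faces the membrane outside: TM1 convention alternates
    ec_is_nterm <- if (tm$ec_end_tm1 == "first") (h %% 2 == 1) else (h %% 2 == 0)
    for (endname in names(ends)) {
      ii <- ends[[endname]]
      p0 <- colMeans(xyz_in[ii, , drop = FALSE])
      p1 <- colMeans(xyz_ac[ii, , drop = FALSE])
      disp <- p1 - p0
      rel <- p0 - axis$centre
      radial_dir <- unit(rel - sum(rel * axis$dir) * axis$dir)
      radial <- sum(disp * radial_dir)
      axial <- sum(disp * axis$dir)
      tangential_dir <- unit(pracma_cross(axis$dir, radial_dir))
      tangential <- sum(disp * tangential_dir)
      side <- if ((endname == "nterm") == ec_is_nterm) "extracellular"
              else "intracellular"
      rows[[paste(h, endname)]] <- data.frame(
        helix = h, end = side,
        dx = disp[1], dy = disp[2], dz = disp[3],
        radial_A = radial, axial_A = axial, tangential_A = tangential,
        magnitude_A = sqrt(sum(disp^2)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("helix_movement_report", "data.frame")
  attr(out, "rmsd_A") <- sup$rmsd_A
  out
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Axial rotation of one helix between two conformations
#'
#' Measures the azimuthal change of a marker residue's side-chain centroid
#' about the helix's own axis after superposing the pair. Viewed from the
#' extracellular side, counter-clockwise is positive; reversing the two
#' structures negates the angle. Result in (-180, 180].
#'
#' @param inactive,active the two structures.
#' @param map_in,map_ac their BW maps.
#' @param tm a `tm_annotation`.
#' @param helix helix index (default 6).
#' @param marker_bw BW label of the marker residue (default "6.29", a lysine
#'   at the cytoplasmic end of TM6 in the TSH receptor).
#' @param core_selection helices used for the superposition.
#' @return rotation angle in degrees.
#' @export
helix_rotation <- function(inactive, active, map_in, map_ac, tm, helix = 6,
                           marker_bw = "6.29", core_selection = 1:7) {
  m <- matched_ca(inactive, active, map_in, map_ac, 1:7)
  sup <- superpose_by_bw(inactive, active, map_in, map_ac, core_selection)

  sc_centroid <- function(model, map, resno) {
    res <- get_residue(model, map$chain[1], resno)
    sc <- res[!res$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    if (nrow(sc) == 0) stop("marker residue ", resno, " has no side-chain atoms")
    colMeans(as.matrix(sc[, c("x", "y", "z")]))
  }
  r_in <- bw_residue(map_in, marker_bw)
  r_ac <- bw_residue(map_ac, marker_bw)
  if (is.na(r_in) || is.na(r_ac)) stop("marker ", marker_bw, " unavailable")

  idx <- which(m$helix == helix)
  if (length(idx) < 3) stop("too few matched residues on helix ", helix)
  xyz_in <- apply_rigid(m$xyz_a, sup$rotation, sup$translation)
  xyz_ac <- m$xyz_b
  ecv <- ec_direction(xyz_in, m$helix, m$labels, map_in, tm)
  ax_in <- principal_axis(xyz_in[idx, , drop = FALSE], ref_dir = ecv)
  ax_ac <- principal_axis(xyz_ac[idx, , drop = FALSE], ref_dir = ecv)

  azimuth <- function(p, ax, ref) {
    rel <- p - ax$centre
    perp <- rel - sum(rel * ax$dir) * ax$dir
    atan2(sum(pracma_cross(ref$u, perp) * ax$dir), sum(ref$u * perp))
  }
  # shared in-plane reference direction (bundle-centre-to-helix), so the
  # angle difference reflects spin about the helix axis, not helix motion
  bundle_centre <- colMeans(rbind(xyz_in, xyz_ac))
  mk_ref <- function(ax) {
    v <- ax$centre - bundle_centre
    list(u = unit(v - sum(v * ax$dir) * ax$dir))
  }
  c_in <- as.numeric(apply_rigid(matrix(sc_centroid(inactive, map_in, r_in), 1, 3),
                                 sup$rotation, sup$translation))
  c_ac <- sc_centroid(active, map_ac, r_ac)
  ang <- azimuth(c_ac, ax_ac, mk_ref(ax_ac)) - azimuth(c_in, ax_in, mk_ref(ax_in))
  ang <- ang * 180 / pi
  if (ang > 180) ang <- ang - 360
  if (ang <= -180) ang <- ang + 360
  ang
}
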