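# Deterministic seven-helix bundles with planted, known features.
#
# Helices are placed on a circle around the z axis (z+ = extracellular);
# odd-numbered helices run N->C from the extracellular to the
# intracellular side and even ones the opposite way, matching the
# orientation convention of `tm_annotation(..., ec_end_tm1 = "first")`.
# Residues are numbered 100*helix + index, and each helix carries a BW
# anchor chosen so the biologically interesting label ranges (3.50 near
# the intracellular end, 6.30 near the TM6 intracellular end, 7.53 in the
# lower third of TM7, ...) fall where they do in real receptors.
# The generator is geometrically idealized on purpose: its job is detector
# testability, not realism.

# first BW position of each helix (30-residue default length)
BUNDLE_P_START <- c(35, 39, 25, 39, 36, 28, 31)

#' Specification of a synthetic helix bundle
#'
#' @param n_helices number of helices (the analysis stack expects 7).
#' @param residues_per_helix helix length (residues).
#' @param bundle_radius circle radius for helix placement (Angstrom).
#' @param residue_types named character vector: author resno -> three-letter
#'   residue type (default: all LEU).
#' @param features list of planted features built with [feat_kink()],
#'   [feat_bulge()], [feat_contact()], [feat_spin()], [feat_motion()];
#'   applied in listed order.
#' @param noise_sd isotropic coordinate jitter (Angstrom), applied before
#'   feature realization so planted contacts stay exact.
#' @param seed integer seed controlling the jitter.
#' @return object of class `bundle_spec`.
#' @export
bundle_spec <- function(n_helices = 7, residues_per_helix = 30,
                        bundle_radius = 10.5, residue_types = character(),
                        features = list(), noise_sd = 0.05, seed = 1L,
                        default_type = "LEU") {
  for (f in features) {
    if (f$type == "contact" && f$target_A < 2.4) {
      stop("infeasible contact: target ", f$target_A,
           " A below van der Waals contact")
    }
  }
  structure(list(n_helices = n_helices,
                 residues_per_helix = residues_per_helix,
                 bundle_radius = bundle_radius,
                 residue_types = residue_types, features = features,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 default_type = default_type),
            class = "bundle_spec")
}

#' Planted helix kink
#' @param helix helix index (1..7).
#' @param resno apex author number.
#' @param angle_deg kink angle (degrees).
#' @export
feat_kink <- function(helix, resno, angle_deg) {
  list(type = "kink", helix = helix, resno = resno, angle_deg = angle_deg)
}

#' Planted alpha-bulge (i->i+4 registry shifted to i->i+5)
#' @param helix helix index.
#' @param resno author number of the first registry-shifted residue.
#' @export
feat_bulge <- function(helix, resno) {
  list(type = "bulge", helix = helix, resno = resno)
}

#' Planted inter-helix contact pair
#'
#' The two residues are retyped, aimed at each other and the second
#' residue's helix translated until the realizing inter-atom distance
#' (charged-group atoms for an oppositely charged pair, minimum side-chain
#' heavy atoms otherwise) meets `target_A`.
#' @param resno_a,resno_b author numbers (on different helices).
#' @param target_A target distance (Angstrom; must exceed van der Waals
#'   contact).
#' @param type_a,type_b three-letter residue types.
#' @param aim_a,aim_b spin the residue's helix so its side chain faces the
#'   partner before the distance is realized; disable for a residue whose
#'   orientation an earlier feature already fixed.
#' @export
feat_contact <- function(resno_a, resno_b, target_A,
                         type_a = "ARG", type_b = "ASP",
                         aim_a = TRUE, aim_b = TRUE) {
  list(type = "contact", resno_a = resno_a, resno_b = resno_b,
       target_A = target_A, type_a = type_a, type_b = type_b,
       aim_a = aim_a, aim_b = aim_b)
}

#' Spin a helix about its own axis
#' @param helix helix index.
#' @param deg rotation (degrees, counter-clockwise viewed from
#'   extracellular).
#' @export
feat_spin <- function(helix, deg) list(type = "spin", helix = helix, deg = deg)

#' Rigid motion of a whole helix
#' @param helix helix index.
#' @param translation 3-vector (Angstrom) in bundle coordinates
#'   (z+ = extracellular).
#' @param spin_deg additional spin about the helix's own axis.
#' @export
feat_motion <- function(helix, translation = c(0, 0, 0), spin_deg = 0) {
  list(type = "motion", helix = helix, translation = translation,
       spin_deg = spin_deg)
}

helix_resno_base <- function(helix) 100L * helix

bundle_anchor <- function(helix, p_start = BUNDLE_P_START) {
  helix_resno_base(helix) + (51L - p_start[helix])
}

#' BW label -> author number in a synthetic bundle
#' @param label BW label like "6.30".
#' @export
bundle_resno <- function(label) {
  p <- strsplit(label, ".", fixed = TRUE)[[1]]
  h <- as.integer(p[1]); pos <- as.integer(p[2])
  helix_resno_base(h) + (pos - BUNDLE_P_START[h] + 1L)
}

helix_atoms_idx <- function(atoms, helix, n_res) {
  base <- helix_resno_base(helix)
  which(atoms$resno > base & atoms$resno <= base + n_res)
}

helix_axis_info <- function(atoms, idx) {
  ca <- atoms[idx, ][atoms$elety[idx] == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  ax <- principal_axis(xyz, ref_dir = c(0, 0, 1))   # oriented extracellular
  list(axis = ax, ca = ca, xyz = xyz)
}

rotate_rows <- function(atoms, idx, R, origin) {
  xyz <- as.matrix(atoms[idx, c("x", "y", "z")])
  xyz <- t(R %*% (t(xyz) - origin)) + matrix(origin, length(idx), 3, byrow = TRUE)
  atoms[idx, c("x", "y", "z")] <- xyz
  atoms
}

translate_rows <- function(atoms, idx, v) {
  atoms[idx, "x"] <- atoms[idx, "x"] + v[1]
  atoms[idx, "y"] <- atoms[idx, "y"] + v[2]
  atoms[idx, "z"] <- atoms[idx, "z"] + v[3]
  atoms
}

spin_helix <- function(atoms, idx, deg) {
  h <- helix_axis_info(atoms, idx)
  rotate_rows(atoms, idx, rot_axis_angle(h$axis$dir, deg), h$axis$centre)
}

atom_coord <- function(atoms, resno, elety) {
  r <- atoms[atoms$resno == resno & atoms$elety == elety, c("x", "y", "z")]
  if (nrow(r) == 0) return(NULL)
  as.numeric(r[1, ])
}

# spin a helix so the CB of `resno` faces `target` (projection onto the
# plane perpendicular to the helix axis)
aim_residue <- function(atoms, idx, resno, target) {
  h <- helix_axis_info(atoms, idx)
  ca <- atom_coord(atoms, resno, "CA")
  cb <- atom_coord(atoms, resno, "CB")
  if (is.null(cb)) return(atoms)     # glycine: nothing to aim
  proj <- function(v) v - sum(v * h$axis$dir) * h$axis$dir
  cur <- proj(cb - ca); des <- proj(target - ca)
  if (sqrt(sum(cur^2)) < 1e-6 || sqrt(sum(des^2)) < 1e-6) return(atoms)
  ang <- atan2(sum(cross3(cur, des) * h$axis$dir), sum(cur * des)) * 180 / pi
  spin_helix(atoms, idx, ang)
}

contact_atoms <- function(atoms, resno, partner_type, own_type) {
  res <- atoms[atoms$resno == resno, , drop = FALSE]
  typing <- atom_typing(include_backbone = FALSE)
  pos <- role_atoms(res, "positive", typing)
  neg <- role_atoms(res, "negative", typing)
  charged_pair <- (nrow(pos) > 0 &&
                   partner_type %in% names(ATOM_TYPING$negative)) ||
                  (nrow(neg) > 0 &&
                   partner_type %in% names(ATOM_TYPING$positive))
  if (charged_pair) {
    if (nrow(pos) > 0) pos else neg
  } else {
    sc <- res[!res$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    if (nrow(sc) == 0) res[res$elety == "CA", , drop = FALSE] else sc
  }
}

realize_contact <- function(atoms, f, n_res) {
  h_a <- (f$resno_a %/% 100L); h_b <- (f$resno_b %/% 100L)
  idx_a <- helix_atoms_idx(atoms, h_a, n_res)
  idx_b <- helix_atoms_idx(atoms, h_b, n_res)
  if (!isFALSE(f$aim_a)) {
    atoms <- aim_residue(atoms, idx_a, f$resno_a,
                         atom_coord(atoms, f$resno_b, "CA"))
  }
  if (!isFALSE(f$aim_b)) {
    atoms <- aim_residue(atoms, idx_b, f$resno_b,
                         atom_coord(atoms, f$resno_a, "CA"))
  }
  for (it in 1:6) {
    A <- contact_atoms(atoms, f$resno_a, f$type_b, f$type_a)
    B <- contact_atoms(atoms, f$resno_b, f$type_a, f$type_b)
    m <- min_cross_distance(A, B)
    if (abs(m$d - f$target_A) < 0.02) break
    pa <- as.numeric(A[A$elety == m$atom_a, c("x", "y", "z")][1, ])
    pb <- as.numeric(B[B$elety == m$atom_b, c("x", "y", "z")][1, ])
    atoms <- translate_rows(atoms, idx_b, unit(pa - pb) * (m$d - f$target_A))
  }
  atoms
}

#' Build a synthetic helix bundle
#'
#' @param spec a [bundle_spec()].
#' @return list with `model` (`tmd_structure`), `tm` (`tm_annotation`),
#'   `map` (`bw_map`), `anchors`, `spec`.
#' @export
build_bundle <- function(spec) {
  n <- spec$residues_per_helix
  nh <- spec$n_helices
  types <- spec$residue_types
  for (f in spec$features) {
    if (f$type == "contact") {
      types[as.character(f$resno_a)] <- f$type_a
      types[as.character(f$resno_b)] <- f$type_b
    }
  }
  bulge_by_helix <- list()
  for (f in spec$features) {
    if (f$type == "bulge") bulge_by_helix[[as.character(f$helix)]] <- f$resno
  }

  pieces <- list()
  for (k in seq_len(nh)) {
    base <- helix_resno_base(k)
    resnos <- base + seq_len(n)
    aa3 <- ifelse(is.na(types[as.character(resnos)]),
                  spec$default_type %||% "LEU", types[as.character(resnos)])
    aa1 <- paste(unname(AA3TO1[aa3]), collapse = "")
    hx <- if (!is.null(bulge_by_helix[[as.character(k)]])) {
      build_bulge_helix(n, bulge_by_helix[[as.character(k)]] - base,
                        sequence = aa1, resno_start = base + 1L)
    } else {
      build_ideal_helix(n, sequence = aa1, resno_start = base + 1L)
    }
    # centre on z, flip odd helices so their N terminus faces extracellular
    hx$z <- hx$z - mean(range(hx$z))
    if (k %% 2 == 1) {
      R <- rot_axis_angle(c(1, 0, 0), 180)
      xyz <- t(R %*% t(as.matrix(hx[, c("x", "y", "z")])))
      hx[, c("x", "y", "z")] <- xyz
    }
    az <- 2 * pi * (k - 1) / nh
    hx$x <- hx$x + spec$bundle_radius * cos(az)
    hx$y <- hx$y + spec$bundle_radius * sin(az)
    pieces[[k]] <- hx
  }
  atoms <- do.call(rbind, pieces)

  if (spec$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, spec$noise_sd)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, spec$noise_sd)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, spec$noise_sd)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }

  for (f in spec$features) {
    idx <- if (!is.null(f$helix)) helix_atoms_idx(atoms, f$helix, n) else NULL
    atoms <- switch(f$type,
      kink = {
        apex_ca <- atom_coord(atoms, f$resno, "CA")
        az <- 2 * pi * (f$helix - 1) / nh
        bend_axis <- c(cos(az), sin(az), 0)    # bend in the tangential plane
        sub <- idx[atoms$resno[idx] > f$resno]
        rotate_rows(atoms, sub, rot_axis_angle(bend_axis, f$angle_deg), apex_ca)
      },
      bulge = atoms,                            # already built into the helix
      spin = spin_helix(atoms, idx, f$deg),
      motion = {
        a2 <- translate_rows(atoms, idx, f$translation)
        if (f$spin_deg != 0) a2 <- spin_helix(a2, idx, f$spin_deg)
        a2
      },
      contact = realize_contact(atoms, f, n),
      stop("unknown feature type ", f$type))
  }

  ranges <- stats::setNames(
    lapply(seq_len(nh), function(k) c(helix_resno_base(k) + 1L,
                                      helix_resno_base(k) + n)),
    paste0("TM", seq_len(nh)))
  tm <- tm_annotation(ranges[paste0("TM", 1:7)], chain = "A",
                      ec_end_tm1 = "first")
  anchors <- structure(stats::setNames(vapply(1:7, bundle_anchor, numeric(1)),
                                       as.character(1:7)),
                       class = "bw_anchors")
  map <- assign_bw(tm, anchors)
  model <- as_tmd_structure(atoms, id = "synthetic_bundle",
                            source_format = "synthetic")
  list(model = model, tm = tm, map = map, anchors = anchors, spec = spec)
}

#' One planned end-displacement for [make_state_pair()]
#' @param helix helix index.
#' @param end "intracellular" or "extracellular".
#' @param radial outward (+) displacement from the bundle axis (Angstrom).
#' @param axial extracellular (+) displacement along the bundle axis.
#' @export
move_end <- function(helix, end = c("intracellular", "extracellular"),
                     radial = 0, axial = 0) {
  list(helix = helix, end = match.arg(end), radial = radial, axial = axial)
}

#' Build an inactive/active synthetic conformation pair
#'
#' The inactive state carries a planted Arg3.50-Asp6.30 ionic lock at
#' `lock_distance_A`, tyrosines at 7.53 and 5.58 aimed away from each other
#' (apart regime), and a lysine marker at 6.29. The active state is the
#' same bundle with the movement plan applied as per-helix rigid motions
#' (plus an optional spin of TM6 about its own axis) and, optionally, the
#' 7.53-5.58 tyrosine pair re-aimed and brought to `toggle_distance_A`.
#'
#' @param spec base [bundle_spec()] (7 helices).
#' @param moves list of [move_end()] displacements.
#' @param tm6_spin_deg axial rotation of TM6 in the active state (degrees,
#'   counter-clockwise viewed from the extracellular side).
#' @param toggle_distance_A target 7.53-5.58 side-chain distance in the
#'   active state (NULL: leave the tyrosines where the movements put them).
#' @param lock_distance_A planted ionic-lock distance in the inactive state.
#' @return list with `inactive`, `active` (`tmd_structure`), shared `tm`,
#'   `map`, `anchors`, and `plan`.
#' @export
make_state_pair <- function(spec, moves = list(), tm6_spin_deg = 0,
                            toggle_distance_A = NULL, lock_distance_A = 3.0) {
  n <- spec$residues_per_helix
  r350 <- bundle_resno("3.50"); r630 <- bundle_resno("6.30")
  r753 <- bundle_resno("7.53"); r558 <- bundle_resno("5.58")
  r629 <- bundle_resno("6.29")
  types <- spec$residue_types
  types[as.character(c(r753, r558))] <- "TYR"
  types[as.character(r629)] <- "LYS"
  spec_in <- bundle_spec(spec$n_helices, n, spec$bundle_radius, types,
                         features = c(spec$features,
                                      list(feat_contact(r350, r630,
                                                        lock_distance_A,
                                                        "ARG", "ASP"))),
                         noise_sd = spec$noise_sd, seed = spec$seed,
                         default_type = spec$default_type %||% "LEU")
  built <- build_bundle(spec_in)
  atoms_in <- built$model$atoms
  # aim the toggle tyrosines away from each other (inactive: apart)
  for (pair in list(c(5, r558, 7), c(7, r753, 5))) {
    idx <- helix_atoms_idx(atoms_in, pair[1], n)
    other <- helix_axis_info(atoms_in, helix_atoms_idx(atoms_in, pair[3], n))
    own <- helix_axis_info(atoms_in, idx)
    away <- own$axis$centre + (own$axis$centre - other$axis$centre)
    atoms_in <- aim_residue(atoms_in, idx, pair[2], away)
  }

  atoms_ac <- atoms_in
  by_helix <- split(moves, vapply(moves, function(m) m$helix, numeric(1)))
  for (h in names(by_helix)) {
    k <- as.integer(h)
    idx <- helix_atoms_idx(atoms_ac, k, n)
    info <- helix_axis_info(atoms_ac, idx)
    nres <- nrow(info$xyz)
    ends <- list(extracellular = NULL, intracellular = NULL)
    # terminal-turn mean positions, matching how movements are measured
    top <- colMeans(info$xyz[order(info$xyz[, 3], decreasing = TRUE)[1:4], ])
    bot <- colMeans(info$xyz[order(info$xyz[, 3])[1:4], ])
    q <- list(extracellular = top, intracellular = bot)
    disp <- list(extracellular = c(0, 0, 0), intracellular = c(0, 0, 0))
    for (m in by_helix[[h]]) {
      p <- q[[m$end]]
      radial_dir <- unit(c(p[1], p[2], 0))
      disp[[m$end]] <- disp[[m$end]] + m$radial * radial_dir +
        c(0, 0, m$axial)
    }
    v_old <- q$extracellular - q$intracellular
    v_new <- v_old + disp$extracellular - disp$intracellular
    R <- rotation_between(v_old, v_new)
    planned <- unique(vapply(by_helix[[h]], function(m) m$end, character(1)))
    if (length(planned) == 1) {
      # single-end plan: anchor the rigid map so that end lands exactly
      # (a rigid body cannot change the end-to-end length, so the midpoint
      # compromise would halve a single-end axial displacement)
      p <- q[[planned]] + disp[[planned]]
      tvec <- p - as.numeric(R %*% q[[planned]])
    } else {
      m_old <- (q$extracellular + q$intracellular) / 2
      m_new <- m_old + (disp$extracellular + disp$intracellular) / 2
      tvec <- m_new - as.numeric(R %*% m_old)
    }
    atoms_ac <- rotate_rows(atoms_ac, idx, R, c(0, 0, 0))
    atoms_ac <- translate_rows(atoms_ac, idx, tvec)
  }
  if (tm6_spin_deg != 0) {
    atoms_ac <- spin_helix(atoms_ac, helix_atoms_idx(atoms_ac, 6, n),
                           tm6_spin_deg)
  }
  if (!is.null(toggle_distance_A)) {
    atoms_ac <- realize_contact(atoms_ac,
                                feat_contact(r558, r753, toggle_distance_A,
                                             "TYR", "TYR"), n)
  }
  list(inactive = as_tmd_structure(atoms_in, "synthetic_inactive", "synthetic"),
       active = as_tmd_structure(atoms_ac, "synthetic_active", "synthetic"),
       tm = built$tm, map = built$map, anchors = built$anchors,
       plan = list(moves = moves, tm6_spin_deg = tm6_spin_deg,
                   toggle_distance_A = toggle_distance_A,
                   lock_distance_A = lock_distance_A))
}
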