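# Local helix-axis fitting and distortion detection.
#
# The axis of a helix is traced by sliding a short window along the CA
# coordinates and taking the principal axis of each window (oriented N->C);
# a kink is a large angle between axis directions of windows separated by
# one window length. An alpha-bulge is detected from the backbone
# hydrogen-bond registry: the defining feature is the shift of the
# i -> i+4 carbonyl-O/amide-N pairing to i -> i+5, which is computable from
# heavy atoms alone (O...N <= 3.5 A), so no hydrogens are required.

#' Fit local helix axes over sliding windows of CA atoms
#'
#' @param ca matrix (n x 3) of consecutive CA coordinates (N- to C-terminal
#'   order).
#' @param resno author numbers aligned with the rows of `ca` (default 1..n).
#' @param window_size odd window length (residues).
#' @return object of class `helix_axis`: list with `window_centres`
#'   (residue numbers), `centre_idx` (row indices), `axis_points` (window
#'   centroids), `axis_dirs` (unit vectors, N->C), `window_size`.
#' @export
fit_helix_axis <- function(ca, resno = NULL, window_size = 7) {
  ca <- as.matrix(ca)
  if (window_size %% 2 != 1 || window_size < 3) stop("window_size must be odd >= 3")
  n <- nrow(ca)
  if (n < window_size) {
    stop(sprintf("insufficient data: %d residues for window of %d", n, window_size))
  }
  if (is.null(resno)) resno <- seq_len(n)
  half <- (window_size - 1) / 2
  centres <- seq(half + 1, n - half)
  dirs <- matrix(NA_real_, length(centres), 3)
  pts <- matrix(NA_real_, length(centres), 3)
  for (j in seq_along(centres)) {
    i <- centres[j]
    w <- ca[(i - half):(i + half), , drop = FALSE]
    # second differences point radially toward the local axis; crossing
    # consecutive ones yields the axis direction exactly for an ideal
    # helix, which keeps short windows usable
    m <- nrow(w)
    u <- w[1:(m - 2), , drop = FALSE] - 2 * w[2:(m - 1), , drop = FALSE] +
      w[3:m, , drop = FALSE]
    acc <- c(0, 0, 0)
    chain_dir <- w[m, ] - w[1, ]
    for (k in seq_len(nrow(u) - 1)) {
      a <- cross3(u[k, ], u[k + 1, ])
      na <- sqrt(sum(a^2))
      if (na < 1e-12) next
      a <- a / na
      if (sum(a * chain_dir) < 0) a <- -a
      acc <- acc + a
    }
    if (sqrt(sum(acc^2)) < 1e-12) acc <- chain_dir
    dirs[j, ] <- acc / sqrt(sum(acc^2))
    pts[j, ] <- colMeans(w)
  }
  structure(list(window_centres = resno[centres], centre_idx = centres,
                 axis_points = pts, axis_dirs = dirs,
                 window_size = window_size),
            class = "helix_axis")
}

angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Detect a kink from fitted helix axes
#'
#' The kink angle is the maximum angle between axis directions of windows
#' separated by one window length (so the two windows share no residues and
#' straddle the putative apex). A kink is called when that angle reaches
#' `threshold_deg`; ideal helices stay below ~5 degrees and canonical
#' proline kinks run ~20-35 degrees, so the default threshold separates the
#' two cleanly.
#'
#' @param axis a `helix_axis`.
#' @param threshold_deg kink-calling threshold (degrees).
#' @param helix helix name carried into the report.
#' @return data.frame of class `distortion_report`: `helix`, `kind`
#'   ("kink" or "none"), `apex_resno`, `angle_deg`, `evidence`.
#' @export
detect_kink <- function(axis, threshold_deg = 15, helix = NA_character_) {
  nw <- length(axis$window_centres)
  gap <- axis$window_size
  if (nw < 2) stop("need at least 2 axis windows")
  best <- c(angle = -1, i = NA)
  for (i in seq_len(nw)) {
    j <- i + gap
    if (j > nw) break
    a <- angle_deg(axis$axis_dirs[i, ], axis$axis_dirs[j, ])
    if (a > best["angle"]) best <- c(angle = a, i = i)
  }
  if (best[["angle"]] < 0) {
    # helix shorter than two disjoint windows: fall back to the extreme pair
    best <- c(angle = angle_deg(axis$axis_dirs[1, ], axis$axis_dirs[nw, ]), i = 1)
    gap <- nw - 1
  }
  i <- best[["i"]]
  apex <- round((axis$window_centres[i] + axis$window_centres[min(i + gap, nw)]) / 2)
  kind <- if (best[["angle"]] >= threshold_deg) "kink" else "none"
  structure(data.frame(helix = helix, kind = kind, apex_resno = apex,
                       angle_deg = best[["angle"]],
                       evidence = sprintf("max inter-window axis angle %.1f deg",
                                          best[["angle"]])),
            class = c("distortion_report", "data.frame"))
}

#' Detect an alpha-bulge from backbone hydrogen-bond registry
#'
#' Scans carbonyl O(i) against amide N(i+4) and N(i+5) (heavy-atom distance
#' <= `hbond_cut`). A bulge is reported where the i->i+4 pairing is broken
#' and replaced by i->i+5 for at least one residue; the apex is the first
#' registry-shifted residue.
#'
#' @param model a `tmd_structure`.
#' @param chain chain id.
#' @param range inclusive `c(start, end)` author-number range of the helix.
#' @param hbond_cut O...N distance cutoff (Angstrom).
#' @param helix helix name carried into the report.
#' @return a `distortion_report` (kind "bulge" or "none").
#' @export
detect_bulge <- function(model, chain, range, hbond_cut = 3.5,
                         helix = NA_character_) {
  res <- seq(range[1], range[2])
  getO <- function(n) {
    a <- get_residue(model, chain, n)
    a[a$elety == "O", c("x", "y", "z"), drop = FALSE]
  }
  getN <- function(n) {
    a <- get_residue(model, chain, n)
    a[a$elety == "N", c("x", "y", "z"), drop = FALSE]
  }
  shifted <- logical(0)
  shifted_res <- integer(0)
  for (n in res) {
    if (n + 5 > range[2]) break
    O <- getO(n); N4 <- getN(n + 4); N5 <- getN(n + 5)
    if (nrow(O) == 0 || nrow(N4) == 0 || nrow(N5) == 0) {
      warning("missing backbone atoms near residue ", n, "; skipped")
      next
    }
    d4 <- sqrt(sum((as.numeric(O) - as.numeric(N4))^2))
    d5 <- sqrt(sum((as.numeric(O) - as.numeric(N5))^2))
    shifted <- c(shifted, d4 > hbond_cut && d5 <= hbond_cut)
    shifted_res <- c(shifted_res, n)
  }
  if (any(shifted)) {
    apex <- shifted_res[which(shifted)[1]]
    structure(data.frame(helix = helix, kind = "bulge", apex_resno = apex,
                         angle_deg = NA_real_,
                         evidence = sprintf(
                           "O(i)->N(i+4) registry replaced by i+5 at %s",
                           paste(shifted_res[shifted], collapse = ","))),
              class = c("distortion_report", "data.frame"))
  } else {
    structure(data.frame(helix = helix, kind = "none", apex_resno = NA_integer_,
                         angle_deg = NA_real_,
                         evidence = "i->i+4 registry intact"),
              class = c("distortion_report", "data.frame"))
  }
}

#' Kink and bulge survey over all annotated helices
#'
#' @param model a `tmd_structure`.
#' @param tm a `tm_annotation`.
#' @param window_size,threshold_deg passed to the kink detector.
#' @return data.frame with one kink row and one bulge row per helix.
#' @export
helix_distortions <- function(model, tm, window_size = 7, threshold_deg = 15) {
  out <- list()
  for (h in names(tm$ranges)) {
    r <- tm$ranges[[h]]
    ca <- helix_ca(model, tm$chain, r)
    if (nrow(ca$xyz) >= window_size) {
      ax <- fit_helix_axis(ca$xyz, ca$resno, window_size)
      out[[paste0(h, "_kink")]] <- detect_kink(ax, threshold_deg, helix = h)
    }
    out[[paste0(h, "_bulge")]] <- detect_bulge(model, tm$chain, r, helix = h)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# CA coordinates (and numbers) of one helix, ordered by residue number
helix_ca <- function(model, chain, range) {
  a <- model$atoms
  sel <- a$chain == chain & a$elety == "CA" &
    a$resno >= range[1] & a$resno <= range[2]
  a <- a[sel, , drop = FALSE]
  a <- a[order(a$resno, a$icode), , drop = FALSE]
  list(xyz = as.matrix(a[, c("x", "y", "z")]), resno = a$resno)
}
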