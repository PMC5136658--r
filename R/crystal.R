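# Crystal-template analyses: TM annotations for the class A receptor
# entries used as modelling templates, and the inactive/active distance
# comparisons between the TM7 position 7.40 and TM1 position 1.39.
#
# The annotations carry explicit 1.50/4.50/5.50 anchor overrides (standard
# Ballesteros-Weinstein assignments for these receptors); the motif-borne
# anchors (2.50, 3.50, 6.50, 7.50) are re-derived from the coordinates'
# own sequence at run time.

CRYSTAL_CONFIG <- list(
  `1u19` = list(chain = "A", state = "inactive", receptor = "rhodopsin",
                ranges = list(TM1 = c(35, 64), TM2 = c(71, 100),
                              TM3 = c(107, 139), TM4 = c(151, 173),
                              TM5 = c(200, 229), TM6 = c(247, 277),
                              TM7 = c(285, 309)),
                overrides = c(`1` = 55, `4` = 161, `5` = 215)),
  `3pqr` = list(chain = "A", state = "active", receptor = "metarhodopsin II",
                ranges = list(TM1 = c(35, 64), TM2 = c(71, 100),
                              TM3 = c(107, 139), TM4 = c(151, 173),
                              TM5 = c(200, 229), TM6 = c(247, 277),
                              TM7 = c(285, 309)),
                overrides = c(`1` = 55, `4` = 161, `5` = 215)),
  `2rh1` = list(chain = "A", state = "inactive", receptor = "beta2 adrenergic",
                ranges = list(TM1 = c(29, 60), TM2 = c(67, 96),
                              TM3 = c(103, 136), TM4 = c(147, 171),
                              TM5 = c(197, 229), TM6 = c(267, 298),
                              TM7 = c(305, 329)),
                overrides = c(`1` = 51, `4` = 158, `5` = 211)),
  `3sn6` = list(chain = "R", state = "active", receptor = "beta2 adrenergic",
                ranges = list(TM1 = c(29, 60), TM2 = c(67, 96),
                              TM3 = c(103, 136), TM4 = c(147, 171),
                              TM5 = c(197, 229), TM6 = c(267, 298),
                              TM7 = c(305, 329)),
                overrides = c(`1` = 51, `4` = 158, `5` = 211)),
  `3uon` = list(chain = "A", state = "inactive", receptor = "M2 muscarinic",
                ranges = list(TM1 = c(20, 50), TM2 = c(56, 85),
                              TM3 = c(91, 126), TM4 = c(138, 162),
                              TM5 = c(185, 216), TM6 = c(383, 412),
                              TM7 = c(418, 446)),
                overrides = c(`1` = 41, `4` = 148, `5` = 198)),
  `4mqs` = list(chain = "A", state = "active", receptor = "M2 muscarinic",
                ranges = list(TM1 = c(20, 50), TM2 = c(56, 85),
                              TM3 = c(91, 126), TM4 = c(138, 162),
                              TM5 = c(185, 216), TM6 = c(383, 412),
                              TM7 = c(418, 446)),
                overrides = c(`1` = 41, `4` = 148, `5` = 198))
)

#' TM annotation config for a crystal template entry
#' @param accession one of 1U19, 3PQR, 2RH1, 3SN6, 3UON, 4MQS.
#' @return list with `tm` (a `tm_annotation`), `overrides`, `chain`,
#'   `state`, `receptor`.
#' @export
crystal_tm_annotation <- function(accession) {
  cfg <- CRYSTAL_CONFIG[[tolower(accession)]]
  if (is.null(cfg)) stop("no packaged annotation for ", accession)
  list(tm = tm_annotation(cfg$ranges, chain = cfg$chain, ec_end_tm1 = "first"),
       overrides = cfg$overrides, chain = cfg$chain, state = cfg$state,
       receptor = cfg$receptor)
}

#' Motif-anchored BW map of a crystal structure
#' @param model a `tmd_structure` of one of the template entries.
#' @param accession its PDB id (selects the packaged annotation).
#' @return list with `map`, `anchors`, `tm`.
#' @export
crystal_bw_map <- function(model, accession) {
  cfg <- crystal_tm_annotation(accession)
  s <- chain_sequence(model, cfg$chain)
  anchors <- infer_anchors(s$sequence, s$numbering, cfg$tm,
                           overrides = cfg$overrides)
  list(map = assign_bw(cfg$tm, anchors), anchors = anchors, tm = cfg$tm)
}

#' Inactive/active distance comparison at positions 7.40 and 1.39
#'
#' For each template entry found in `dir` (as `<accession>.pdb`), measures
#' the side-chain minimum and the CA distance between the residues at BW
#' 7.40 and 1.39, and for the active rhodopsin entry also the 7.53-5.58
#' tyrosine side-chain distance. Entries not present are downloaded when
#' `fetch = TRUE`.
#'
#' @param dir directory holding (or receiving) the PDB files.
#' @param accessions entries to analyse.
#' @param fetch download missing entries from the public archive.
#' @param timeout per-download timeout (seconds).
#' @return data.frame: accession, receptor, state, `sidechain_A`, `ca_A`,
#'   `tyr_toggle_A` (NA except for metarhodopsin II).
#' @export
crystal_distance_report <- function(dir = "scratch/pdb",
                                    accessions = c("1u19", "3pqr", "2rh1",
                                                   "3sn6", "3uon", "4mqs"),
                                    fetch = TRUE, timeout = 30) {
  rows <- list()
  for (acc in tolower(accessions)) {
    path <- file.path(dir, paste0(acc, ".pdb"))
    if (!file.exists(path)) {
      if (!fetch) stop("missing structure file ", path)
      path <- fetch_pdb(acc, dir, timeout = timeout)
    }
    model <- read_structure(path)
    bw <- crystal_bw_map(model, acc)
    cfg <- crystal_tm_annotation(acc)
    res <- function(lab) get_residue(model, cfg$chain, bw_residue(bw$map, lab))
    sc <- suppressWarnings(pair_distance(res("7.40"), res("1.39"),
                                         "min_sidechain_heavy"))
    ca <- pair_distance(res("7.40"), res("1.39"), "ca")
    tog <- if (acc == "3pqr") {
      suppressWarnings(pair_distance(res("7.53"), res("5.58"),
                                     "min_sidechain_heavy"))
    } else NA_real_
    rows[[acc]] <- data.frame(accession = toupper(acc),
                              receptor = cfg$receptor, state = cfg$state,
                              sidechain_A = sc, ca_A = ca, tyr_toggle_A = tog)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
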