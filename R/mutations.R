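# Interaction-based rationalization of receptor mutations.
#
# The annotator is deliberately heuristic and qualitative: it compares the
# chemical capabilities of the wild-type and mutant side chains against the
# residue's observed interaction environment in the inactive and the active
# conformation, scores each conformation, and predicts which state the
# mutation stabilizes (never a fold change). Side-chain reach comes from an
# idealized maximum-extension table; induced-dipole and weak-hydrophobic
# contributions count at half weight.

# capability sets (three-letter codes)
CAP_POSITIVE <- c("ARG", "LYS")
CAP_NEGATIVE <- c("ASP", "GLU")
CAP_POLAR <- c("ARG", "LYS", "ASP", "GLU", "ASN", "GLN", "HIS", "SER",
               "THR", "TYR", "TRP")
CAP_AROMATIC <- c("PHE", "TYR", "TRP", "HIS")
CAP_HYDROPHOBIC <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP",
                     "TYR", "PRO", "CYS")

# idealized side-chain maximum extension, CA to farthest heavy atom (A)
SIDECHAIN_REACH <- c(GLY = 0, ALA = 1.5, SER = 2.4, CYS = 2.8, THR = 2.6,
                     VAL = 2.5, LEU = 3.9, ILE = 3.9, PRO = 2.4, MET = 5.3,
                     ASP = 3.6, ASN = 3.6, GLU = 5.0, GLN = 5.0, LYS = 6.3,
                     ARG = 7.3, HIS = 4.5, PHE = 4.9, TYR = 6.4, TRP = 6.0)

TIER_WEIGHT <- c(salt_bridge = 1, hbond = 1, weak_polar = 0.75, aromatic = 1,
                 hydrophobic_strong = 1, hydrophobic_weak = 0.5,
                 induced_dipole = 0.5, water_mediated_possible = 0,
                 none = 0)

#' Load the packaged mutation-phenotype tables
#'
#' Six tables of activating and inactivating/silencing mutations of the
#' glycoprotein hormone receptors, transcribed row-for-row from the
#' published compilations (stored verbatim; BW labels are never
#' cross-checked between receptors).
#'
#' @param receptor optionally restrict to "TSHR", "FSHR" or "LHR".
#' @return data.frame: `receptor`, `mutation`, `bw`, `category` ("CAM",
#'   "activating", "inactivating", "silencing"), `activity` (verbatim),
#'   `activity_fold_wt` (parsed, NA when not reported), `source_table`.
#' @export
load_phenotype_tables <- function(receptor = NULL) {
  path <- system.file("extdata", "phenotype_tables.tsv", package = "gphrtmd")
  if (path == "") path <- file.path("inst", "extdata", "phenotype_tables.tsv")
  if (!file.exists(path)) stop("packaged phenotype tables not found")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("receptor", "mutation", "bw", "category", "activity",
            "activity_fold_wt", "source_table")
  if (!all(need %in% names(tab))) stop("malformed phenotype table file")
  if (!all(tab$category %in% c("CAM", "activating", "inactivating",
                               "silencing"))) {
    stop("malformed phenotype table: unknown category")
  }
  if (!is.null(receptor)) tab <- tab[tab$receptor == receptor, , drop = FALSE]
  tab
}

#' Look up one mutation in the phenotype tables
#' @param receptor "TSHR", "FSHR" or "LHR".
#' @param mutation e.g. "L512R".
#' @return one-row data.frame, or zero rows when absent.
#' @export
lookup_phenotype <- function(receptor, mutation) {
  tab <- load_phenotype_tables(receptor)
  tab[tab$mutation == mutation, , drop = FALSE]
}

parse_mutation <- function(mutation) {
  m <- regmatches(mutation, regexec("^([A-Z])([0-9]+)([A-Z])$", mutation))[[1]]
  if (length(m) != 4) stop("cannot parse mutation string: ", mutation)
  wt1 <- AA1TO3[m[2]]; mut1 <- AA1TO3[m[4]]
  if (is.na(wt1) || is.na(mut1)) stop("unknown residue code in ", mutation)
  list(wt = unname(wt1), resno = as.integer(m[3]), mut = unname(mut1))
}

#' Build a mutation profile object from explicit interaction tables
#'
#' Used both by [wt_interaction_profile()] and directly in tests or
#' analyses that engineer a residue's environment. Each state table needs
#' `partner_type` (three-letter), `tier` (interaction tier, "none" for a
#' non-interacting neighbour) and `distance_A`.
#'
#' @param wt_type three-letter wild-type residue.
#' @param inactive,active state tables (data.frames).
#' @param resno optional author number.
#' @return object of class `mutation_profiles`.
#' @export
mutation_profile <- function(wt_type, inactive, active, resno = NA_integer_) {
  chk <- function(d) {
    if (nrow(d) > 0 &&
        !all(c("partner_type", "tier", "distance_A") %in% names(d))) {
      stop("profile tables need partner_type, tier, distance_A")
    }
    d
  }
  structure(list(wt_type = wt_type, resno = resno,
                 inactive = chk(inactive), active = chk(active)),
            class = "mutation_profiles")
}

#' Interaction profile of a wild-type residue in both conformations
#'
#' Collects the residue's classified contacts plus non-interacting
#' neighbours (side-chain minimum distance below `neighbor_cut`) in the
#' inactive and active structures.
#'
#' @param residue BW label ("3.43") or author number.
#' @param inactive,active `tmd_structure` conformation pair.
#' @param map_in,map_ac BW maps (map_ac defaults to map_in).
#' @param typing,cutoffs see [classify_pair()].
#' @param neighbor_cut neighbour inclusion distance (Angstrom).
#' @return a `mutation_profiles` object; one-sided (with a flag) when the
#'   residue is unresolved in one state.
#' @export
wt_interaction_profile <- function(residue, inactive, active, map_in,
                                   map_ac = map_in, typing = atom_typing(),
                                   cutoffs = interaction_cutoffs(),
                                   neighbor_cut = 6.5) {
  state_profile <- function(model, map) {
    chain <- map$chain[1]
    resno <- if (is.character(residue)) bw_residue(map, residue) else residue
    res <- get_residue(model, chain, resno)
    if (nrow(res) == 0) return(NULL)
    rows <- list()
    for (other in setdiff(intersect(map$resno, unique(model$atoms$resno)), resno)) {
      if (map$helix[match(other, map$resno)] ==
          map$helix[match(resno, map$resno)] && abs(other - resno) <= 4) next
      o <- get_residue(model, chain, other)
      ca_d <- tryCatch(pair_distance(res, o, "ca"), error = function(e) Inf)
      if (ca_d > 18) next
      rec <- classify_pair(res, o, typing, cutoffs)
      scd <- suppressWarnings(pair_distance(res, o, "min_sidechain_heavy"))
      if (rec$is_contact) {
        rows[[length(rows) + 1]] <- data.frame(
          partner = other, partner_bw = bw_label(map, other),
          partner_type = o$resname[1], tier = rec$tier,
          distance_A = rec$distance_A)
      } else if (scd <= neighbor_cut) {
        rows[[length(rows) + 1]] <- data.frame(
          partner = other, partner_bw = bw_label(map, other),
          partner_type = o$resname[1], tier = "none", distance_A = scd)
      }
    }
    if (length(rows) == 0) {
      data.frame(partner = integer(), partner_bw = character(),
                 partner_type = character(), tier = character(),
                 distance_A = numeric())
    } else do.call(rbind, rows)
  }
  p_in <- state_profile(inactive, map_in)
  p_ac <- state_profile(active, map_ac)
  if (is.null(p_in) && is.null(p_ac)) stop("residue unresolved in both states")
  one_sided <- is.null(p_in) || is.null(p_ac)
  if (one_sided) warning("residue unresolved in one state; one-sided profile")
  empty <- data.frame(partner = integer(), partner_bw = character(),
                      partner_type = character(), tier = character(),
                      distance_A = numeric())
  resno_in <- if (is.character(residue)) bw_residue(map_in, residue) else residue
  wt_res <- get_residue(if (is.null(p_in)) active else inactive,
                        map_in$chain[1], resno_in)
  prof <- mutation_profile(wt_res$resname[1], p_in %||% empty, p_ac %||% empty,
                           resno = resno_in)
  attr(prof, "one_sided") <- one_sided
  prof
}

# best achievable interaction weight between a residue type and one
# partner row, using reach-adjusted distances
achievable_weight <- function(own, partner, d, wt) {
  reach_gain <- max(0, SIDECHAIN_REACH[[own]] - SIDECHAIN_REACH[[wt]])
  d_polar <- max(2.8, d - reach_gain)
  d_hyd <- max(2.8, d + SIDECHAIN_REACH[[wt]] - SIDECHAIN_REACH[[own]])
  w <- 0
  opp_charge <- (own %in% CAP_POSITIVE && partner %in% CAP_NEGATIVE) ||
                (own %in% CAP_NEGATIVE && partner %in% CAP_POSITIVE)
  if (opp_charge && d_polar <= 4.0) w <- max(w, TIER_WEIGHT[["salt_bridge"]])
  if (own %in% CAP_POLAR && partner %in% CAP_POLAR) {
    if (d_polar <= 3.5) w <- max(w, TIER_WEIGHT[["hbond"]])
    else if (d_polar <= 4.0) w <- max(w, TIER_WEIGHT[["weak_polar"]])
  }
  if (own %in% CAP_AROMATIC && partner %in% CAP_AROMATIC && d_hyd <= 4.5) {
    w <- max(w, TIER_WEIGHT[["aromatic"]])
  }
  if (own %in% CAP_HYDROPHOBIC && partner %in% CAP_HYDROPHOBIC) {
    if (d_hyd <= 4.0) w <- max(w, TIER_WEIGHT[["hydrophobic_strong"]])
    else if (d_hyd <= 4.5) w <- max(w, TIER_WEIGHT[["hydrophobic_weak"]])
  }
  polar_vs_apolar <-
    (own %in% CAP_POLAR && partner %in% CAP_HYDROPHOBIC && d_polar <= 4.5) ||
    (own %in% CAP_HYDROPHOBIC && partner %in% CAP_POLAR && d_hyd <= 4.5)
  if (polar_vs_apolar) w <- max(w, TIER_WEIGHT[["induced_dipole"]])
  unname(w)
}

#' Predict the conformational effect of a point mutation
#'
#' Scores the mutant against the wild-type interaction environment in each
#' conformation: interactions the mutant side chain can no longer support
#' count as losses, chemically enabled interactions within reach-adjusted
#' distance bands count as gains, and the conformation with the higher net
#' change is called as the stabilized state. The prediction is a direction
#' only, matching the qualitative reasoning style the profiles support.
#'
#' @param mutation mutation string, e.g. "L512R" (wild type must match the
#'   profile).
#' @param profiles a `mutation_profiles` object.
#' @param category optional phenotype category ("CAM", "activating",
#'   "inactivating", "silencing") for the consistency verdict.
#' @return object of class `mutation_effect`: mutation, per-state net
#'   scores, `stabilization_call` ("active", "inactive", "neutral"),
#'   `phenotype_consistency` ("consistent", "inconsistent", "untestable").
#' @export
predict_mutation_effect <- function(mutation, profiles, category = NULL) {
  mt <- parse_mutation(mutation)
  if (mt$wt != profiles$wt_type) {
    stop("mutation wild type ", mt$wt, " does not match profile (",
         profiles$wt_type, ")")
  }
  state_delta <- function(tab) {
    if (nrow(tab) == 0) return(0)
    sum(vapply(seq_len(nrow(tab)), function(i) {
      achievable_weight(mt$mut, tab$partner_type[i], tab$distance_A[i], mt$wt) -
        TIER_WEIGHT[[tab$tier[i]]]
    }, numeric(1)))
  }
  identity_sub <- mt$wt == mt$mut
  d_in <- if (identity_sub) 0 else state_delta(profiles$inactive)
  d_ac <- if (identity_sub) 0 else state_delta(profiles$active)
  call <- if (identity_sub || abs(d_ac - d_in) < 1e-9) "neutral"
          else if (d_ac > d_in) "active" else "inactive"
  consistency <- if (is.null(category) || call == "neutral") "untestable"
                 else if (call == "active" && category %in% c("CAM", "activating"))
                   "consistent"
                 else if (call == "inactive" &&
                          category %in% c("silencing", "inactivating"))
                   "consistent"
                 else "inconsistent"
  structure(list(mutation = mutation, wt_type = mt$wt, mut_type = mt$mut,
                 net_inactive = d_in, net_active = d_ac,
                 stabilization_call = call,
                 phenotype_consistency = consistency),
            class = "mutation_effect")
}

#' @export
print.mutation_effect <- function(x, ...) {
  cat(sprintf("%s: net inactive %+.2f, net active %+.2f -> stabilizes %s (%s)\n",
              x$mutation, x$net_inactive, x$net_active, x$stabilization_call,
              x$phenotype_consistency))
  invisible(x)
}
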