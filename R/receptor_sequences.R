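# Packaged glycoprotein hormone receptor TMD sequences.
#
# These are SYNTHETIC pinned-residue reconstructions, not the genuine
# full-length UniProt sequences. Every residue identity that published
# mutation tables and motif annotations place at a specific author number
# (motif residues, anchor residues, mutated positions) sits at that number;
# all remaining positions are neutral leucine filler chosen so that no
# spurious motif hit or anchor candidate is created. Ballesteros-Weinstein
# anchoring and label arithmetic depend only on the pinned positions, so the
# numbering produced from these reconstructions matches the numbering of the
# real receptors at every annotated site.

GPHR_PINS <- list(
  TSHR = c(`421` = "V", `424` = "V", `432` = "N", `455` = "N", `456` = "L",
           `460` = "D", `466` = "Y", `467` = "L", `468` = "L", `486` = "I",
           `488` = "W", `499` = "F", `501` = "T", `502` = "V", `508` = "S",
           `509` = "V", `512` = "L", `513` = "T", `518` = "E", `519` = "R",
           `520` = "W", `527` = "M", `546` = "W", `554` = "L", `556` = "P",
           `582` = "Y", `593` = "A", `594` = "F", `601` = "Y", `608` = "V",
           `618` = "K", `619` = "D", `625` = "R", `629` = "L", `630` = "I",
           `631` = "F", `632` = "T", `633` = "D", `634` = "F", `636` = "C",
           `637` = "M", `638` = "A", `639` = "P", `641` = "S", `642` = "F",
           `643` = "Y", `644` = "A", `645` = "L", `665` = "L", `670` = "N",
           `671` = "S", `674` = "N", `675` = "P", `678` = "Y"),
  FSHR = c(`385` = "N", `401` = "M", `403` = "N", `404` = "L", `408` = "D",
           `418` = "I", `419` = "A", `447` = "F", `449` = "T", `460` = "L",
           `466` = "E", `467` = "R", `468` = "W", `494` = "W", `502` = "L",
           `519` = "P", `545` = "I", `549` = "A", `553` = "Y", `567` = "D",
           `573` = "R", `574` = "M", `575` = "A", `578` = "I", `580` = "T",
           `584` = "C", `585` = "M", `587` = "P", `601` = "L", `622` = "N",
           `623` = "P", `626` = "Y"),
  LHR  = c(`373` = "A", `374` = "I", `377` = "N", `392` = "T", `398` = "M",
           `400` = "N", `401` = "L", `405` = "D", `444` = "F", `457` = "L",
           `463` = "E", `464` = "R", `465` = "W", `491` = "W", `499` = "M",
           `528` = "I", `538` = "A", `542` = "I", `543` = "C", `564` = "D",
           `568` = "A", `571` = "M", `572` = "A", `575` = "I", `577` = "T",
           `578` = "D", `581` = "C", `582` = "M", `584` = "P", `593` = "A",
           `615` = "N", `616` = "S", `619` = "N", `620` = "P", `623` = "Y",
           `625` = "I")
)

GPHR_SPAN <- list(TSHR = c(410, 690), FSHR = c(365, 640), LHR = c(360, 640))

GPHR_TM <- list(
  TSHR = list(TM1 = c(417, 444), TM2 = c(449, 474), TM3 = c(494, 525),
              TM4 = c(535, 560), TM5 = c(578, 608), TM6 = c(614, 645),
              TM7 = c(658, 683)),
  FSHR = list(TM1 = c(371, 395), TM2 = c(397, 422), TM3 = c(442, 473),
              TM4 = c(483, 508), TM5 = c(534, 560), TM6 = c(562, 593),
              TM7 = c(606, 631)),
  LHR  = list(TM1 = c(363, 391), TM2 = c(394, 419), TM3 = c(439, 470),
              TM4 = c(480, 505), TM5 = c(523, 553), TM6 = c(559, 593),
              TM7 = c(603, 628))
)

# The glycoprotein hormone receptors carry Ala, not the class A consensus
# Pro, at position 5.50, so the TM5 anchor cannot be motif-detected and is
# supplied explicitly (TSHR Ala593, FSHR Ala549, LHR Ala538).
GPHR_ANCHOR_OVERRIDES <- list(TSHR = c(`5` = 593), FSHR = c(`5` = 549),
                              LHR = c(`5` = 538))

#' Packaged receptor TMD sequence (synthetic pinned reconstruction)
#'
#' Returns the transmembrane-domain sequence of a glycoprotein hormone
#' receptor as a pinned-residue reconstruction: annotated residues at their
#' published author numbers, leucine filler elsewhere (see file header).
#'
#' @param receptor "TSHR", "FSHR" or "LHR".
#' @return list with `sequence`, `numbering` (aligned author numbers),
#'   `pinned` (data.frame of the pinned positions).
#' @export
gphr_sequence <- function(receptor = c("TSHR", "FSHR", "LHR")) {
  receptor <- match.arg(receptor)
  span <- GPHR_SPAN[[receptor]]
  numbering <- seq(span[1], span[2])
  chars <- rep("L", length(numbering))
  pins <- GPHR_PINS[[receptor]]
  idx <- match(as.integer(names(pins)), numbering)
  chars[idx] <- unname(pins)
  list(sequence = paste(chars, collapse = ""),
       numbering = numbering,
       pinned = data.frame(resno = as.integer(names(pins)), aa = unname(pins)))
}

#' TM-helix annotation for a packaged receptor
#' @inheritParams gphr_sequence
#' @param chain chain id to stamp on the annotation.
#' @export
gphr_tm_annotation <- function(receptor = c("TSHR", "FSHR", "LHR"), chain = "A") {
  receptor <- match.arg(receptor)
  tm_annotation(GPHR_TM[[receptor]], chain = chain, ec_end_tm1 = "first")
}

#' Anchor overrides for a packaged receptor (the Ala 5.50 exception)
#' @inheritParams gphr_sequence
#' @export
gphr_anchor_overrides <- function(receptor = c("TSHR", "FSHR", "LHR")) {
  receptor <- match.arg(receptor)
  GPHR_ANCHOR_OVERRIDES[[receptor]]
}

#' Motif-anchored BW map for a packaged receptor
#'
#' Convenience wrapper: scans the packaged sequence, infers the anchor set
#' (with the Ala 5.50 override) and assigns labels across the annotated
#' helices.
#' @inheritParams gphr_tm_annotation
#' @return list with `anchors` (`bw_anchors`) and `map` (`bw_map`).
#' @export
gphr_bw_map <- function(receptor = c("TSHR", "FSHR", "LHR"), chain = "A") {
  receptor <- match.arg(receptor)
  s <- gphr_sequence(receptor)
  tm <- gphr_tm_annotation(receptor, chain)
  anchors <- infer_anchors(s$sequence, s$numbering, tm,
                           overrides = gphr_anchor_overrides(receptor))
  list(anchors = anchors, map = assign_bw(tm, anchors))
}
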