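# Ballesteros-Weinstein numbering anchored at conserved class A motifs.
#
# Each transmembrane helix gets a reference residue labelled x.50 (the most
# conserved position of that helix); every other residue in the helix is
# labelled by plain arithmetic offset from the anchor. No bulge/insertion
# sub-labels are used: the positions analysed here all obey plain offsets.

MOTIF_PATTERNS <- c(
  NLxxxD    = "N[LIVMF]...D",   # TM2, D = 2.50
  DRY_ERW   = "[ED]R[YW]",      # TM3, R = 3.50
  CWxP_CMxP = "C[WMF].P",       # TM6, P = 6.50
  NPxxY     = "NP..Y"           # TM7, P = 7.50 (N = 7.49)
)

MOTIF_HELIX <- c(NLxxxD = "TM2", DRY_ERW = "TM3", CWxP_CMxP = "TM6",
                 NPxxY = "TM7", N1.50 = "TM1", W4.50 = "TM4",
                 P5.50_A5.50 = "TM5")

#' Scan a sequence for conserved class A motifs
#'
#' Finds NLxxxD (TM2), the E/DRY - ERW arginine motif (TM3), CWxP/CMxP (TM6)
#' and NPxxY (TM7). When a TM annotation is supplied, the single-residue
#' anchor candidates N (TM1), W (TM4) and P (TM5) are also reported, and
#' every hit is flagged according to whether it falls inside the helix it is
#' expected in. Overlapping hits are all returned.
#'
#' @param sequence one-letter amino-acid string.
#' @param numbering integer author numbers aligned with `sequence`
#'   (default: 1..nchar).
#' @param tm optional `tm_annotation`.
#' @return data.frame with columns `motif`, `start`, `end`, `matched`,
#'   `helix` (helix containing the hit or NA), `in_expected_helix`.
#' @export
scan_motifs <- function(sequence, numbering = NULL, tm = NULL) {
  empty <- data.frame(motif = character(), start = integer(), end = integer(),
                      matched = character(), helix = character(),
                      in_expected_helix = logical())
  if (is.null(sequence) || nchar(sequence) == 0) return(empty)
  if (is.null(numbering)) numbering <- seq_len(nchar(sequence))
  if (length(numbering) != nchar(sequence)) {
    stop("numbering length does not match sequence length")
  }
  hits <- list()
  add_hit <- function(motif, i, len) {
    hits[[length(hits) + 1]] <<- data.frame(
      motif = motif, start = numbering[i], end = numbering[i + len - 1],
      matched = substr(sequence, i, i + len - 1))
  }
  for (m in names(MOTIF_PATTERNS)) {
    # lookahead so overlapping occurrences are all found
    pat <- paste0("(?=", MOTIF_PATTERNS[m], ")")
    pos <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    len <- c(NLxxxD = 6L, DRY_ERW = 3L, CWxP_CMxP = 4L, NPxxY = 5L)[[m]]
    if (pos[1] != -1) for (i in as.integer(pos)) add_hit(m, i, len)
  }
  if (!is.null(tm)) {
    single <- list(N1.50 = c("N", "TM1"), W4.50 = c("W", "TM4"),
                   P5.50_A5.50 = c("P", "TM5"))
    chars <- strsplit(sequence, "")[[1]]
    for (m in names(single)) {
      r <- tm$ranges[[single[[m]][2]]]
      idx <- which(chars == single[[m]][1] & numbering >= r[1] & numbering <= r[2])
      for (i in idx) add_hit(m, i, 1L)
    }
  }
  if (length(hits) == 0) return(empty)
  out <- do.call(rbind, hits)
  if (!is.null(tm)) {
    out$helix <- vapply(out$start, function(n) helix_of(tm, n), character(1))
    out$in_expected_helix <- !is.na(out$helix) &
      out$helix == MOTIF_HELIX[out$motif]
  } else {
    out$helix <- NA_character_
    out$in_expected_helix <- NA
  }
  rownames(out) <- NULL
  out
}

# pick one hit of a motif: prefer hits inside the expected helix; among
# those, the first in sequence (warning when the choice was ambiguous)
pick_hit <- function(hits, motif, helix) {
  h <- hits[hits$motif == motif, , drop = FALSE]
  if (nrow(h) == 0) return(NULL)
  inh <- h[!is.na(h$in_expected_helix) & h$in_expected_helix, , drop = FALSE]
  pool <- if (nrow(inh) > 0) inh else h
  if (nrow(pool) > 1) {
    warning(sprintf("%d candidate %s hits; using the first (residue %d)",
                    nrow(pool), motif, pool$start[1]), call. = FALSE)
  }
  pool[1, , drop = FALSE]
}

#' Infer the x.50 anchor residue of each helix
#'
#' Anchors: 2.50 = the Asp of NLxxxD; 3.50 = the Arg of E/DR(Y|W);
#' 6.50 = the Pro of C(W|M)xP; 7.50 = the Pro of NPxxY; 1.50 = the single
#' Asn in TM1; 4.50 = the single Trp in TM4; 5.50 = the Pro in TM5 or, for
#' receptors such as the glycoprotein hormone receptors that carry an
#' alanine at 5.50, a user-supplied override.
#'
#' @param sequence,numbering as in [scan_motifs()].
#' @param tm a `tm_annotation` (required: anchors must lie inside helices).
#' @param overrides optional named vector, names in `as.character(1:7)`,
#'   giving anchor author numbers directly (e.g. `c("5" = 593)`).
#' @return named numeric vector of length 7 (`"1"`..`"7"`), class
#'   `bw_anchors`.
#' @export
infer_anchors <- function(sequence, numbering = NULL, tm, overrides = NULL) {
  if (is.null(numbering)) numbering <- seq_len(nchar(sequence))
  hits <- scan_motifs(sequence, numbering, tm)
  anchors <- stats::setNames(rep(NA_real_, 7), as.character(1:7))
  take <- function(motif, helixn, offset) {
    h <- pick_hit(hits, motif, paste0("TM", helixn))
    if (is.null(h)) return(NA_real_)
    h$start + offset
  }
  anchors["2"] <- take("NLxxxD", 2, 5)       # ...D
  anchors["3"] <- take("DRY_ERW", 3, 1)      # .R.
  anchors["6"] <- take("CWxP_CMxP", 6, 3)    # ...P
  anchors["7"] <- take("NPxxY", 7, 1)        # .P...  (N = 7.49)
  anchors["1"] <- take("N1.50", 1, 0)
  anchors["4"] <- take("W4.50", 4, 0)
  anchors["5"] <- take("P5.50_A5.50", 5, 0)
  if (!is.null(overrides)) {
    for (k in names(overrides)) anchors[k] <- as.numeric(overrides[[k]])
  }
  for (k in as.character(1:7)) {
    if (is.na(anchors[k])) {
      stop("cannot infer anchor for TM", k,
           ": required motif not found and no override supplied")
    }
    r <- tm$ranges[[paste0("TM", k)]]
    if (anchors[k] < r[1] || anchors[k] > r[2]) {
      stop("anchor for TM", k, " (", anchors[k], ") outside annotated range")
    }
  }
  structure(anchors, class = "bw_anchors")
}

#' Assign Ballesteros-Weinstein labels across annotated helices
#'
#' Label of residue n in helix h is `h.(50 + n - anchor_h)`; the mapping is
#' bidirectional via [bw_label()] and [bw_residue()].
#'
#' @param tm a `tm_annotation`.
#' @param anchors a `bw_anchors` vector (see [infer_anchors()]).
#' @return data.frame of class `bw_map` with columns `chain`, `resno`,
#'   `helix` (integer 1..7), `pos` (integer), `label` ("3.50" style).
#' @export
assign_bw <- function(tm, anchors) {
  rows <- list()
  for (k in as.character(1:7)) {
    r <- tm$ranges[[paste0("TM", k)]]
    res <- seq(r[1], r[2])
    pos <- 50 + res - anchors[[k]]
    if (any(pos < 1 | pos > 99)) {
      stop("BW position outside 1..99 in TM", k,
           "; check anchor/annotation consistency")
    }
    rows[[k]] <- data.frame(chain = tm$chain, resno = res,
                            helix = as.integer(k), pos = as.integer(pos))
  }
  map <- do.call(rbind, rows)
  map$label <- sprintf("%d.%02d", map$helix, map$pos)
  rownames(map) <- NULL
  class(map) <- c("bw_map", "data.frame")
  map
}

#' Look up the BW label of an author residue number
#' @param map a `bw_map`.
#' @param resno author number(s).
#' @return label string(s); NA outside annotated helices.
#' @export
bw_label <- function(map, resno) {
  map$label[match(resno, map$resno)]
}

#' Look up the author residue number carrying a BW label
#' @param map a `bw_map`.
#' @param label label(s) like "3.50" or "6.30" (zero-padded or not).
#' @return author number(s); NA when the label is not assigned.
#' @export
bw_residue <- function(map, label) {
  norm <- function(l) {
    p <- strsplit(l, ".", fixed = TRUE)
    vapply(p, function(q) sprintf("%d.%02d", as.integer(q[1]), as.integer(q[2])),
           character(1))
  }
  map$resno[match(norm(label), map$label)]
}

#' Read a sequence from a FASTA file with a start-number offset
#'
#' Convenience input path for [scan_motifs()] / [infer_anchors()]: the
#' first record of the file becomes an inline sequence whose numbering
#' starts at `start_number`.
#'
#' @param path FASTA file.
#' @param start_number author number of the first residue.
#' @return list with `sequence` and `numbering`.
#' @export
read_sequence_fasta <- function(path, start_number = 1) {
  fa <- bio3d::read.fasta(path)
  seq <- toupper(paste(fa$ali[1, fa$ali[1, ] != "-"], collapse = ""))
  list(sequence = seq,
       numbering = seq(start_number, length.out = nchar(seq)))
}

#' Write a BW map as TSV
#' @param map a `bw_map`.
#' @param path output file.
#' @export
write_bw_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
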