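tshr <- gphr_sequence("TSHR")
tshr_tm <- gphr_tm_annotation("TSHR")

test_that("conserved motifs are found at their annotated TSHR positions", {
  hits <- scan_motifs(tshr$sequence, tshr$numbering, tshr_tm)
  hit <- function(m) hits[hits$motif == m & hits$in_expected_helix, ]
  expect_equal(hit("CWxP_CMxP")$start, 636)
  expect_equal(hit("CWxP_CMxP")$end, 639)
  expect_equal(hit("NPxxY")$start, 674)
  expect_equal(hit("NPxxY")$end, 678)
  expect_equal(hit("NLxxxD")$start, 455)
  expect_equal(hit("DRY_ERW")$start, 518)
  expect_match(hit("DRY_ERW")$matched, "^ERW$")
  expect_equal(nrow(scan_motifs("")), 0)
})

test_that("anchor inference recovers the x.50 set for the packaged receptors", {
  anchors <- infer_anchors(tshr$sequence, tshr$numbering, tshr_tm,
                           overrides = gphr_anchor_overrides("TSHR"))
  expect_equal(unname(anchors[c("2", "3", "5", "6", "7")]),
               c(460, 519, 593, 639, 675))
  fsh <- gphr_bw_map("FSHR")
  expect_equal(bw_residue(fsh$map, "3.50"), 467)
  expect_equal(bw_residue(fsh$map, "6.30"), 567)
  lhr <- gphr_bw_map("LHR")
  expect_equal(bw_residue(lhr$map, "3.50"), 464)
  expect_equal(bw_residue(lhr$map, "6.30"), 564)
})

test_that("a sequence lacking a required motif errors naming the helix", {
  seq_no_npxxy <- gsub("NP", "NL", tshr$sequence)  # destroy the TM7 motif
  expect_error(
    infer_anchors(seq_no_npxxy, tshr$numbering, tshr_tm,
                  overrides = gphr_anchor_overrides("TSHR")),
    "TM7")
})

test_that("label arithmetic reproduces the published TSHR assignments", {
  bw <- gphr_bw_map("TSHR")
  published <- c(`421` = "1.39", `424` = "1.42", `455` = "2.45",
                 `460` = "2.50", `468` = "2.58", `499` = "3.30",
                 `508` = "3.39", `509` = "3.40", `512` = "3.43",
                 `513` = "3.44", `518` = "3.49", `519` = "3.50",
                 `554` = "4.58", `582` = "5.39", `593` = "5.50",
                 `594` = "5.51", `601` = "5.58", `608` = "5.65",
                 `619` = "6.30", `629` = "6.40", `630` = "6.41",
                 `633` = "6.44", `636` = "6.47", `637` = "6.48",
                 `639` = "6.50", `665` = "7.40", `670` = "7.45",
                 `671` = "7.46", `674` = "7.49", `678` = "7.53")
  got <- bw_label(bw$map, as.integer(names(published)))
  expect_equal(got, unname(published))
  # positions printed with conflicting labels resolve by plain arithmetic
  expect_equal(bw_label(bw$map, 634), "6.45")
  expect_equal(bw_label(bw$map, 670), "7.45")
})

test_that("BW maps are arithmetic and bidirectional across every helix", {
  bw <- gphr_bw_map("TSHR")
  for (h in 1:7) {
    sub <- bw$map[bw$map$helix == h, ]
    sub <- sub[order(sub$resno), ]
    expect_equal(diff(sub$pos), rep(1L, nrow(sub) - 1))
  }
  expect_equal(bw_residue(bw$map, bw_label(bw$map, bw$map$resno)),
               bw$map$resno)
  expect_true(is.na(bw_label(bw$map, 9999)))
})

test_that("anchors outside annotated ranges and labels outside 1..99 error", {
  tm <- gphr_tm_annotation("TSHR")
  anchors <- structure(stats::setNames(c(432, 460, 519, 546, 593, 639, 675),
                                       as.character(1:7)),
                       class = "bw_anchors")
  bad <- anchors; bad["6"] <- 700
  expect_error(infer_anchors(tshr$sequence, tshr$numbering, tm,
                             overrides = c(`5` = 593, `6` = 700)), "outside")
  shifted <- anchors; shifted["3"] <- 560   # helix range maps below position 1
  expect_error(assign_bw(tm, shifted), "outside 1..99|check anchor")
})

test_that("FASTA input feeds the motif scanner with offset numbering", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">fragment starting at 516", "LIERWHAITL"), path)
  s <- read_sequence_fasta(path, start_number = 516)
  expect_equal(s$sequence, "LIERWHAITL")
  hits <- scan_motifs(s$sequence, s$numbering)
  expect_equal(hits$start[hits$motif == "DRY_ERW"], 518)
})

test_that("BW maps serialize to TSV and read back", {
  bw <- gphr_bw_map("TSHR")
  path <- tempfile(fileext = ".tsv")
  write_bw_map(bw$map, path)
  back <- utils::read.delim(path, colClasses = c(label = "character"))
  expect_equal(nrow(back), nrow(bw$map))
  expect_equal(back$label[back$resno == 519], "3.50")
})
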