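test_that("pair_distance modes behave and match a brute-force oracle", {
  h <- build_ideal_helix(8, sequence = "LFRDSKYW")
  m <- as_tmd_structure(h, "octa", "synthetic")
  res <- lapply(1:8, function(i) gphrtmd:::get_residue(m, "A", i))
  expect_equal(pair_distance(res[[3]], res[[3]], "ca"), 0)
  expect_equal(pair_distance(res[[3]], res[[3]], "min_heavy"), 0)
  for (i in 1:4) for (j in 5:8) {
    expect_equal(pair_distance(res[[i]], res[[j]], "min_heavy"),
                 brute_min_heavy(res[[i]], res[[j]]), tolerance = 1e-10)
  }
  d_named <- pair_distance(res[[3]], res[[4]], "named_atoms",
                           atoms = c("CA", "CA"))
  expect_equal(d_named, pair_distance(res[[3]], res[[4]], "ca"))
  expect_error(pair_distance(res[[3]], res[[4]], "named_atoms",
                             atoms = c("XX1", "CA")), "missing atoms")
})

test_that("glycine falls back to CA in side-chain mode with a warning", {
  gly <- fake_residue("GLY", list(N = c(-1.4, 0, 0), CA = c(0, 0, 0),
                                  C = c(1, 1, 0), O = c(1, 2, 0)))
  leu <- fake_residue("LEU", list(CA = c(5, 0, 0), CB = c(4, 0, 0)), resno = 2)
  expect_warning(d <- pair_distance(gly, leu, "min_sidechain_heavy"),
                 "falling back to CA")
  expect_equal(d, 4)
})

test_that("the tier ladder reproduces the calibration distances", {
  cls <- function(p) classify_pair(p$a, p$b,
                                   atom_typing(include_backbone = FALSE))
  # 3.4 A apolar carbon pair: a true hydrophobic interaction
  p <- residue_pair_at("ALA", "CB", "ILE", "CD1", 3.4)
  expect_equal(cls(p)$tier, "hydrophobic_strong")
  # 4.2 A apolar pair: weak hydrophobic
  expect_equal(cls(residue_pair_at("LEU", "CD1", "VAL", "CG1", 4.2))$tier,
               "hydrophobic_weak")
  # 4.9 A apolar pair: no interaction
  r49 <- cls(residue_pair_at("ALA", "CB", "ILE", "CD1", 4.9))
  expect_equal(r49$tier, "none")
  expect_false(r49$is_contact)
  # 3.8 A donor/acceptor: polar interaction or weak hydrogen bond
  r38 <- cls(residue_pair_at("ASN", "ND2", "ASP", "OD1", 3.8))
  expect_equal(r38$tier, "weak_polar")
  # 3.2 A donor/acceptor: hydrogen bond
  expect_equal(cls(residue_pair_at("ASN", "ND2", "ASP", "OD1", 3.2))$tier,
               "hbond")
  # 3.0 A opposite charges: salt bridge
  expect_equal(cls(residue_pair_at("ARG", "NH1", "ASP", "OD1", 3.0))$tier,
               "salt_bridge")
  # 2.9 A ring atoms: aromatic
  expect_equal(cls(residue_pair_at("PHE", "CZ", "PHE", "CZ", 2.9))$tier,
               "aromatic")
  # 4.6 A tyrosine hydroxyls: not a contact, water-mediated possible
  r46 <- cls(residue_pair_at("TYR", "OH", "TYR", "OH", 4.6))
  expect_equal(r46$tier, "water_mediated_possible")
  expect_false(r46$is_contact)
  expect_true(r46$water_mediated_possible)
})

test_that("classification is symmetric in its arguments", {
  pairs <- list(residue_pair_at("ARG", "NH1", "GLU", "OE1", 3.6),
                residue_pair_at("SER", "OG", "THR", "OG1", 3.9),
                residue_pair_at("PHE", "CD1", "TRP", "CZ2", 4.1),
                residue_pair_at("MET", "CE", "LEU", "CD2", 4.4))
  for (p in pairs) {
    t_ab <- classify_pair(p$a, p$b)
    t_ba <- classify_pair(p$b, p$a)
    expect_equal(t_ab$tier, t_ba$tier)
    expect_equal(t_ab$distance_A, t_ba$distance_A)
  }
})

test_that("shrinking a salt-bridge distance never skips through lower tiers", {
  # monotone ladder: moving the realizing atoms closer can only keep or
  # promote the tier, never demote toward none
  rank <- c(none = 0, water_mediated_possible = 0.5, induced_dipole = 1,
            hydrophobic_weak = 1, hydrophobic_strong = 2, aromatic = 2,
            weak_polar = 2, hbond = 3, salt_bridge = 4)
  prev <- -Inf
  for (d in seq(6.5, 2.8, by = -0.25)) {
    tier <- classify_pair(residue_pair_at("LYS", "NZ", "GLU", "OE2", d)$a,
                          residue_pair_at("LYS", "NZ", "GLU", "OE2", d)$b,
                          atom_typing(include_backbone = FALSE))$tier
    expect_gte(rank[[tier]], prev)
    prev <- rank[[tier]]
  }
})

test_that("a planted salt bridge is the only record in a sparse bundle map", {
  sp <- bundle_spec(default_type = "GLY",
                    features = list(feat_contact(bundle_resno("3.50"),
                                                 bundle_resno("6.30"), 3.0,
                                                 "ARG", "ASP")),
                    seed = 2)
  b <- build_bundle(sp)
  typing <- atom_typing(include_backbone = FALSE)
  im <- interaction_map(b$model, b$map, typing = typing)
  expect_equal(nrow(im), 1)
  expect_equal(im$tier, "salt_bridge")
  expect_equal(sort(c(im$bw_a, im$bw_b)), c("3.50", "6.30"))
  # translating the partner helix far away empties the map
  sp2 <- bundle_spec(default_type = "GLY",
                     features = list(feat_contact(bundle_resno("3.50"),
                                                  bundle_resno("6.30"), 3.0,
                                                  "ARG", "ASP"),
                                     feat_motion(6, translation = c(40, 0, 0))),
                     seed = 2)
  im2 <- interaction_map(build_bundle(sp2)$model, b$map, typing = typing)
  expect_equal(nrow(im2), 0)
})

test_that("the map equals brute-force classification over qualifying pairs", {
  b <- build_bundle(bundle_spec(residues_per_helix = 10, seed = 5))
  im <- interaction_map(b$model, b$map, ca_prefilter = 30)
  # brute force: classify every qualifying pair directly
  resnos <- sort(intersect(b$map$resno, unique(b$model$atoms$resno)))
  want <- 0
  for (i in seq_along(resnos)) for (j in seq_along(resnos)) {
    if (j <= i) next
    ri <- resnos[i]; rj <- resnos[j]
    hi <- b$map$helix[match(ri, b$map$resno)]
    hj <- b$map$helix[match(rj, b$map$resno)]
    if (hi == hj && abs(rj - ri) <= 4) next
    rec <- classify_pair(gphrtmd:::get_residue(b$model, "A", ri),
                         gphrtmd:::get_residue(b$model, "A", rj))
    if (rec$is_contact) {
      want <- want + 1
      row <- im[im$resno_a == ri & im$resno_b == rj, ]
      expect_equal(nrow(row), 1)
      expect_equal(row$tier, rec$tier)
      expect_equal(row$distance_A, rec$distance_A, tolerance = 1e-9)
    }
  }
  expect_equal(nrow(im), want)
  expect_true(!is.unsorted(im$distance_A))
})
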