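test_that("packaged phenotype tables load with published row counts and values", {
  tab <- load_phenotype_tables()
  act <- tab[tab$category %in% c("CAM", "activating"), ]
  inact <- tab[tab$category %in% c("inactivating", "silencing"), ]
  expect_equal(sum(act$receptor == "FSHR"), 10)
  expect_equal(sum(act$receptor == "LHR"), 17)
  expect_equal(sum(act$receptor == "TSHR"), 23)
  expect_equal(sum(inact$receptor == "FSHR"), 7)
  expect_equal(sum(inact$receptor == "LHR"), 6)
  expect_equal(sum(inact$receptor == "TSHR"), 19)
  d633a <- lookup_phenotype("TSHR", "D633A")
  expect_equal(d633a$category, "CAM")
  expect_equal(d633a$activity_fold_wt, 13.6)
  expect_equal(d633a$bw, "6.44")
  d460a <- lookup_phenotype("TSHR", "D460A")
  expect_equal(d460a$category, "silencing")
  expect_equal(d460a$activity_fold_wt, 0.28)
  expect_equal(nrow(lookup_phenotype("TSHR", "Q999Z")), 0)
  expect_true(all(is.na(tab$activity_fold_wt) | tab$activity_fold_wt >= 0))
})

test_that("wild-type profiles count planted contacts per conformation", {
  r343 <- bundle_resno("3.43")
  r640 <- bundle_resno("6.40")
  r250 <- bundle_resno("2.50")
  sp <- bundle_spec(default_type = "GLY",
                    features = list(
                      feat_contact(r343, r640, 3.4, "LEU", "ILE"),
                      feat_contact(r343, r250, 3.6, "LEU", "LEU",
                                   aim_a = FALSE)),
                    seed = 3)
  b <- build_bundle(sp)
  # active counterpart: both partner helices pushed away
  sp2 <- bundle_spec(default_type = "GLY",
                     features = c(sp$features, list(
                       feat_motion(6, translation = c(25, 0, 0)),
                       feat_motion(2, translation = c(-25, 10, 0)))),
                     seed = 3)
  b2 <- build_bundle(sp2)
  typing <- atom_typing(include_backbone = FALSE)
  prof <- wt_interaction_profile("3.43", b$model, b2$model, b$map,
                                 typing = typing, neighbor_cut = 5)
  expect_equal(sum(prof$inactive$tier != "none"), 2)
  expect_equal(nrow(prof$active[prof$active$tier != "none", ]), 0)
  # per-residue filter of the full map gives the same contacts
  im <- interaction_map(b$model, b$map, typing = typing)
  from_map <- im[im$resno_a == r343 | im$resno_b == r343, ]
  expect_equal(sort(from_map$tier),
               sort(prof$inactive$tier[prof$inactive$tier != "none"]))
})

test_that("mutation-effect calls are deterministic and order-independent", {
  prof <- mutation_profile("LEU",
    inactive = data.frame(partner_type = c("ASP", "LEU"),
                          tier = c("induced_dipole", "hydrophobic_weak"),
                          distance_A = c(3.5, 4.4)),
    active = data.frame(partner_type = c("TYR", "ASN", "ASN"),
                        tier = c("hydrophobic_strong", "induced_dipole",
                                 "induced_dipole"),
                        distance_A = c(3.8, 4.4, 4.4)))
  e1 <- predict_mutation_effect("L512R", prof, "CAM")
  shuffled <- mutation_profile("LEU", prof$inactive[2:1, ],
                               prof$active[c(3, 1, 2), ])
  e2 <- predict_mutation_effect("L512R", shuffled, "CAM")
  expect_equal(e1$stabilization_call, e2$stabilization_call)
  expect_equal(e1$net_active, e2$net_active)
  expect_equal(e1$net_inactive, e2$net_inactive)
  expect_equal(e1$stabilization_call, "active")
  expect_equal(e1$phenotype_consistency, "consistent")
})

test_that("identity substitutions are neutral and untestable", {
  prof <- mutation_profile("LEU",
    inactive = data.frame(partner_type = "ASP", tier = "induced_dipole",
                          distance_A = 3.5),
    active = data.frame(partner_type = "ASP", tier = "induced_dipole",
                        distance_A = 3.5))
  e <- predict_mutation_effect("L512L", prof, "CAM")
  expect_equal(e$stabilization_call, "neutral")
  expect_equal(e$phenotype_consistency, "untestable")
  expect_error(predict_mutation_effect("M512R", prof), "does not match")
  expect_error(predict_mutation_effect("L512", prof), "cannot parse")
})

test_that("a shielding substitution is called inactive-stabilizing", {
  # Ala6.38 -> Val gaining a hydrophobic contact over a tyrosine neighbour
  # in the inactive conformation only
  prof <- mutation_profile("ALA",
    inactive = data.frame(partner_type = "TYR", tier = "none",
                          distance_A = 4.9),
    active = data.frame(partner_type = "TYR", tier = "none",
                        distance_A = 6.2))
  e <- predict_mutation_effect("A575V", prof, "inactivating")
  expect_equal(e$stabilization_call, "inactive")
  expect_equal(e$phenotype_consistency, "consistent")
})

test_that("profiles from structures feed the effect predictor end to end", {
  r343 <- bundle_resno("3.43")
  r745 <- bundle_resno("7.45")
  sp_in <- bundle_spec(default_type = "GLY",
                       features = list(feat_contact(r343, r745, 8.0,
                                                    "LEU", "ASN")),
                       seed = 13)
  sp_ac <- bundle_spec(default_type = "GLY",
                       features = list(feat_contact(r343, r745, 4.3,
                                                    "LEU", "ASN")),
                       seed = 13)
  typing <- atom_typing(include_backbone = FALSE)
  prof <- wt_interaction_profile("3.43", build_bundle(sp_in)$model,
                                 build_bundle(sp_ac)$model,
                                 build_bundle(sp_in)$map, typing = typing)
  # Leu -> Arg: the long polar arm reaches the asparagine in the active
  # state (4.3 A observed), turning a weak contact into a hydrogen bond
  e <- predict_mutation_effect("L319R", prof, "CAM")
  expect_equal(e$stabilization_call, "active")
})
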