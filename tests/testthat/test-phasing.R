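test_that("transmitted-allele deduction is Mendelian subtraction", {
  t1 <- deduce_transmitted_allele(c("A", "G"), c("A", "A"), c("A", "G"))
  expect_identical(as.character(t1), "G")
  expect_identical(attr(t1, "status"), "resolved")

  t2 <- deduce_transmitted_allele(c("A", "G"), c("A", "G"), c("A", "G"))
  expect_true(is.na(t2))
  expect_identical(attr(t2, "status"), "ambiguous")

  # sperm are haploid observations of the carrier's gamete
  t3 <- deduce_transmitted_allele(c("A", "G"), NULL, "G",
                                  sample_kind = "sperm")
  expect_identical(as.character(t3), "G")

  # Mendelian-inconsistent genotypes are flagged, not errored
  t4 <- deduce_transmitted_allele(c("A", "G"), c("A", "A"), c("G", "G"))
  expect_true(is.na(t4))
  expect_identical(attr(t4, "status"), "inconsistent")

  # X-linked male embryo: its single allele is the maternal gamete
  t5 <- deduce_transmitted_allele(c("A", "G"), c("A", "A"), "G",
                                  inheritance = "x_linked",
                                  sample_sex = "M")
  expect_identical(as.character(t5), "G")
})

test_that("proband phasing labels the transmitted allele by disease status", {
  sites <- c(100, 200, 300, 400)
  carrier <- c("A/G", "C/T", "A/G", "A/C")
  other <- c("A/A", "C/C", "A/G", "A/A")
  proband <- c("A/G", "C/C", "A/G", "A/C")
  pair <- phase_with_proband(carrier, other, proband, sites,
                             proband_affected = TRUE)
  # site 100: transmitted G -> disease G / normal A
  expect_equal(pair$phase$disease_allele[pair$phase$site == 100], "G")
  expect_equal(pair$phase$normal_allele[pair$phase$site == 100], "A")
  # site 200: transmitted C -> disease C / normal T
  expect_equal(pair$phase$disease_allele[pair$phase$site == 200], "C")
  # site 300 is ambiguous (all heterozygous) and discarded
  expect_true(300 %in% pair$discarded$site)
  expect_equal(pair$discarded$reason[pair$discarded$site == 300],
               "ambiguous")
  # an unaffected sibling labels the complement
  pair_u <- phase_with_proband(carrier, other, proband, sites,
                               proband_affected = FALSE)
  expect_equal(pair_u$phase$disease_allele[pair_u$phase$site == 100], "A")
  expect_equal(pair_u$phase$normal_allele[pair_u$phase$site == 100], "G")
})

test_that("a Mendelian-inconsistent proband triggers the mix-up guard", {
  sites <- 1:8 * 100
  carrier <- rep("A/G", 8)
  other <- rep("A/A", 8)
  proband <- rep("G/G", 8)  # impossible given the parents
  expect_error(phase_with_proband(carrier, other, proband, sites),
               "mix-up")
})

toy_transmitted <- function() {
  hapD <- c("A", "C", "G", "T", "A")
  hapN <- c("G", "T", "T", "A", "C")
  m <- rbind(E1 = hapD, E2 = hapD, E3 = hapD,
             E4 = hapN, E5 = hapN, E6 = hapN)
  colnames(m) <- as.character(1:5 * 100)
  list(m = m, carrier = paste(pmin(hapD, hapN), pmax(hapD, hapN), sep = "/"),
       mc = c(E1 = TRUE, E2 = TRUE, E3 = TRUE,
              E4 = FALSE, E5 = FALSE, E6 = FALSE))
}

test_that("proband-free phasing separates and labels a clean family", {
  toy <- toy_transmitted()
  pair <- phase_without_proband(toy$m[1:4, ],
                                toy$mc[1:4],
                                carrier_gts = toy$carrier)
  expect_equal(pair$n_sites, 5L)
  expect_equal(pair$phase$disease_allele, c("A", "C", "G", "T", "A"))
  expect_equal(pair$phase$normal_allele, c("G", "T", "T", "A", "C"))
  cls <- attr(pair, "classes")
  expect_setequal(cls$disease, c("E1", "E2", "E3"))
  expect_setequal(cls$normal, "E4")

  # balanced 3+3 family
  toy6 <- toy_transmitted()
  pair6 <- phase_without_proband(toy6$m, toy6$mc,
                                 carrier_gts = toy6$carrier)
  expect_equal(pair6$n_sites, 5L)
  cls6 <- attr(pair6, "classes")
  expect_setequal(cls6$disease, c("E1", "E2", "E3"))
  expect_setequal(cls6$normal, c("E4", "E5", "E6"))
})

test_that("sites with more than one discordant source are discarded,
           singletons survive", {
  toy <- toy_transmitted()
  m <- toy$m
  # singleton corruption at site 200 (E2 flips to the other haplotype)
  m["E2", "200"] <- "T"
  # double corruption at site 400, one in each class
  m["E1", "400"] <- "A"
  m["E4", "400"] <- "T"
  pair <- phase_without_proband(m, toy$mc, carrier_gts = toy$carrier)
  expect_true("400" %in% pair$discarded$site)
  expect_equal(pair$discarded$reason[pair$discarded$site == "400"],
               "discordant")
  # the singleton-corrupted site is retained with the majority consensus
  expect_true("200" %in% pair$phase$site)
  expect_equal(pair$phase$disease_allele[pair$phase$site == "200"], "C")
})

test_that("identical class consensuses are discarded", {
  toy <- toy_transmitted()
  m <- toy$m
  m[, "300"] <- "G"  # both classes now read G at site 300
  carrier <- toy$carrier
  carrier[3] <- "G/G"
  pair <- phase_without_proband(m, toy$mc, carrier_gts = carrier)
  expect_true("300" %in% pair$discarded$site)
  expect_equal(pair$discarded$reason[pair$discarded$site == "300"],
               "identical_consensus")
})

test_that("fewer than four sources is a hard error", {
  toy <- toy_transmitted()
  expect_error(phase_without_proband(toy$m[1:3, ], toy$mc[1:3],
                                     carrier_gts = toy$carrier),
               "at least 4")
})

test_that("labelling fails when mutation evidence does not separate classes", {
  toy <- toy_transmitted()
  expect_error(
    phase_without_proband(toy$m, setNames(rep(TRUE, 6), rownames(toy$m)),
                          carrier_gts = toy$carrier),
    "both haplotype classes")
  expect_error(
    phase_without_proband(toy$m, setNames(rep(NA, 6), rownames(toy$m)),
                          carrier_gts = toy$carrier),
    "does not separate")
})

test_that("source order does not change the phase (label symmetry)", {
  toy <- toy_transmitted()
  m <- toy$m
  m["E3", "100"] <- NA  # some missingness
  m["E5", "300"] <- NA
  ref_pair <- phase_without_proband(m, toy$mc, carrier_gts = toy$carrier)
  set.seed(9)
  for (i in 1:5) {
    perm <- sample(nrow(m))
    pair <- phase_without_proband(m[perm, ], toy$mc[perm],
                                  carrier_gts = toy$carrier)
    expect_equal(pair$phase, ref_pair$phase)
    expect_setequal(attr(pair, "classes")$disease,
                    attr(ref_pair, "classes")$disease)
  }
})

test_that("polar-body conflicts are recorded per embryo and site", {
  toy <- toy_transmitted()
  pair <- phase_without_proband(toy$m, toy$mc, carrier_gts = toy$carrier)
  emb_t <- toy$m[1:2, , drop = FALSE]
  pb_t <- emb_t
  pb_t["E1", "300"] <- "T"   # PB2 implies the other allele: conflict
  pb_t["E2", "200"] <- NA    # no coverage: no action
  pair2 <- augment_with_polar_bodies(pair, emb_t, pb_t)
  excl <- attr(pair2, "embryo_exclusions")
  expect_equal(nrow(excl), 1L)
  expect_equal(excl$embryo_id, "E1")
  expect_equal(excl$site, "300")
  expect_equal(excl$reason, "polar_body_conflict")
})
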