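phase_GA <- c(disease = "G", normal = "A")

test_that("combination classification follows Mendelian transmission", {
  # embryo's G can only come from the carrier's disease haplotype
  expect_identical(
    classify_combination(c("A", "G"), c("A", "A"), c("A", "G"), phase_GA),
    "disease_supportive")
  # either parent could contribute the G
  expect_identical(
    classify_combination(c("A", "G"), c("A", "G"), c("A", "G"), phase_GA),
    "neutral")
  # homozygous carrier is uninformative
  expect_identical(
    classify_combination(c("A", "A"), c("A", "G"), c("A", "G"),
                         c(disease = "A", normal = "A")),
    "neutral")
  # Mendelian-inconsistent: the other parent cannot supply a G
  expect_identical(
    classify_combination(c("A", "G"), c("A", "A"), c("G", "G"), phase_GA),
    "neutral")
  # normal-supportive mirror
  expect_identical(
    classify_combination(c("A", "G"), c("A", "A"), c("A", "A"), phase_GA),
    "normal_supportive")
  expect_error(
    classify_combination(c("A", "G"), c("A", "A"), c("A", "G"),
                         c(disease = "T", normal = "A")),
    "phase")
})

test_that("X-linked male embryos are classified on the single maternal allele", {
  expect_identical(
    classify_combination(c("A", "G"), c("A", "A"), "G", phase_GA,
                         inheritance = "x_linked", embryo_sex = "M"),
    "disease_supportive")
  expect_identical(
    classify_combination(c("A", "G"), c("A", "A"), "A", phase_GA,
                         inheritance = "x_linked", embryo_sex = "M"),
    "normal_supportive")
  expect_error(
    classify_combination(c("A", "G"), c("A", "A"), "A", phase_GA,
                         inheritance = "x_linked"),
    "embryo_sex")
})

test_that("site evidence reproduces hand-enumerated values", {
  carrier_het <- certain_post(2)
  other_rr <- certain_post(1)
  embryo_het <- certain_post(2, id = "E1")
  ev <- site_evidence(carrier_het, other_rr, embryo_het, phase_GA)
  expect_equal(c(ev$p_disease, ev$p_normal), c(1, 0))
  expect_equal(ev$n_combinations, 27L)

  # everything heterozygous: all mass neutral, split half-half
  ev2 <- site_evidence(carrier_het, certain_post(2), embryo_het, phase_GA)
  expect_equal(c(ev2$p_disease, ev2$p_normal), c(0.5, 0.5))

  # carrier (het 0.9, hom_ref 0.1): p_disease = 0.9 + 0.1/2
  carrier_mix <- make_post(c(0.1, 0.9, 0))
  ev3 <- site_evidence(carrier_mix, other_rr, embryo_het, phase_GA)
  expect_equal(ev3$p_disease, 0.95)
})

test_that("swapping phase labels swaps the evidence pair exactly", {
  set.seed(42)
  for (i in 1:10) {
    cp <- make_post(prop.table(runif(3)))
    op <- make_post(prop.table(runif(3)))
    ep <- make_post(prop.table(runif(3)), id = "E1")
    a <- site_evidence(cp, op, ep, c(disease = "G", normal = "A"))
    b <- site_evidence(cp, op, ep, c(disease = "A", normal = "G"))
    expect_equal(a$p_disease, b$p_normal, tolerance = 1e-12)
    expect_equal(a$p_normal, b$p_disease, tolerance = 1e-12)
  }
})

test_that("certain genotypes only yield (1,0), (0,1) or (1/2,1/2)", {
  for (ci in 1:3) for (oi in 1:3) for (ei in 1:3) {
    ev <- site_evidence(certain_post(ci), certain_post(oi),
                        certain_post(ei, id = "E"), phase_GA)
    expect_true(any(vapply(list(c(1, 0), c(0, 1), c(0.5, 0.5)),
                           function(x) isTRUE(all.equal(
                             c(ev$p_disease, ev$p_normal), x)),
                           logical(1))))
  }
})

test_that("vectorized evidence equals the per-combination enumeration", {
  set.seed(7)
  n <- 40
  cp <- t(apply(matrix(runif(3 * n), n), 1, prop.table))
  op <- t(apply(matrix(runif(3 * n), n), 1, prop.table))
  ep <- t(apply(matrix(runif(3 * n), n), 1, prop.table))
  colnames(cp) <- colnames(op) <- colnames(ep) <-
    c("hom_ref", "het", "hom_alt")
  alt_dis <- runif(n) < 0.5
  fast <- pgtlink:::site_evidence_matrix(cp, op, ep, alt_dis)
  for (i in seq_len(n)) {
    ph <- if (alt_dis[i]) c(disease = "G", normal = "A")
          else c(disease = "A", normal = "G")
    slow <- site_evidence(make_post(cp[i, ]), make_post(op[i, ]),
                          make_post(ep[i, ], id = "E"), ph)
    expect_equal(unname(fast[i, ]), c(slow$p_disease, slow$p_normal),
                 tolerance = 1e-12)
  }
  # haploid male-embryo variant against the general enumerator
  eph <- t(apply(matrix(runif(2 * n), n), 1, prop.table))
  colnames(eph) <- c("ref", "alt")
  fast_x <- pgtlink:::site_evidence_matrix_xmale(cp, eph, alt_dis)
  for (i in seq_len(n)) {
    ph <- if (alt_dis[i]) c(disease = "G", normal = "A")
          else c(disease = "A", normal = "G")
    slow <- site_evidence(make_post(cp[i, ]), NULL,
                          make_post(eph[i, ], id = "E", ploidy = "haploid"),
                          ph, inheritance = "x_linked", embryo_sex = "M")
    expect_equal(unname(fast_x[i, ]), c(slow$p_disease, slow$p_normal),
                 tolerance = 1e-12)
  }
})

test_that("linkage-site collection applies window, depth and phase filters", {
  mut <- 10e6
  pos <- mut + c(-2e6, -1e6, -0.5e6, 0.5e6, 1e6, 2e6)
  sel <- collect_linkage_sites(pos, mut, embryo_depth = 5,
                               carrier_het_prob = 1, phase_defined = TRUE)
  expect_equal(length(sel$upstream) + length(sel$downstream), 4L)
  expect_equal(pos[sel$upstream], mut + c(-0.5e6, -1e6))  # nearest first
  expect_equal(pos[sel$downstream], mut + c(0.5e6, 1e6))

  # depth below min_reads excludes a site for that embryo
  sel2 <- collect_linkage_sites(pos, mut,
                                embryo_depth = c(5, 1, 5, 5, 5, 5),
                                min_reads = 2)
  expect_false(which(pos == mut - 1e6) %in%
                 c(sel2$upstream, sel2$downstream))

  # homozygous carrier (low het mass) is uninformative
  sel3 <- collect_linkage_sites(pos, mut,
                                carrier_het_prob = c(1, 0.2, 1, 1, 1, 1))
  expect_false(which(pos == mut - 1e6) %in%
                 c(sel3$upstream, sel3$downstream))

  # whitelist bypasses everything except the window
  sel4 <- collect_linkage_sites(pos, mut, embryo_depth = 0,
                                carrier_het_prob = 0, phase_defined = FALSE,
                                whitelist = pos[c(1, 2, 5)])
  expect_equal(sort(pos[c(sel4$upstream, sel4$downstream)]),
               sort(pos[c(2, 5)]))  # pos[1] is outside the window

  expect_warning(collect_linkage_sites(pos, mut, embryo_depth = 0),
                 "no linkage sites")
})
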