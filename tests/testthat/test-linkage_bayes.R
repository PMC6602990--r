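test_that("configuration validates priors, thresholds and modes", {
  cfg <- analysis_config()
  expect_equal(cfg$prior_disease + cfg$prior_normal, 1)
  expect_error(analysis_config(prior_disease = 0), "prior")
  expect_error(analysis_config(thresholds = c(normal = 0.1,
                                              normal_risk = 1e-4,
                                              risk = 0.6,
                                              disease_risk = 0.9)),
               "thresholds")
  expect_error(analysis_config(mode = "nonsense"))
})

test_that("single-site chains follow the terminal formula", {
  ch <- linkage_chain(1, 0, 0)
  expect_equal(chain_conditional(ch, "disease"), 1)
  expect_equal(chain_conditional(ch, "normal"), 0)
  ch2 <- linkage_chain(1, 0, 0.01)
  expect_equal(chain_conditional(ch2, "disease"), 0.99)
  expect_equal(chain_conditional(ch2, "normal"), 0.01)
  # empty chain is the empty product
  expect_equal(chain_conditional(pgtlink:::empty_chain(), "disease"), 1)
})

test_that("two-site recursion matches the hand path enumeration", {
  ch <- linkage_chain(c(0.9, 0.8), c(0.1, 0.2), c(0.01, 0.02))
  expect_equal(chain_conditional(ch, "disease"), 0.70232,
               tolerance = 1e-12)
  # all-neutral evidence cannot distinguish the states
  chn <- linkage_chain(rep(0.5, 6), rep(0.5, 6), runif(6, 0, 0.5))
  expect_equal(chain_conditional(chn, "disease"),
               chain_conditional(chn, "normal"), tolerance = 1e-12)
})

test_that("chain construction enforces ordering and transition bounds", {
  expect_error(linkage_chain(c(0.9, 0.8), c(0.1, 0.2), c(0.1, 0.6)),
               "transition")
  expect_error(linkage_chain(c(0.9, 0.8), c(0.1, 0.2), c(0.01, 0.02),
                             pos = c(5e6, 4e6), mutation_pos = 1e6),
               "increasing distance")
  # nearest-first ordering passes
  expect_s3_class(linkage_chain(c(0.9, 0.8), c(0.1, 0.2), c(0.01, 0.02),
                                pos = c(2e6, 4e6), mutation_pos = 1e6),
                  "linkage_chain")
})

test_that("posterior combines flanks, priors and mutation-site evidence", {
  # no sites: the prior is returned
  expect_equal(as.numeric(posterior_disease()), 0.5)
  expect_equal(as.numeric(posterior_disease(
    config = analysis_config(prior_disease = 0.3))), 0.3)

  # hand Bayes arithmetic: L_D = .9*.8, L_N = .1*.2
  up <- linkage_chain(0.9, 0.1, 0)
  dn <- linkage_chain(0.8, 0.2, 0)
  expect_equal(as.numeric(posterior_disease(up, dn)), 0.72 / 0.74,
               tolerance = 1e-12)

  # definitive mutation-site PCR evidence overrides neutral chains
  neutral <- linkage_chain(rep(0.5, 4), rep(0.5, 4), rep(0.1, 4))
  expect_equal(as.numeric(posterior_disease(neutral, neutral, c(0, 1))), 0)
  expect_equal(as.numeric(posterior_disease(neutral, neutral, c(1, 0))), 1)

  # contradictory certain evidence has no consistent state
  expect_error(posterior_disease(linkage_chain(1, 0, 0),
                                 linkage_chain(0, 1, 0)),
               "self-contradictory")
})

test_that("classification reproduces the five-category partition", {
  cfg <- analysis_config()
  expect_equal(classify(1e-5, cfg), "normal")
  expect_equal(classify(0.95, cfg), "disease")
  expect_equal(classify(0.3, cfg), "risk")
  # boundary probes: ties fall toward the more cautious category
  expect_equal(classify(c(0, 1e-4 - 1e-12, 1e-4, 0.1 - 1e-12, 0.1,
                          0.6, 0.6 + 1e-12, 0.9, 0.9 + 1e-12, 1), cfg),
               c("normal", "normal", "normal_risk", "normal_risk", "risk",
                 "risk", "disease_risk", "disease_risk", "disease",
                 "disease"))
  # the categories partition [0, 1]
  probes <- seq(0, 1, by = 1e-3)
  expect_true(all(classify(probes, cfg) %in%
                    c("normal", "normal_risk", "risk", "disease_risk",
                      "disease")))
})

test_that("error probability is the mass on the losing side", {
  expect_equal(error_probability(1e-6, "normal"), 1e-6,
               ignore_attr = TRUE)
  expect_equal(error_probability(0.97, "disease"), 0.03,
               ignore_attr = TRUE)
  ep <- error_probability(0.5, "risk")
  expect_equal(as.numeric(ep), 0.5)
  expect_true(attr(ep, "indeterminate"))
  expect_false(any(attr(error_probability(c(1e-6, 0.97),
                                          c("normal", "disease")),
                        "indeterminate")))
})

test_that("recursion equals exhaustive path enumeration on random chains", {
  set.seed(101)
  worst <- 0
  for (i in 1:200) {
    up <- random_chain(sample(0:6, 1))
    dn <- random_chain(sample(0:6, 1))
    me <- if (runif(1) < 0.5) NULL else {
      x <- runif(1)
      c(x, 1 - x)
    }
    a <- as.numeric(posterior_disease(up, dn, me))
    b <- brute_force_posterior(up, dn, me)
    worst <- max(worst, abs(a - b) / max(abs(b), 1e-300))
  }
  expect_lt(worst, 1e-12)
  expect_error(brute_force_posterior(random_chain(12), random_chain(12)),
               "refused")
})

test_that("flipping all evidence maps the posterior to its complement", {
  set.seed(55)
  for (i in 1:20) {
    n1 <- sample(1:6, 1)
    n2 <- sample(0:6, 1)
    pd1 <- runif(n1)
    pd2 <- runif(n2)
    r1 <- runif(n1, 0, 0.5)
    r2 <- runif(n2, 0, 0.5)
    x <- runif(1)
    p <- as.numeric(posterior_disease(linkage_chain(pd1, 1 - pd1, r1),
                                      linkage_chain(pd2, 1 - pd2, r2),
                                      c(x, 1 - x)))
    pf <- as.numeric(posterior_disease(linkage_chain(1 - pd1, pd1, r1),
                                       linkage_chain(1 - pd2, pd2, r2),
                                       c(1 - x, x)))
    expect_equal(pf, 1 - p, tolerance = 1e-9)
  }
})

test_that("supportive sites never decrease the posterior; zero-recombination
           certain chains are decisive", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    pd <- runif(n)
    r <- runif(n, 0, 0.5)
    base <- as.numeric(posterior_disease(linkage_chain(pd, 1 - pd, r)))
    ext <- as.numeric(posterior_disease(
      linkage_chain(c(pd, 1), c(1 - pd, 0), c(r, runif(1, 0, 0.49)))))
    expect_gte(ext, base - 1e-12)
  }
  # certain evidence with r = 0 everywhere
  certain <- linkage_chain(c(1, 1, 1), c(0, 0, 0), c(0, 0, 0))
  expect_equal(as.numeric(posterior_disease(certain)), 1)
  certain_n <- linkage_chain(c(0, 0), c(1, 1), c(0, 0))
  expect_equal(as.numeric(posterior_disease(certain_n)), 0)
})
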