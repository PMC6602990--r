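# Shared fixtures: quick posterior constructors, a brute-force genotype
# oracle that expands the read mixture as a sum over per-read haplotype
# assignments (independent of the production likelihood code), and a
# one-call synthetic-family runner.

make_post <- function(probs, ref = "A", alt = "G", id = "s", chrom = "chr1",
                      pos = 100L, ploidy = "diploid") {
  nm <- if (ploidy == "diploid") c("hom_ref", "het", "hom_alt")
        else c("ref", "alt")
  stopifnot(length(probs) == length(nm))
  names(probs) <- nm
  pgtlink:::new_genotype_posterior(id, chrom, pos, ref, alt, probs, ploidy)
}

certain_post <- function(which, ...) {
  p <- c(0, 0, 0)
  p[which] <- 1
  make_post(p, ...)
}

# Independent oracle: P(reads | gt') expanded as a sum over all 2^n
# per-read haplotype choices, amplification channel enumerated explicitly.
bf_genotype_posterior <- function(reads, ref, alt, e, ado, far,
                                  prior = c(0.25, 0.5, 0.25)) {
  gts <- list(hom_ref = c(ref, ref), het = c(ref, alt),
              hom_alt = c(alt, alt))
  read_mix <- function(g) {
    n <- length(reads)
    if (n == 0) return(1)
    tot <- 0
    for (mask in 0:(2^n - 1)) {
      w <- 1
      for (j in seq_len(n)) {
        hap <- g[1 + bitwAnd(bitwShiftR(mask, j - 1L), 1L)]
        w <- w * (if (reads[j] == hap) 1 - e else e / 3) / 2
      }
      tot <- tot + w
    }
    tot
  }
  liks <- vapply(gts, function(g) {
    trans <- if (g[1] != g[2]) {
      list(list(g = g, p = 1 - ado),
           list(g = c(g[1], g[1]), p = ado / 2),
           list(g = c(g[2], g[2]), p = ado / 2))
    } else {
      other <- if (g[1] == ref) alt else ref
      list(list(g = g, p = 1 - far),
           list(g = c(g[1], other), p = far))
    }
    sum(vapply(trans, function(t) t$p * read_mix(t$g), 0))
  }, 0)
  joint <- prior * liks
  joint / sum(joint)
}

random_chain <- function(n, allow_zero = FALSE) {
  if (n == 0) return(pgtlink:::empty_chain())
  pd <- stats::runif(n)
  if (allow_zero && n > 1) pd[sample(n, 1)] <- sample(c(0, 1), 1)
  linkage_chain(pd, 1 - pd, stats::runif(n, 0, 0.5))
}

# Simulate a family and run one analysis mode; returns list(sim, calls).
run_sim_family <- function(seed, mode = "bayes_p_plus", n_embryos = 6,
                           n_sites = 60, whitelist = NULL,
                           amp = amplification_model(), base_error = 0.01,
                           ...) {
  p <- sim_params(seed = seed, n_embryos = n_embryos, n_sites = n_sites, ...)
  sim <- simulate_family(p, file.path(tempdir(), paste0("fam", seed)))
  fam <- load_family(sim$sheet, sim$vcf)
  map <- load_recomb_map(sim$map, units = "cM_per_Mb")
  mi <- sim$truth$mutation_index
  mut <- mutation_spec(p$chrom, p$mutation_pos, sim$truth$ref[mi],
                       sim$truth$alt[mi],
                       inheritance = p$inheritance, carrier = p$carrier)
  calls <- suppressWarnings(
    run_analysis(fam, mut, map, analysis_config(mode = mode),
                 amp = amp, base_error = base_error,
                 whitelist = whitelist))
  list(sim = sim, fam = fam, map = map, mut = mut, calls = calls)
}

# Collapse five categories against binary simulation truth.
status_correct <- function(calls, truth) {
  called <- ifelse(calls$category %in% c("disease", "disease_risk"),
                   "disease",
                   ifelse(calls$category %in% c("normal", "normal_risk"),
                          "normal", "risk"))
  called == unname(truth$disease_status[calls$embryo_id])
}

phase_accuracy <- function(pair, truth) {
  m <- match(as.character(pair$phase$site), as.character(truth$pos))
  ok <- pair$phase$disease_allele == truth$disease_hap[m] &
    pair$phase$normal_allele == truth$normal_hap[m]
  c(n_correct = sum(ok), n_retained = length(ok))
}
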