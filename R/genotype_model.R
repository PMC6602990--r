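#' Single-cell amplification error model
#'
#' Parameters of the whole-genome-amplification noise channel applied to a
#' true genotype before reads are observed. A heterozygous genotype loses
#' one allele (allele dropout, ADO) with probability `ado_rate`, collapsing
#' to either homozygote with probability `ado_rate/2` each; a homozygous
#' genotype gains a spurious second allele with probability
#' `false_allele_rate`, becoming heterozygous. Defaults reflect typical
#' MALBAC single-cell amplification behaviour.
#'
#' @param ado_rate Allele-dropout probability for a heterozygote, in `[0,1)`.
#' @param false_allele_rate Probability a homozygote acquires a spurious
#'   allele, in `[0,1)`.
#' @return An object of class `amplification_model`.
#' @export
amplification_model <- function(ado_rate = 0.2, false_allele_rate = 0.01) {
  stopifnot(is.numeric(ado_rate), ado_rate >= 0, ado_rate < 1,
            is.numeric(false_allele_rate), false_allele_rate >= 0,
            false_allele_rate < 1, ado_rate + false_allele_rate < 1)
  structure(list(ado_rate = ado_rate, false_allele_rate = false_allele_rate),
            class = "amplification_model")
}

#' Per-sample read observations at one site
#'
#' @param sample_id Sample identifier.
#' @param chrom,pos Site coordinates (1-based).
#' @param ref,alt Reference and alternate allele labels. Indel alleles are
#'   treated as atomic labels; the model is allele-symbolic.
#' @param reads Character vector of observed allele labels, one per read
#'   (may be empty).
#' @param base_error Per-read miscall probability, in `[0, 0.75)`. A miscall
#'   lands on each of the three other bases with probability `base_error/3`.
#' @return An object of class `site_pileup`.
#' @export
site_pileup <- function(sample_id, chrom, pos, ref, alt, reads = character(),
                        base_error = 0.01) {
  stopifnot(nzchar(ref), nzchar(alt), ref != alt,
            is.numeric(base_error), base_error >= 0, base_error < 0.75)
  if (length(reads) > 0 && (anyNA(reads) || any(!nzchar(reads)))) {
    stop("reads must be non-missing allele labels")
  }
  structure(list(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, reads = as.character(reads),
                 base_error = base_error),
            class = "site_pileup")
}

# P(read | haplotype carrying allele 'hap'): 1-e on match, e/3 otherwise.
read_given_hap <- function(reads, hap, base_error) {
  ifelse(reads == hap, 1 - base_error, base_error / 3)
}

#' Likelihood of a read set given a post-amplification genotype
#'
#' The probability of the observed reads if the amplified template has
#' genotype `gt`: each read is drawn from one of the two haplotypes with
#' probability 1/2 each (a single haplotype when `gt` is haploid), matching
#' its allele with probability `1 - base_error` and any other base with
#' probability `base_error/3`. The empty read set has likelihood 1.
#'
#' @param pileup A [site_pileup()].
#' @param gt Character vector of allele labels: length 2 for a diploid
#'   genotype (order irrelevant), length 1 for a haploid one.
#' @return A probability.
#' @examples
#' p <- site_pileup("s", "chr1", 100, "A", "G", reads = c("A", "A"),
#'                  base_error = 0.01)
#' read_set_likelihood(p, c("A", "A"))  # 0.9801
#' @export
read_set_likelihood <- function(pileup, gt) {
  stopifnot(inherits(pileup, "site_pileup"), length(gt) %in% c(1L, 2L),
            !anyNA(gt))
  reads <- pileup$reads
  if (length(reads) == 0) return(1)
  e <- pileup$base_error
  if (length(gt) == 1) {
    return(prod(read_given_hap(reads, gt, e)))
  }
  prod(read_given_hap(reads, gt[1], e) / 2 + read_given_hap(reads, gt[2], e) / 2)
}

# Post-amplification genotype distribution for a diploid true genotype.
# Returns list of list(gt=, p=).
amp_transitions <- function(gt, ref, alt, amp) {
  if (is_het(gt)) {
    list(list(gt = gt, p = 1 - amp$ado_rate),
         list(gt = c(gt[1], gt[1]), p = amp$ado_rate / 2),
         list(gt = c(gt[2], gt[2]), p = amp$ado_rate / 2))
  } else {
    other <- if (gt[1] == ref) alt else if (gt[1] == alt) ref else
      stop("homozygous genotype allele '", gt[1],
           "' is neither the site ref nor alt allele")
    list(list(gt = gt, p = 1 - amp$false_allele_rate),
         list(gt = c(gt[1], other), p = amp$false_allele_rate))
  }
}

#' Likelihood of a read set given the true genotype, after amplification
#'
#' Marginalizes the post-amplification genotype over the
#' [amplification_model()] channel:
#' `P(reads | true gt) = sum over gt' of P(gt' | gt) * P(reads | gt')`.
#' Haploid genotypes pass through unchanged (no dropout channel for a
#' single-copy template).
#'
#' @inheritParams read_set_likelihood
#' @param amp An [amplification_model()].
#' @return A probability.
#' @export
amplified_likelihood <- function(pileup, gt, amp = amplification_model()) {
  stopifnot(inherits(amp, "amplification_model"))
  if (length(gt) == 1) return(read_set_likelihood(pileup, gt))
  trans <- amp_transitions(gt, pileup$ref, pileup$alt, amp)
  sum(vapply(trans, function(t) t$p * read_set_likelihood(pileup, t$gt), 0))
}

default_prior <- function(ploidy) {
  if (ploidy == "diploid") c(hom_ref = 0.25, het = 0.5, hom_alt = 0.25)
  else c(ref = 0.5, alt = 0.5)
}

genotype_space <- function(ref, alt, ploidy) {
  if (ploidy == "diploid") {
    list(hom_ref = c(ref, ref), het = c(ref, alt), hom_alt = c(alt, alt))
  } else {
    list(ref = ref, alt = alt)
  }
}

new_genotype_posterior <- function(sample_id, chrom, pos, ref, alt, probs,
                                   ploidy) {
  structure(list(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, probs = probs, ploidy = ploidy),
            class = "genotype_posterior")
}

#' Genotype posterior from a read pileup
#'
#' Bayes posterior over the biallelic genotype space (`hom_ref`, `het`,
#' `hom_alt`; or `ref`, `alt` when haploid) given the observed reads, with
#' the amplification channel marginalized out. With no reads the prior is
#' returned unchanged.
#'
#' @inheritParams amplified_likelihood
#' @param prior Named prior over genotypes summing to 1; defaults to
#'   (1/4, 1/2, 1/4) diploid and (1/2, 1/2) haploid.
#' @param ploidy `"diploid"` or `"haploid"` (e.g. X sites in male embryos,
#'   sperm cells).
#' @return An object of class `genotype_posterior` with a `probs` vector
#'   summing to 1.
#' @export
genotype_posterior <- function(pileup, amp = amplification_model(),
                               prior = NULL,
                               ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  space <- genotype_space(pileup$ref, pileup$alt, ploidy)
  if (is.null(prior)) prior <- default_prior(ploidy)
  stopifnot(length(prior) == length(space),
            abs(sum(prior) - 1) < 1e-9, all(prior >= 0))
  if (is.null(names(prior))) names(prior) <- names(space)
  prior <- prior[names(space)]
  if (length(pileup$reads) == 0) {
    return(new_genotype_posterior(pileup$sample_id, pileup$chrom, pileup$pos,
                                  pileup$ref, pileup$alt, prior, ploidy))
  }
  lik <- vapply(space, function(g) amplified_likelihood(pileup, g, amp), 0)
  joint <- prior * lik
  tot <- sum(joint)
  if (tot <= 0) stop("zero total posterior mass at ", pileup$chrom, ":",
                     pileup$pos, " for sample ", pileup$sample_id)
  new_genotype_posterior(pileup$sample_id, pileup$chrom, pileup$pos,
                         pileup$ref, pileup$alt, joint / tot, ploidy)
}

#' @export
print.genotype_posterior <- function(x, ...) {
  cat("genotype_posterior ", x$sample_id, " @ ", x$chrom, ":", x$pos,
      " (", x$ploidy, ")\n", sep = "")
  print(round(x$probs, 6))
  invisible(x)
}

#' Genotype posterior from Phred-scaled genotype likelihoods
#'
#' Converts a PL triple (pair when haploid), as emitted by standard variant
#' callers in the VCF `PL` field, to a normalized posterior:
#' likelihood `10^(-PL/10)` times the prior, renormalized.
#'
#' @param pl Non-negative numeric vector of Phred-scaled likelihoods, length
#'   3 (`hom_ref`, `het`, `hom_alt`) or 2 (`ref`, `alt`).
#' @param prior Named prior over genotypes; defaults as in
#'   [genotype_posterior()].
#' @param sample_id,chrom,pos,ref,alt Site annotation carried through.
#' @return A `genotype_posterior`.
#' @export
posterior_from_pl <- function(pl, prior = NULL, sample_id = NA_character_,
                              chrom = NA_character_, pos = NA_integer_,
                              ref = "ref", alt = "alt") {
  if (anyNA(pl) || any(pl < 0)) stop("PL values must be non-negative")
  stopifnot(length(pl) %in% c(2L, 3L))
  ploidy <- if (length(pl) == 3) "diploid" else "haploid"
  if (is.null(prior)) prior <- default_prior(ploidy)
  stopifnot(length(prior) == length(pl), abs(sum(prior) - 1) < 1e-9)
  lik <- 10^(-pl / 10)
  joint <- as.numeric(prior) * lik
  probs <- joint / sum(joint)
  names(probs) <- names(default_prior(ploidy))
  new_genotype_posterior(sample_id, chrom, pos, ref, alt, probs, ploidy)
}

# Vectorized posterior computation from ref/alt read counts. Rows with zero
# depth get the prior. Returns an n x 3 (diploid) or n x 2 (haploid) matrix.
posteriors_from_counts <- function(nref, nalt, base_error,
                                   amp = amplification_model(),
                                   ploidy = "diploid", prior = NULL) {
  stopifnot(length(nref) == length(nalt))
  e <- base_error
  if (is.null(prior)) prior <- default_prior(ploidy)
  if (ploidy == "diploid") {
    # per-read probability of a ref read under each post-amp genotype
    pr <- c(hom_ref = 1 - e, het = (1 - e) / 2 + e / 6, hom_alt = e / 3)
    pa <- c(hom_ref = e / 3, het = (1 - e) / 2 + e / 6, hom_alt = 1 - e)
    L <- cbind(pr[1]^nref * pa[1]^nalt,
               pr[2]^nref * pa[2]^nalt,
               pr[3]^nref * pa[3]^nalt)
    A <- rbind(c(1 - amp$false_allele_rate, amp$false_allele_rate, 0),
               c(amp$ado_rate / 2, 1 - amp$ado_rate, amp$ado_rate / 2),
               c(0, amp$false_allele_rate, 1 - amp$false_allele_rate))
    Lamp <- L %*% t(A)
    joint <- sweep(Lamp, 2, prior, "*")
  } else {
    pr <- c(ref = 1 - e, alt = e / 3)
    pa <- c(ref = e / 3, alt = 1 - e)
    L <- cbind(pr[1]^nref * pa[1]^nalt, pr[2]^nref * pa[2]^nalt)
    joint <- sweep(L, 2, prior, "*")
  }
  post <- joint / rowSums(joint)
  nodata <- (nref + nalt) == 0
  if (any(nodata)) post[nodata, ] <- matrix(prior, sum(nodata),
                                            length(prior), byrow = TRUE)
  colnames(post) <- names(default_prior(ploidy))
  post
}

# Point genotype call from a posterior row: modal genotype if its mass
# reaches min_mass, else NA. gts: matrix from posteriors_from_counts;
# returns genotype strings like "A/G" (haploid: "A").
point_genotypes <- function(post, ref, alt, min_mass = 0.9) {
  ploidy <- if (ncol(post) == 3) "diploid" else "haploid"
  out <- rep(NA_character_, nrow(post))
  mode_i <- max.col(post, ties.method = "first")
  mass <- post[cbind(seq_len(nrow(post)), mode_i)]
  ok <- mass >= min_mass
  for (i in which(ok)) {
    sp <- genotype_space(ref[i], alt[i], ploidy)
    out[i] <- gt_string(sp[[mode_i[i]]])
  }
  out
}
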