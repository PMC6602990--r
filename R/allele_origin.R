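#' Classify a parent-embryo genotype combination by haplotype origin
#'
#' Given point genotypes for the carrier parent, the other parent and the
#' embryo at one linkage site, together with the carrier's phase at that
#' site (which allele sits on the disease-carrying haplotype), decides which
#' carrier haplotype could have produced the embryo genotype under Mendelian
#' transmission. If only the disease-haplotype allele explains the embryo
#' the combination is disease-supportive; if only the normal-haplotype
#' allele does, normal-supportive; if both could, neither could
#' (Mendelian-inconsistent, a genotyping-error signal), or the carrier is
#' homozygous (uninformative), the combination is neutral.
#'
#' @param carrier_gt Character vector of the carrier parent's alleles
#'   (length 2; length 1 for a hemizygous carrier is not supported — the
#'   carrier is heterozygous at informative sites by construction).
#' @param other_gt The other parent's alleles (length 2, or length 1 for a
#'   hemizygous father at X-linked sites). Ignored for male embryos at
#'   X-linked sites.
#' @param embryo_gt The embryo's alleles (length 2; length 1 for male
#'   embryos at X-linked sites).
#' @param phase Named character vector `c(disease = , normal = )`: the
#'   carrier's phased alleles at this site. Must compose the carrier's
#'   heterozygous genotype.
#' @param inheritance `"autosomal"` or `"x_linked"`.
#' @param embryo_sex `"M"` or `"F"`; required for `"x_linked"`.
#' @return One of `"disease_supportive"`, `"normal_supportive"`, `"neutral"`.
#' @export
classify_combination <- function(carrier_gt, other_gt, embryo_gt, phase,
                                 inheritance = c("autosomal", "x_linked"),
                                 embryo_sex = NULL) {
  inheritance <- match.arg(inheritance)
  stopifnot(length(carrier_gt) == 2, !anyNA(carrier_gt))
  if (!is_het(carrier_gt)) return("neutral")
  if (!setequal(names(phase), c("disease", "normal")) ||
      !setequal(unname(phase), carrier_gt)) {
    stop("phase (disease/normal alleles) does not compose the carrier genotype")
  }
  x_male <- inheritance == "x_linked" && identical(embryo_sex, "M")
  if (inheritance == "x_linked" && is.null(embryo_sex)) {
    stop("embryo_sex is required for X-linked sites")
  }
  explains <- function(transmitted) {
    if (x_male) {
      length(embryo_gt) == 1 && embryo_gt == transmitted
    } else {
      if (length(embryo_gt) != 2) stop("diploid embryo genotype expected")
      any(vapply(other_gt, function(o) {
        setequal_multiset(c(transmitted, o), embryo_gt)
      }, logical(1)))
    }
  }
  d_ok <- explains(phase[["disease"]])
  n_ok <- explains(phase[["normal"]])
  if (d_ok && !n_ok) "disease_supportive"
  else if (n_ok && !d_ok) "normal_supportive"
  else "neutral"
}

# multiset equality for allele pairs
setequal_multiset <- function(a, b) {
  length(a) == length(b) && identical(sort(a), sort(b))
}

#' Per-site haplotype-origin evidence for one embryo
#'
#' Enumerates every genotype combination of the carrier parent, the other
#' parent and the embryo at a site, weighting each combination by the
#' product of the three genotype posteriors, and classifying it with
#' [classify_combination()]. The evidence pair is
#' `p_disease = S_d + S_n/2`, `p_normal = S_no + S_n/2`
#' (sums over disease-supportive, normal-supportive and neutral mass),
#' normalized to sum to 1 so it can act as a two-state weight in the
#' linkage chain.
#'
#' @param carrier,other,embryo [genotype_posterior()] objects at the same
#'   site. For male embryos at X-linked sites `embryo` is haploid and
#'   `other` is ignored; for female embryos at X-linked sites `other` (the
#'   father) is haploid.
#' @param phase Named vector `c(disease =, normal =)` of carrier alleles.
#' @param inheritance,embryo_sex See [classify_combination()].
#' @return An object of class `site_evidence`: list with `embryo_id`,
#'   `chrom`, `pos`, `p_disease`, `p_normal`, `n_combinations`.
#' @export
site_evidence <- function(carrier, other, embryo, phase,
                          inheritance = c("autosomal", "x_linked"),
                          embryo_sex = NULL) {
  inheritance <- match.arg(inheritance)
  stopifnot(inherits(carrier, "genotype_posterior"),
            inherits(embryo, "genotype_posterior"))
  x_male <- inheritance == "x_linked" && identical(embryo_sex, "M")
  cg <- genotype_space(carrier$ref, carrier$alt, carrier$ploidy)
  eg <- genotype_space(embryo$ref, embryo$alt, embryo$ploidy)
  if (x_male) {
    og <- list(.ignored = NA_character_)
    ow <- c(.ignored = 1)
  } else {
    stopifnot(inherits(other, "genotype_posterior"))
    og <- genotype_space(other$ref, other$alt, other$ploidy)
    ow <- other$probs
  }
  s <- c(disease_supportive = 0, normal_supportive = 0, neutral = 0)
  n_comb <- 0L
  for (ci in seq_along(cg)) for (oi in seq_along(og)) for (ei in seq_along(eg)) {
    w <- carrier$probs[[ci]] * ow[[oi]] * embryo$probs[[ei]]
    n_comb <- n_comb + 1L
    if (w == 0) next
    lab <- classify_combination(cg[[ci]],
                                if (x_male) c("0", "0") else og[[oi]],
                                eg[[ei]], phase, inheritance, embryo_sex)
    s[lab] <- s[lab] + w
  }
  tot <- sum(s)
  if (tot <= 0) stop("site has no usable posterior mass")
  p_d <- s[["disease_supportive"]] + s[["neutral"]] / 2
  p_n <- s[["normal_supportive"]] + s[["neutral"]] / 2
  z <- p_d + p_n
  structure(list(embryo_id = embryo$sample_id, chrom = embryo$chrom,
                 pos = embryo$pos, p_disease = p_d / z, p_normal = p_n / z,
                 n_combinations = n_comb),
            class = "site_evidence")
}

# Vectorized evidence over many autosomal diploid sites.
# carrier_post/other_post/embryo_post: n x 3 matrices (hom_ref, het, hom_alt);
# alt_is_disease: logical vector, TRUE when the carrier's alt allele is on
# the disease haplotype. Returns n x 2 matrix (p_disease, p_normal).
# The 27-combination class table is fixed by symmetry: with disease = alt,
#   carrier het x other hom_ref x embryo het        -> disease-supportive
#   carrier het x other hom_ref x embryo hom_ref    -> normal-supportive
#   carrier het x other hom_alt x embryo hom_alt    -> disease-supportive
#   carrier het x other hom_alt x embryo het        -> normal-supportive
#   carrier het x other het    x embryo hom_alt     -> disease-supportive
#   carrier het x other het    x embryo hom_ref     -> normal-supportive
# and every other combination is neutral (carrier hom, fully ambiguous, or
# Mendelian-inconsistent). Verified against classify_combination in tests.
site_evidence_matrix <- function(carrier_post, other_post, embryo_post,
                                 alt_is_disease) {
  ch <- carrier_post[, "het"]
  sd_alt <- ch * (other_post[, "hom_ref"] * embryo_post[, "het"] +
                  other_post[, "hom_alt"] * embryo_post[, "hom_alt"] +
                  other_post[, "het"] * embryo_post[, "hom_alt"])
  sn_alt <- ch * (other_post[, "hom_ref"] * embryo_post[, "hom_ref"] +
                  other_post[, "hom_alt"] * embryo_post[, "het"] +
                  other_post[, "het"] * embryo_post[, "hom_ref"])
  s_d <- ifelse(alt_is_disease, sd_alt, sn_alt)
  s_n <- ifelse(alt_is_disease, sn_alt, sd_alt)
  s_neutral <- 1 - s_d - s_n
  p_d <- s_d + s_neutral / 2
  p_n <- s_n + s_neutral / 2
  cbind(p_disease = p_d / (p_d + p_n), p_normal = p_n / (p_d + p_n))
}

# X-linked male-embryo variant: embryo_post is n x 2 (ref, alt); the other
# parent is ignored.
site_evidence_matrix_xmale <- function(carrier_post, embryo_post,
                                       alt_is_disease) {
  ch <- carrier_post[, "het"]
  sd_alt <- ch * embryo_post[, "alt"]
  sn_alt <- ch * embryo_post[, "ref"]
  s_d <- ifelse(alt_is_disease, sd_alt, sn_alt)
  s_n <- ifelse(alt_is_disease, sn_alt, sd_alt)
  s_neutral <- 1 - s_d - s_n
  p_d <- s_d + s_neutral / 2
  p_n <- s_n + s_neutral / 2
  cbind(p_disease = p_d / (p_d + p_n), p_normal = p_n / (p_d + p_n))
}

#' Select linkage sites around the causal mutation
#'
#' Filters candidate sites for one embryo and splits them into upstream and
#' downstream lists ordered by increasing distance from the mutation.
#' Retained sites lie within `window_mb` of the mutation, have embryo read
#' depth of at least `min_reads`, an informative (heterozygous) carrier
#' parent, and a defined phase. With a site whitelist only the window check
#' applies (fixed-panel mode).
#'
#' @param pos Integer vector of candidate 1-based site positions (one
#'   chromosome, the mutation's).
#' @param mutation_pos Position of the causal mutation.
#' @param embryo_depth Read depth per site for the embryo under analysis
#'   (`Inf` to disable; sites backed by PL records count as covered).
#' @param carrier_het_prob Carrier het posterior mass per site.
#' @param phase_defined Logical per site: phase available and not discarded.
#' @param window_mb Window half-width in Mb each side (default 1.5).
#' @param min_reads Minimum embryo depth (default 2; shallow single-cell
#'   data supports a depth limit of 2-3).
#' @param het_floor Minimum carrier het posterior mass (default 0.5).
#' @param whitelist Optional vector of positions: use exactly these sites
#'   (window check only).
#' @return List with integer index vectors `upstream` and `downstream`
#'   (nearest-first), ready to be chained.
#' @export
collect_linkage_sites <- function(pos, mutation_pos, embryo_depth = Inf,
                                  carrier_het_prob = 1, phase_defined = TRUE,
                                  window_mb = 1.5, min_reads = 2,
                                  het_floor = 0.5, whitelist = NULL) {
  n <- length(pos)
  embryo_depth <- rep_len(embryo_depth, n)
  carrier_het_prob <- rep_len(carrier_het_prob, n)
  phase_defined <- rep_len(phase_defined, n)
  dist <- abs(pos - mutation_pos)
  keep <- dist > 0 & dist <= window_mb * 1e6
  if (!is.null(whitelist)) {
    keep <- keep & pos %in% whitelist
  } else {
    keep <- keep & embryo_depth >= min_reads &
      carrier_het_prob >= het_floor & phase_defined
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    warning("no linkage sites retained; analysis proceeds on the mutation ",
            "site alone")
  }
  up <- idx[pos[idx] < mutation_pos]
  down <- idx[pos[idx] > mutation_pos]
  list(upstream = up[order(dist[up])], downstream = down[order(dist[down])])
}
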