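#' Deduce the carrier-parent allele transmitted to a sample
#'
#' Mendelian subtraction at one site from point genotypes: returns the
#' unique carrier allele consistent with the sample genotype given the
#' other parent's genotype, or `NA` when ambiguous (both carrier alleles
#' could explain the sample) or Mendelian-inconsistent (neither could).
#' The attribute `"status"` distinguishes `"resolved"`, `"ambiguous"` and
#' `"inconsistent"`. Sperm cells are haploid: the observed allele is the
#' transmitted allele whenever it is one of the carrier's. Second polar
#' bodies are treated as haploid carriers of the egg's sister chromatid,
#' so their observed allele is the implied egg (transmitted) allele.
#'
#' @param carrier_gt Carrier parent alleles (length 2).
#' @param other_gt Other parent alleles (length 2, or 1 for a hemizygous
#'   father at X-linked sites); ignored for haploid samples and male
#'   embryos at X-linked sites.
#' @param sample_gt Sample alleles (length 2; length 1 for sperm, polar
#'   bodies and male embryos at X-linked sites).
#' @param inheritance `"autosomal"` or `"x_linked"`.
#' @param sample_kind `"embryo"`, `"sperm"` or `"polar_body"`.
#' @param sample_sex Embryo sex for X-linked sites.
#' @return A single allele label, or `NA_character_`, with attribute
#'   `"status"`.
#' @export
deduce_transmitted_allele <- function(carrier_gt, other_gt, sample_gt,
                                      inheritance = c("autosomal", "x_linked"),
                                      sample_kind = c("embryo", "sperm",
                                                      "polar_body"),
                                      sample_sex = NULL) {
  inheritance <- match.arg(inheritance)
  sample_kind <- match.arg(sample_kind)
  res <- function(allele, status) structure(allele, status = status)
  if (anyNA(carrier_gt) || anyNA(sample_gt)) {
    return(res(NA_character_, "ambiguous"))
  }
  if (!is_het(carrier_gt)) return(res(NA_character_, "ambiguous"))
  haploid <- sample_kind %in% c("sperm", "polar_body") ||
    (inheritance == "x_linked" && identical(sample_sex, "M"))
  if (haploid) {
    a <- sample_gt[1]
    if (a %in% carrier_gt) return(res(a, "resolved"))
    return(res(NA_character_, "inconsistent"))
  }
  if (anyNA(other_gt)) return(res(NA_character_, "ambiguous"))
  ok <- vapply(carrier_gt, function(c_allele) {
    any(vapply(other_gt, function(o) {
      setequal_multiset(c(c_allele, o), sample_gt)
    }, logical(1)))
  }, logical(1))
  hits <- unique(carrier_gt[ok])
  if (length(hits) == 1) res(hits, "resolved")
  else if (length(hits) == 0) res(NA_character_, "inconsistent")
  else res(NA_character_, "ambiguous")
}

new_haplotype_pair <- function(carrier_id, sites, disease_allele,
                               normal_allele, discarded) {
  structure(list(carrier_id = carrier_id,
                 phase = data.frame(site = sites,
                                    disease_allele = disease_allele,
                                    normal_allele = normal_allele,
                                    stringsAsFactors = FALSE),
                 n_sites = length(sites),
                 discarded = discarded),
            class = "parental_haplotype_pair")
}

#' @export
print.parental_haplotype_pair <- function(x, ...) {
  cat("parental_haplotype_pair for", x$carrier_id, "-", x$n_sites,
      "phased sites,", nrow(x$discarded), "discarded\n")
  invisible(x)
}

#' Phase the carrier parent's haplotypes with a proband sample
#'
#' At each informative site the allele the proband inherited from the
#' carrier parent is deduced by Mendelian subtraction; for an affected
#' proband that allele is labelled disease-carrying (for an unaffected
#' proband, normal), and the carrier's other allele gets the complementary
#' label. Ambiguous sites are discarded with a reason. A high fraction of
#' Mendelian-inconsistent sites triggers a hard error as a sample mix-up
#' guard.
#'
#' @param carrier_gts,other_gts,proband_gts Character vectors of point
#'   genotype strings (e.g. `"A/G"`, `NA` when uncalled), one per site.
#' @param sites Site positions (names for the output).
#' @param proband_affected `TRUE` if the proband carries the disease.
#' @param carrier_id Carrier sample id (annotation).
#' @param max_inconsistent Maximum tolerated fraction of
#'   Mendelian-inconsistent sites among deducible ones (default 0.25).
#' @return A `parental_haplotype_pair`.
#' @export
phase_with_proband <- function(carrier_gts, other_gts, proband_gts, sites,
                               proband_affected = TRUE,
                               carrier_id = "carrier",
                               max_inconsistent = 0.25) {
  n <- length(sites)
  stopifnot(length(carrier_gts) == n, length(other_gts) == n,
            length(proband_gts) == n)
  transmitted <- rep(NA_character_, n)
  status <- rep("ambiguous", n)
  for (i in seq_len(n)) {
    cg <- gt_alleles(carrier_gts[i])
    if (length(cg) != 2 || anyNA(cg)) next
    t <- deduce_transmitted_allele(cg, gt_alleles(other_gts[i]),
                                   gt_alleles(proband_gts[i]))
    transmitted[i] <- as.character(t)
    status[i] <- attr(t, "status")
  }
  n_inc <- sum(status == "inconsistent")
  n_det <- sum(status != "ambiguous")
  if (n_det > 0 && n_inc / n_det > max_inconsistent) {
    stop("proband is Mendelian-inconsistent with the parents at ", n_inc,
         " of ", n_det, " deducible sites; possible sample mix-up")
  }
  keep <- status == "resolved"
  other_allele <- vapply(which(keep), function(i) {
    cg <- gt_alleles(carrier_gts[i])
    setdiff(cg, transmitted[i])[1]
  }, "")
  disease <- if (proband_affected) transmitted[keep] else other_allele
  normal <- if (proband_affected) other_allele else transmitted[keep]
  discarded <- data.frame(site = sites[!keep],
                          reason = ifelse(status[!keep] == "inconsistent",
                                          "discordant", "ambiguous"),
                          stringsAsFactors = FALSE)
  new_haplotype_pair(carrier_id, sites[keep], disease, normal, discarded)
}

#' Phase the carrier parent's haplotypes without a proband
#'
#' Proband-free phasing by cross-validation among the alleles the carrier
#' parent transmitted to several embryos (or sperm cells): the transmitted
#' alleles are partitioned into two haplotype classes by agreement at
#' anchor sites (sites resolved in most sources), a per-class consensus is
#' built at every site, sites with more than one discordant source or with
#' identical class consensuses are discarded, and the class whose members
#' carry the causal mutation (by majority of the per-source mutation-site
#' evidence, which is itself subject to single-cell error) is labelled the
#' disease haplotype. Phasing fails hard when the evidence places the
#' mutation in both classes or in neither.
#'
#' The partition is a deterministic greedy seed-and-extend: sources are
#' ordered by completeness (ties broken by id), the most complete source
#' seeds class one, and each subsequent source joins the class whose
#' running consensus it matches at more anchor sites. Where one class has
#' no observed allele at a site, the missing consensus is filled as the
#' complement of the other class within the carrier's heterozygous
#' genotype (the two haplotypes of a heterozygote are complementary).
#'
#' @param transmitted Character matrix, sources x sites: the transmitted
#'   allele deduced per source per site (`NA` = unknown). Row names are
#'   source ids, column names site positions.
#' @param mutation_carrier Named logical: does each source carry the causal
#'   mutation (from the PCR-amplified mutation-site genotype)? `NA` allowed;
#'   such sources do not contribute to labelling.
#' @param carrier_gts Optional character vector of carrier point genotype
#'   strings per site, used for complement filling.
#' @param min_sources Minimum number of sources (default 4: proband-free
#'   phasing needs no fewer than four embryos or sperm cells).
#' @param anchor_frac Fraction of sources that must resolve a site for it
#'   to serve as an anchor (default 0.75).
#' @param carrier_id Carrier sample id (annotation).
#' @return A `parental_haplotype_pair`; attribute `"classes"` records the
#'   source partition. Discard reasons are one of `"discordant"`,
#'   `"identical_consensus"`, `"ambiguous"`.
#' @export
phase_without_proband <- function(transmitted, mutation_carrier,
                                  carrier_gts = NULL, min_sources = 4,
                                  anchor_frac = 0.75,
                                  carrier_id = "carrier") {
  stopifnot(is.matrix(transmitted))
  n_src <- nrow(transmitted)
  if (n_src < min_sources) {
    stop("proband-free phasing requires at least ", min_sources,
         " embryos or sperm cells; got ", n_src)
  }
  sites <- colnames(transmitted) %||% as.character(seq_len(ncol(transmitted)))
  ids <- rownames(transmitted) %||% paste0("src", seq_len(n_src))

  resolved_frac <- colMeans(!is.na(transmitted))
  anchors <- which(resolved_frac >= anchor_frac)
  if (length(anchors) == 0) stop("no anchor sites: too few resolved genotypes")

  # majority allele per site over a set of rows; NA on tie or no data
  consensus_of <- function(rows, cols = seq_len(ncol(transmitted))) {
    vapply(cols, function(j) {
      x <- transmitted[rows, j]
      x <- x[!is.na(x)]
      if (length(x) == 0) return(NA_character_)
      tab <- sort(table(x), decreasing = TRUE)
      if (length(tab) > 1 && tab[1] == tab[2]) return(NA_character_)
      names(tab)[1]
    }, "")
  }

  ord <- order(-rowSums(!is.na(transmitted)), ids)
  class1 <- ord[1]
  class2 <- integer()
  unassigned <- integer()
  for (k in ord[-1]) {
    cons1 <- consensus_of(class1, anchors)
    s1 <- agreement_score(transmitted[k, anchors], cons1)
    if (length(class2) == 0) {
      if (s1 > 0) class1 <- c(class1, k)
      else if (s1 < 0) class2 <- k
      else unassigned <- c(unassigned, k)
    } else {
      cons2 <- consensus_of(class2, anchors)
      s2 <- agreement_score(transmitted[k, anchors], cons2)
      if (s1 > s2) class1 <- c(class1, k)
      else if (s2 > s1) class2 <- c(class2, k)
      else unassigned <- c(unassigned, k)
    }
  }

  # Refinement: the greedy pass scores each source against a consensus
  # built from whatever was already assigned, so an erroneous seed can
  # strand later sources on a tie. Re-scoring everything against the full
  # class consensuses (a few stable passes, deterministic) recovers them.
  for (iter in 1:5) {
    cons1a <- consensus_of(class1, anchors)
    cons2a <- if (length(class2) > 0) consensus_of(class2, anchors)
              else NULL
    new1 <- integer()
    new2 <- integer()
    newu <- integer()
    for (k in ord) {
      s1 <- agreement_score(transmitted[k, anchors], cons1a)
      s2 <- if (is.null(cons2a)) -Inf
            else agreement_score(transmitted[k, anchors], cons2a)
      if (s1 > s2) new1 <- c(new1, k)
      else if (s2 > s1) new2 <- c(new2, k)
      else newu <- c(newu, k)
    }
    stable <- setequal(new1, class1) && setequal(new2, class2)
    if (length(new1) > 0) {
      class1 <- new1
      class2 <- new2
      unassigned <- newu
    }
    if (stable) break
  }

  # Observed majority allele and its support per class per site. A
  # consensus is "established" only with >= 2 agreeing members; an
  # established consensus may fill the opposite class by complementation
  # within the carrier's heterozygous genotype. The identical-consensus
  # check runs on OBSERVED majorities at any support: a consensus built
  # from erroneous deductions flips to the complementary allele and
  # collides with the other class's (correct) observation, which is
  # exactly the error signature the check removes.
  n_sites_tot <- ncol(transmitted)
  maj <- function(rows, j) {
    x <- transmitted[rows, j]
    x <- x[!is.na(x)]
    if (length(x) == 0) return(list(allele = NA_character_, support = 0L))
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      return(list(allele = NA_character_, support = 0L))
    }
    list(allele = names(tab)[1], support = as.integer(tab[1]))
  }
  obs1 <- obs2 <- final1 <- final2 <- rep(NA_character_, n_sites_tot)
  sup1 <- sup2 <- integer(n_sites_tot)
  for (j in seq_len(n_sites_tot)) {
    m1 <- maj(class1, j)
    m2 <- maj(class2, j)
    obs1[j] <- m1$allele
    sup1[j] <- m1$support
    obs2[j] <- m2$allele
    sup2[j] <- m2$support
  }
  res1 <- colSums(!is.na(transmitted[class1, , drop = FALSE]))
  res2 <- if (length(class2) > 0)
    colSums(!is.na(transmitted[class2, , drop = FALSE]))
  else integer(n_sites_tot)
  est1 <- ifelse(sup1 >= 2, obs1, NA_character_)
  est2 <- ifelse(sup2 >= 2, obs2, NA_character_)
  final1 <- est1
  final2 <- est2
  # Complement filling demands a unanimous established source consensus:
  # an erroneous 2-of-3 consensus always carries a dissenting correct
  # member, so internal discordance disqualifies it from propagating.
  fill1_ok <- sup1 >= 2 & sup1 == res1
  fill2_ok <- sup2 >= 2 & sup2 == res2
  if (!is.null(carrier_gts)) {
    for (j in seq_len(n_sites_tot)) {
      cg <- gt_alleles(carrier_gts[j])
      if (length(cg) != 2 || anyNA(cg) || !is_het(cg)) next
      if (is.na(final2[j]) && fill1_ok[j] && est1[j] %in% cg) {
        final2[j] <- setdiff(cg, est1[j])[1]
      } else if (is.na(final1[j]) && fill2_ok[j] && est2[j] %in% cg) {
        final1[j] <- setdiff(cg, est2[j])[1]
      }
    }
  }

  n_discord <- vapply(seq_len(n_sites_tot), function(j) {
    d1 <- if (is.na(final1[j])) 0L else
      sum(!is.na(transmitted[class1, j]) & transmitted[class1, j] != final1[j])
    d2 <- if (length(class2) == 0 || is.na(final2[j])) 0L else
      sum(!is.na(transmitted[class2, j]) & transmitted[class2, j] != final2[j])
    d1 + d2
  }, 0L)

  reason <- rep(NA_character_, n_sites_tot)
  same <- !is.na(obs1) & !is.na(obs2) & obs1 == obs2
  reason[same] <- "identical_consensus"
  reason[is.na(reason) & (is.na(final1) | is.na(final2))] <- "ambiguous"
  reason[is.na(reason) & n_discord > 1] <- "discordant"
  keep <- is.na(reason)
  cons1 <- final1
  cons2 <- final2

  # Label classes by the causal-mutation evidence of their members. A
  # single-cell mutation genotype can itself suffer dropout or a spurious
  # allele, so the label follows the majority within each class; a source
  # whose mutation call disagrees with its class majority is recorded as
  # discordant rather than fatal. Phasing fails hard only when the
  # majorities of both classes claim (or both deny) the mutation.
  mc <- mutation_carrier[ids]
  vote <- function(cls) {
    v <- mc[cls]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA else mean(v)
  }
  v1 <- vote(class1)
  v2 <- vote(class2)
  if (!is.na(v1) && !is.na(v2) && v1 > 0.5 && v2 > 0.5) {
    stop("phasing failed: both haplotype classes are majority ",
         "mutation-carriers")
  }
  if ((is.na(v1) || v1 == 0.5) && (is.na(v2) || v2 == 0.5)) {
    stop("phasing failed: mutation-site evidence does not separate the ",
         "two haplotype classes")
  }
  disease_is_1 <- if (is.na(v2)) v1 > 0.5
                  else if (is.na(v1)) v2 <= 0.5
                  else v1 > v2
  mut_discordant <- ids[c(
    class1[!is.na(mc[class1]) & mc[class1] != disease_is_1],
    class2[!is.na(mc[class2]) & mc[class2] == disease_is_1])]

  disease <- if (disease_is_1) cons1 else cons2
  normal <- if (disease_is_1) cons2 else cons1

  discarded <- data.frame(site = sites[!keep], reason = reason[!keep],
                          stringsAsFactors = FALSE)
  pair <- new_haplotype_pair(carrier_id, sites[keep], disease[keep],
                             normal[keep], discarded)
  attr(pair, "classes") <- list(
    disease = ids[if (disease_is_1) class1 else class2],
    normal = ids[if (disease_is_1) class2 else class1],
    unassigned = ids[unassigned],
    mutation_discordant = mut_discordant)
  pair
}

# agreement minus disagreement over positions resolved in both vectors
agreement_score <- function(x, cons) {
  both <- !is.na(x) & !is.na(cons)
  sum(x[both] == cons[both]) - sum(x[both] != cons[both])
}

#' Filter embryo evidence sites with polar-body genotypes
#'
#' The second polar body carries the sister chromatid of the egg
#' pronucleus, so (absent a crossover between them) its allele equals the
#' allele the mother transmitted to the embryo. Sites where the
#' polar-body-implied egg allele contradicts the embryo's deduced
#' transmitted allele are flagged as genotyping errors and excluded from
#' that embryo's evidence. Polar bodies never overrule embryo genotypes;
#' they only remove sites.
#'
#' @param pair A `parental_haplotype_pair` (maternal carrier).
#' @param embryo_transmitted Character matrix embryos x sites of deduced
#'   transmitted alleles (`NA` = unknown).
#' @param pb_transmitted Character matrix embryos x sites of the egg allele
#'   implied by each embryo's second polar body (`NA` = no coverage).
#' @return The pair with attribute `"embryo_exclusions"`: data frame
#'   `embryo_id`, `site`, `reason = "polar_body_conflict"`.
#' @export
augment_with_polar_bodies <- function(pair, embryo_transmitted,
                                      pb_transmitted) {
  stopifnot(inherits(pair, "parental_haplotype_pair"),
            is.matrix(embryo_transmitted), is.matrix(pb_transmitted),
            identical(dim(embryo_transmitted), dim(pb_transmitted)))
  conflict <- !is.na(embryo_transmitted) & !is.na(pb_transmitted) &
    embryo_transmitted != pb_transmitted
  idx <- which(conflict, arr.ind = TRUE)
  excl <- data.frame(
    embryo_id = (rownames(embryo_transmitted) %||%
                   as.character(seq_len(nrow(embryo_transmitted))))[idx[, 1]],
    site = (colnames(embryo_transmitted) %||%
              as.character(seq_len(ncol(embryo_transmitted))))[idx[, 2]],
    reason = rep("polar_body_conflict", nrow(idx)),
    stringsAsFactors = FALSE)
  attr(pair, "embryo_exclusions") <- excl
  pair
}
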