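#' Analysis configuration
#'
#' Priors, window, depth and classification thresholds for a linkage
#' analysis, plus the analysis mode. The disease/normal priors default to
#' 0.5 each, reflecting Mendelian transmission from a heterozygous carrier.
#'
#' Modes: `"bayes_p_plus"` (proband available, all collected sites),
#' `"p_plus_10sites"` (proband available, explicit site whitelist — the
#' fixed-panel mode), `"bayes_p_plus_pb"` (proband plus polar-body
#' filtering), `"bayes_p_minus"` (proband-free, phased from >= 4 embryos),
#' `"bayes_p_minus_sperm"` (proband-free, phased from sperm cells). The
#' mode changes site selection and phasing inputs, never the chain math.
#'
#' @param prior_disease Prior probability the embryo carries the disease
#'   allele (default 0.5); `prior_normal` is its complement.
#' @param window_mb Linkage window half-width, Mb each side (default 1.5).
#' @param min_reads Minimum embryo depth at a linkage site (default 2).
#' @param het_floor Minimum carrier het posterior mass for a site to count
#'   as informative (default 0.5).
#' @param thresholds Named increasing vector of the four classification
#'   bounds, defaults `c(normal = 1e-4, normal_risk = 0.1, risk = 0.6,
#'   disease_risk = 0.9)`.
#' @param mode Analysis mode, see Details.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(prior_disease = 0.5, window_mb = 1.5,
                            min_reads = 2, het_floor = 0.5,
                            thresholds = c(normal = 1e-4, normal_risk = 0.1,
                                           risk = 0.6, disease_risk = 0.9),
                            mode = c("bayes_p_plus", "p_plus_10sites",
                                     "bayes_p_plus_pb", "bayes_p_minus",
                                     "bayes_p_minus_sperm")) {
  mode <- match.arg(mode)
  stopifnot(prior_disease > 0, prior_disease < 1, window_mb > 0,
            min_reads >= 0, length(thresholds) == 4)
  if (!(all(diff(thresholds) > 0) && thresholds[1] > 0 && thresholds[4] < 1)) {
    stop("thresholds must satisfy 0 < t1 < t2 < t3 < t4 < 1")
  }
  structure(list(prior_disease = prior_disease,
                 prior_normal = 1 - prior_disease,
                 window_mb = window_mb, min_reads = min_reads,
                 het_floor = het_floor, thresholds = thresholds, mode = mode),
            class = "analysis_config")
}

#' Construct a linkage chain for one side of the mutation
#'
#' Bundles the per-site evidence pairs of one flank (upstream or
#' downstream), ordered nearest-first from the mutation, with the
#' recombination probabilities between consecutive sites.
#' `transitions[i]` is the recombination probability between site `i` and
#' site `i-1`, where site 0 is the mutation itself.
#'
#' @param p_disease,p_normal Evidence pairs per site (each pair sums to 1).
#' @param transitions Recombination probabilities, same length, in
#'   `[0, 0.5]`.
#' @param pos Optional site positions; with `mutation_pos` the
#'   nearest-first ordering is validated.
#' @param mutation_pos Optional mutation position for ordering validation.
#' @return An object of class `linkage_chain`.
#' @export
linkage_chain <- function(p_disease, p_normal, transitions,
                          pos = NULL, mutation_pos = NULL) {
  n <- length(p_disease)
  stopifnot(length(p_normal) == n, length(transitions) == n)
  if (n > 0) {
    stopifnot(all(p_disease >= 0), all(p_normal >= 0),
              all(abs(p_disease + p_normal - 1) < 1e-6))
    if (any(transitions < 0 | transitions > 0.5)) {
      stop("transition probabilities must lie in [0, 0.5]")
    }
    if (!is.null(pos) && !is.null(mutation_pos)) {
      d <- abs(pos - mutation_pos)
      if (is.unsorted(d, strictly = TRUE)) {
        stop("chain sites must be ordered by strictly increasing distance ",
             "from the mutation")
      }
    }
  }
  structure(list(p_disease = as.numeric(p_disease),
                 p_normal = as.numeric(p_normal),
                 transitions = as.numeric(transitions), pos = pos),
            class = "linkage_chain")
}

empty_chain <- function() linkage_chain(numeric(), numeric(), numeric())

# Backward recursion over one flank, in log space.
# Returns c(logfD, logfN): log P(sites 1..N | mutation state disease/normal).
chain_loglik <- function(chain) {
  pd <- chain$p_disease
  pn <- chain$p_normal
  r <- chain$transitions
  n <- length(pd)
  if (n == 0) return(c(D = 0, N = 0))
  lpd <- log(pd)
  lpn <- log(pn)
  lr <- log(r)
  l1r <- log1p(-r)
  # terminal site N conditioned on site N-1
  fD <- logsumexp2(lpd[n] + l1r[n], lpn[n] + lr[n])
  fN <- logsumexp2(lpd[n] + lr[n], lpn[n] + l1r[n])
  if (n > 1) {
    for (i in (n - 1):1) {
      newD <- logsumexp2(fD + lpd[i] + l1r[i], fN + lpn[i] + lr[i])
      newN <- logsumexp2(fD + lpd[i] + lr[i], fN + lpn[i] + l1r[i])
      fD <- newD
      fN <- newN
    }
  }
  c(D = fD, N = fN)
}

#' Conditional probability of a flank given the state at the mutation
#'
#' Evaluates `P(sites 1..N | mutation-site state)` by the backward
#' recursion: the evidence pair of each site is mixed with the
#' recombination probability to its inner neighbour, starting from the
#' terminal site N. Computed in log space with log-sum-exp; an empty chain
#' returns 1.
#'
#' @param chain A [linkage_chain()].
#' @param state `"disease"` or `"normal"`: the haplotype state at the
#'   mutation site.
#' @return A probability.
#' @export
chain_conditional <- function(chain, state = c("disease", "normal")) {
  state <- match.arg(state)
  stopifnot(inherits(chain, "linkage_chain"))
  ll <- chain_loglik(chain)
  exp(ll[[if (state == "disease") "D" else "N"]])
}

#' Posterior disease-carrying probability of an embryo
#'
#' Combines the upstream and downstream flank likelihoods (flanks are
#' conditionally independent given the state at the mutation) and, when
#' available, the mutation site's own evidence — attached as a special
#' linkage site whose recombination distance to the hidden state is zero —
#' through Bayes' theorem with the configured priors:
#' `P(disease | all sites) = L_D p_D / (L_D p_D + L_N p_N)`.
#'
#' @param upstream,downstream [linkage_chain()] objects (either may be
#'   empty).
#' @param mutation_evidence Optional length-2 numeric
#'   `c(p_disease, p_normal)` from the mutation-site genotype itself
#'   (PCR-enriched deep coverage); `NULL` when the mutation site could not
#'   be typed.
#' @param config An [analysis_config()].
#' @return The posterior probability, with attributes `"loglik_disease"`
#'   and `"loglik_normal"`.
#' @export
posterior_disease <- function(upstream = empty_chain(),
                              downstream = empty_chain(),
                              mutation_evidence = NULL,
                              config = analysis_config()) {
  llu <- chain_loglik(upstream)
  lld <- chain_loglik(downstream)
  lmut <- c(D = 0, N = 0)
  if (!is.null(mutation_evidence)) {
    stopifnot(length(mutation_evidence) == 2, all(mutation_evidence >= 0))
    lmut <- c(D = log(mutation_evidence[[1]]), N = log(mutation_evidence[[2]]))
  }
  llD <- llu[["D"]] + lld[["D"]] + lmut[["D"]]
  llN <- llu[["N"]] + lld[["N"]] + lmut[["N"]]
  a <- llD + log(config$prior_disease)
  b <- llN + log(config$prior_normal)
  if (is.infinite(a) && is.infinite(b) && a < 0 && b < 0) {
    stop("both disease and normal likelihoods are zero; the evidence is ",
         "self-contradictory (loglik_disease and loglik_normal both -Inf)")
  }
  p <- exp(a - logsumexp2(a, b))
  structure(p, loglik_disease = llD, loglik_normal = llN)
}

#' Classify a disease-carrying posterior into the five categories
#'
#' `p < 1e-4` is `normal`; `1e-4 <= p < 0.1` is `normal_risk`;
#' `0.1 <= p <= 0.6` is `risk`; `0.6 < p <= 0.9` is `disease_risk`;
#' `p > 0.9` is `disease`. The five half-open intervals partition `[0,1]`;
#' values exactly on a boundary fall in the more cautious category.
#'
#' @param p_disease Posterior probability (vectorized).
#' @param config An [analysis_config()] carrying the thresholds.
#' @return Character vector of categories.
#' @export
classify <- function(p_disease, config = analysis_config()) {
  stopifnot(all(p_disease >= 0 & p_disease <= 1))
  t <- config$thresholds
  ifelse(p_disease < t[["normal"]], "normal",
    ifelse(p_disease < t[["normal_risk"]], "normal_risk",
      ifelse(p_disease <= t[["risk"]], "risk",
        ifelse(p_disease <= t[["disease_risk"]], "disease_risk", "disease"))))
}

#' Error probability of an embryo call
#'
#' The probability that the assigned status is wrong: `p_disease` when the
#' embryo is called normal (or normal_risk), `1 - p_disease` when called
#' disease (or disease_risk). A `risk` call is indeterminate; its error
#' probability is reported as `min(p, 1 - p)` and flagged via the
#' `"indeterminate"` attribute.
#'
#' @param p_disease Posterior probability (vectorized).
#' @param category Matching category vector from [classify()].
#' @return Numeric vector with logical attribute `"indeterminate"`.
#' @export
error_probability <- function(p_disease, category) {
  stopifnot(length(p_disease) == length(category))
  out <- ifelse(category %in% c("normal", "normal_risk"), p_disease,
                ifelse(category %in% c("disease", "disease_risk"),
                       1 - p_disease, pmin(p_disease, 1 - p_disease)))
  attr(out, "indeterminate") <- category == "risk"
  out
}

# Exhaustive path enumeration over one flank (verification oracle).
bf_chain <- function(pd, pn, r, state) {
  n <- length(pd)
  if (n == 0) return(1)
  paths <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), n)))  # TRUE = D
  total <- 0
  for (k in seq_len(nrow(paths))) {
    o <- paths[k, ]
    w <- 1
    prev <- state == "disease"
    for (i in seq_len(n)) {
      w <- w * (if (o[i]) pd[i] else pn[i]) *
        (if (o[i] == prev) 1 - r[i] else r[i])
      prev <- o[i]
    }
    total <- total + w
  }
  total
}

#' Brute-force posterior by haplotype-origin path enumeration
#'
#' Independent oracle for [posterior_disease()]: enumerates every
#' assignment of haplotype origin (disease/normal) to every chained site,
#' accumulating the exact joint probability of each path under both
#' mutation-site states, and applies the same Bayes combination. Refuses
#' more than 20 sites in total.
#'
#' @inheritParams posterior_disease
#' @return The posterior probability.
#' @export
brute_force_posterior <- function(upstream = empty_chain(),
                                  downstream = empty_chain(),
                                  mutation_evidence = NULL,
                                  config = analysis_config()) {
  n_tot <- length(upstream$p_disease) + length(downstream$p_disease)
  if (n_tot > 20) stop("brute-force enumeration refused for more than 20 sites")
  mD <- if (is.null(mutation_evidence)) 1 else mutation_evidence[[1]]
  mN <- if (is.null(mutation_evidence)) 1 else mutation_evidence[[2]]
  LD <- bf_chain(upstream$p_disease, upstream$p_normal,
                 upstream$transitions, "disease") *
    bf_chain(downstream$p_disease, downstream$p_normal,
             downstream$transitions, "disease") * mD
  LN <- bf_chain(upstream$p_disease, upstream$p_normal,
                 upstream$transitions, "normal") *
    bf_chain(downstream$p_disease, downstream$p_normal,
             downstream$transitions, "normal") * mN
  a <- LD * config$prior_disease
  b <- LN * config$prior_normal
  if (a + b == 0) stop("both likelihoods zero")
  a / (a + b)
}
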