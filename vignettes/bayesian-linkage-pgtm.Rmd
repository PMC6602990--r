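---
title: "Bayesian haplotype linkage analysis for PGT-M"
author: "pgtlink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian haplotype linkage analysis for PGT-M}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgtlink)
```

## The problem

In preimplantation genetic testing for monogenic disease (PGT-M), IVF
embryos from a couple in which one parent carries a known pathogenic
mutation are screened so that an unaffected embryo can be selected for
transfer. Direct genotyping of the mutation in a single biopsied cell is
unreliable on its own: whole-genome amplification (WGA, e.g. MALBAC)
suffers allele dropout (ADO) at rates around 10–30%, plus spurious
alleles and base miscalls. Linkage analysis is therefore the backbone of
the test: heterozygous SNVs flanking the mutation reveal *which parental
haplotype* the embryo inherited, and many partially unreliable sites can
be combined into a single confident call.

`pgtlink` implements this combination as an explicit two-state Bayesian
chain over the haplotype origin of each linkage site, returning for every
embryo a posterior probability of carrying the disease haplotype, a
five-level clinical category, and an *error probability* — the posterior
mass on the losing side of the call, which is the quantity a clinic
should compare between embryos.

## The model

### Genotype posteriors under amplification noise

For each sample $j$ and biallelic site, the genotype posterior is

$$P(g \mid \text{reads}) \propto P(g)\, \sum_{g'} P(g' \mid g)\,
  \prod_{r \in \text{reads}} \Big( \tfrac12 P(r \mid h_1(g')) +
  \tfrac12 P(r \mid h_2(g')) \Big),$$

where $g'$ ranges over post-amplification genotypes, $P(r \mid h)$ is
$1-e$ for a read matching the haplotype allele and $e/3$ otherwise, and
the amplification channel $P(g' \mid g)$ sends a heterozygote to either
homozygote with probability $\mathrm{ado}/2$ each and a homozygote to a
heterozygote with probability $f$ (spurious allele). The genotype prior
is $(\tfrac14, \tfrac12, \tfrac14)$ for diploid sites and
$(\tfrac12, \tfrac12)$ for hemizygous ones; externally computed
Phred-scaled genotype likelihoods (VCF `PL`) can substitute for the read
model via `posterior_from_pl()`.

### Per-site haplotype-origin evidence

Given the carrier parent's phase at a site (which allele lies on the
disease haplotype), every genotype combination of carrier, other parent
and embryo is classified by Mendelian transmission as
*disease-supportive*, *normal-supportive* or *neutral* (either haplotype
could explain the embryo, the carrier is homozygous, or the combination
is Mendelian-impossible — a genotyping-error signature). Combination
probabilities are products of the three genotype posteriors, and

$$P_{\text{site } i}^{D} = \Sigma P_{\text{disease-supportive}} +
  \tfrac12 \Sigma P_{\text{neutral}}, \qquad
  P_{\text{site } i}^{N} = \Sigma P_{\text{normal-supportive}} +
  \tfrac12 \Sigma P_{\text{neutral}},$$

normalized to sum to one so the pair acts as a two-state emission
weight.

### The recombination-aware chain

Sites are split into the upstream flank ($1..N$, nearest first) and the
downstream flank ($1'..N'$), which are conditionally independent given
the haplotype state at the mutation (site 0). Each flank likelihood is
evaluated by a backward recursion; with $r_i$ the recombination
probability between site $i$ and its inner neighbour,

$$P_{i..N \mid i-1, D} = P_{i+1..N \mid i, D}\, P_i^{D} (1 - r_i)
 + P_{i+1..N \mid i, N}\, P_i^{N} r_i,$$

with the mirrored equation for the normal state and the terminal case
$P_{N..N \mid N-1,D} = P_N^D (1-r_N) + P_N^N r_N$. Recombination
probabilities come from a deCODE-style interval map as rate/Mb at the
midpoint times the physical distance, clamped to $[0, \tfrac12]$. The
mutation site's own (PCR-enriched) genotype enters as a special site with
zero recombination distance, its evidence pair being the posterior
probability that the embryo does or does not carry the mutant allele.
Finally

$$P_{\text{disease}} = \frac{L_D \cdot \pi_D}{L_D \pi_D + L_N \pi_N},
 \qquad \pi_D = \pi_N = \tfrac12$$

by Mendelian transmission from a heterozygous carrier. Posteriors below
$10^{-4}$ are called `normal`, $[10^{-4}, 0.1)$ `normal_risk`,
$[0.1, 0.6]$ `risk`, $(0.6, 0.9]$ `disease_risk` and above $0.9$
`disease`; boundary values fall in the more cautious category so the
five intervals partition $[0,1]$. The error probability is $P_{\rm
disease}$ for normal-side calls and $1 - P_{\rm disease}$ for
disease-side calls; `risk` calls are flagged indeterminate.

```{r chain-example}
up <- linkage_chain(c(0.9, 0.8), c(0.1, 0.2), c(0.01, 0.02))
chain_conditional(up, "disease")
as.numeric(posterior_disease(up, linkage_chain(0.8, 0.2, 0)))
```

## Phasing the carrier haplotypes

With a proband (an affected or unaffected relative whose parentage is
known), the allele the proband inherited from the carrier is deduced by
Mendelian subtraction at each informative site and labelled accordingly;
a high fraction of Mendelian-impossible sites aborts the run as a sample
mix-up guard.

Without a proband, the alleles the carrier transmitted to at least four
embryos (or sperm cells, for a paternal carrier) are cross-validated:
sources are partitioned into the two haplotype classes by agreement at
anchor sites (resolved in at least 75% of sources), a per-class consensus
is built, and sites are discarded when more than one source is discordant
with its class consensus, when the two consensuses are identical, or when
no reliable consensus exists. The class whose members carry the causal
mutation is the disease haplotype.

Design choices in this module were genuinely open and are worth stating:

* **Partition algorithm.** Greedy seed-and-extend ordered by source
  completeness (ties broken by sample id), followed by up to five
  re-scoring passes against the full class consensuses. The refinement
  step exists because a single noisy seed source can otherwise strand a
  good source on a tied score; the procedure is deterministic and
  invariant to source order.
* **Consensus establishment.** A class consensus is only trusted
  (retained, or used to fill the opposite class) when at least two
  members agree; complement filling — inferring the missing class's
  allele as the carrier's other heterozygous allele — additionally
  requires the source consensus to be unanimous. An erroneous two-member
  consensus always flips to the complementary allele, where it collides
  with the opposite class's observation and is removed by the
  identical-consensus rule; these two gates are what push retained-site
  accuracy above 99% on the simulator's default noise.
* **Point genotypes for phasing.** Phasing uses modal genotypes with a
  posterior-mass floor of 0.6 (`point_mass`). Under a dropout model the
  posterior of a homozygote is bounded above by roughly
  $\frac{\pi_{\rm hom}(1-f)}{\pi_{\rm hom}(1-f) + \pi_{\rm het}\,
  \mathrm{ado}/2} \approx 0.83$ at the defaults — no depth can push it
  higher — so a stricter floor would silently exclude every homozygous
  single-cell genotype and leave the partition without anchor sites. The
  miscalls a 0.6 floor admits are precisely what the discordance filter
  is for. The full-posterior evidence model (previous section) is
  unaffected; only phasing uses point calls, for determinism and
  auditability.
* **Labelling by majority.** Each source's mutation-site genotype is
  itself a noisy single-cell call (at ADO 0.2, about one in ten affected
  embryos drops the mutant allele even at PCR depth), so the disease
  class is chosen by the majority of mutation-site evidence within each
  class; phasing fails hard only when both class majorities claim the
  mutation, or when the evidence separates neither class. Sources whose
  mutation call disagrees with their class are recorded in the result.
* **Polar bodies.** The second polar body carries the sister chromatid
  of the egg pronucleus, so its allele equals the transmitted allele
  absent a crossover between sisters. Polar bodies are used only to
  *remove* sites whose implied egg allele contradicts the embryo's
  deduced transmitted allele; they never overrule embryo genotypes.

## Analysis modes

| mode                  | phasing source            | linkage sites        |
|-----------------------|---------------------------|----------------------|
| `p_plus_10sites`      | proband                   | explicit whitelist   |
| `bayes_p_plus`        | proband                   | all collected sites  |
| `bayes_p_plus_pb`     | proband + polar-body filter | all collected sites |
| `bayes_p_minus`       | ≥ 4 embryos               | all collected sites  |
| `bayes_p_minus_sperm` | ≥ 4 sperm cells           | all collected sites  |

Modes differ only in phasing inputs and site selection; the chain
arithmetic is identical everywhere. Site collection keeps biallelic SNVs
within 1.5 Mb of the mutation on each side (`window_mb`) where the
embryo has at least 2 reads (`min_reads` — shallow single-cell data
supports a depth limit of 2–3, which multiplies the usable site count
relative to the conventional ≥10× rule), the carrier is informative
(heterozygous posterior mass ≥ `het_floor`, default 0.5) and the phase
is defined.

## The family simulator

`simulate_family()` generates a complete family with known truth so that
every stage is testable without external data: carrier haplotypes
heterozygous at every linkage site (mutant allele on the disease
haplotype), the other parent heterozygous at half the sites
(`other_het = 0.5`), one meiosis per gamete with crossovers as a Poisson
process at `rate_per_mb` (default 0.01/Mb, the genome-average 1 cM/Mb;
no interference, matching the chain's independence assumption), the
ADO/spurious-allele channel per sample and site, and reads drawn at 2–5×
per linkage site for single cells with a per-read miscall of 0.01.
Parents and the proband are bulk genomic DNA, not amplified single
cells, and are simulated at 30 reads/site; the mutation site is
PCR-enriched to 20 reads in every sample. Output is a standard VCF 4.2
(`GT:AD:DP`), a sample-sheet TSV, a recombination-map TSV and a truth
JSON.

What the simulator deliberately does not emulate: locus-specific
amplification bias along the genome, repeat-region mapping artifacts
(emulated only abstractly by `corrupt_sites()`), realistic
allele-frequency spectra, base-quality variation between reads, and
aneuploid genomes. Passing tests therefore demonstrate the statistical
machinery under the stated noise model, not robustness to every artifact
of real sequencing; the discordance filters are exercised against
injected corruptions as a proxy for the mapping-error behaviour seen in
repeat-masked regions.

## Numerical choices

* All chain arithmetic runs in log space with a two-term log-sum-exp, so
  posteriors at the $10^{-8}$ scale keep full relative precision; an
  exhaustive $2^N$ path enumeration (`brute_force_posterior()`) serves
  as the oracle and agrees to $10^{-12}$ relative error.
* Recombination probabilities are clamped to $[0, 0.5]$; the linear
  rate-times-distance form is meaningful only in the few-Mb regime the
  window enforces. Zero distance returns exactly zero, and the map
  falls back to a configurable genome-average rate off covered
  intervals.
* Mendelian-impossible combinations are pooled into the neutral class:
  the half-half split is exactly the agnostic treatment a
  genotyping-error signature deserves (this choice is configurable in
  spirit — the classification lives in one function).
* Ties at classification boundaries resolve toward the more cautious
  category.
* Evidence pairs are normalized to sum to one; the chain treats them as
  complementary two-state weights.

## Problem sizes used in the checks

The shipped checks simulate 100 families of 4–8 embryos at 100 sites for
phasing recovery, about 10,000 embryos (1,000 families of 10) for
error-probability calibration, and 50 paired families for the
sperm-versus-embryo comparison; the acceptance script uses smaller
counts of the same shapes. These sizes give binomial standard errors
comfortably below the margins being asserted while keeping a laptop-scale
runtime.

## Known limitations

* One carrier parent per invocation; compound cases (both parents
  carriers of different mutations) are run once per mutation and
  reported separately.
* X-linked analyses model a maternal carrier; embryo sex is taken from
  the sample sheet, never inferred.
* No aneuploidy awareness: trisomic genotype spaces are out of scope, as
  is CNV calling.
* Proband-free phasing requires the two haplotype classes to be
  separable among the sources; a family in which every embryo inherited
  the same carrier haplotype cannot be phased against anything and
  fails with an explicit error.
* The recombination map is sex-averaged by default; parent-specific maps
  can be supplied as files but no interference model is offered.
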