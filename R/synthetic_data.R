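#' Simulation parameters for a synthetic PGT-M family
#'
#' Defaults emulate shallow single-cell whole-genome-amplified sequencing
#' around a causal mutation: a 1.5 Mb window each side, allele dropout 0.2,
#' spurious-allele rate 0.01, per-read miscall 0.01, 2-5 reads per linkage
#' site, and deep (PCR-enriched) coverage at the mutation site itself.
#'
#' @param seed Integer seed; mandatory for reproducibility.
#' @param n_sites Number of biallelic linkage SNVs in the window (default
#'   60, a typical all-available-sites count for this window).
#' @param n_embryos Number of embryos (default 6).
#' @param n_sperm Number of sperm cells (paternal carrier only; default 0).
#' @param with_proband Simulate an affected child as proband (default TRUE).
#' @param with_polar_bodies Simulate first and second polar bodies per
#'   embryo (maternal carrier only; default FALSE).
#' @param carrier `"father"` or `"mother"`.
#' @param inheritance `"autosomal"` or `"x_linked"` (X-linked implies a
#'   maternal carrier; male embryos are hemizygous).
#' @param chrom Chromosome name.
#' @param mutation_pos Mutation position (window center).
#' @param window_mb Window half-width in Mb.
#' @param rate_per_mb Recombination probability per Mb (Poisson crossover
#'   intensity; default 0.01/Mb, the genome average).
#' @param ado_rate,false_allele_rate,base_error Amplification/read noise.
#' @param depth_range Integer range of reads per linkage site for
#'   single-cell samples: embryos, sperm, polar bodies (default 2:5).
#' @param parent_depth Reads per site for the parents and the proband,
#'   which are bulk genomic DNA rather than amplified single cells
#'   (default 30).
#' @param mutation_depth Reads at the PCR-enriched mutation site (default 20).
#' @param other_het Heterozygosity of the non-carrier parent at linkage
#'   sites (default 0.5), producing a realistic mix of informative and
#'   ambiguous sites.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(seed, n_sites = 60, n_embryos = 6, n_sperm = 0,
                       with_proband = TRUE, with_polar_bodies = FALSE,
                       carrier = c("father", "mother"),
                       inheritance = c("autosomal", "x_linked"),
                       chrom = "chr11", mutation_pos = 69255368L,
                       window_mb = 1.5, rate_per_mb = 0.01,
                       ado_rate = 0.2, false_allele_rate = 0.01,
                       base_error = 0.01, depth_range = 2:5,
                       parent_depth = 30, mutation_depth = 20,
                       other_het = 0.5) {
  carrier <- match.arg(carrier)
  inheritance <- match.arg(inheritance)
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  stopifnot(n_sites >= 1, n_embryos >= 0, n_sperm >= 0,
            ado_rate >= 0, ado_rate < 1, false_allele_rate >= 0,
            false_allele_rate < 1, base_error >= 0, base_error < 1,
            rate_per_mb >= 0, other_het >= 0, other_het <= 1)
  if (inheritance == "x_linked" && carrier != "mother") {
    stop("X-linked simulation requires a maternal carrier")
  }
  if (n_sperm > 0 && carrier != "father") {
    stop("sperm cells require a paternal carrier")
  }
  if (with_polar_bodies && carrier != "mother") {
    stop("polar bodies require a maternal carrier")
  }
  structure(list(seed = as.integer(seed), n_sites = n_sites,
                 n_embryos = n_embryos, n_sperm = n_sperm,
                 with_proband = with_proband,
                 with_polar_bodies = with_polar_bodies, carrier = carrier,
                 inheritance = inheritance, chrom = chrom,
                 mutation_pos = as.integer(mutation_pos),
                 window_mb = window_mb, rate_per_mb = rate_per_mb,
                 ado_rate = ado_rate, false_allele_rate = false_allele_rate,
                 base_error = base_error, depth_range = depth_range,
                 parent_depth = parent_depth,
                 mutation_depth = mutation_depth, other_het = other_het),
            class = "sim_params")
}

BASES <- c("A", "C", "G", "T")

# One meiosis over the site grid: crossovers as a Poisson process along the
# window, no interference. haps: 2 x n allele matrix. Returns the gamete
# allele vector, its origin (1/2 per site) and the breakpoint positions.
meiosis <- function(haps, pos, rate_per_mb) {
  span_mb <- (max(pos) - min(pos)) / 1e6
  n_break <- stats::rpois(1, rate_per_mb * span_mb)
  bp <- sort(stats::runif(n_break, min(pos), max(pos)))
  start <- sample(1:2, 1)
  crossings <- vapply(pos, function(p) sum(bp < p), 0L)
  origin <- ifelse(crossings %% 2 == 0, start, 3 - start)
  list(alleles = haps[cbind(origin, seq_along(pos))], origin = origin,
       breakpoints = bp)
}

# Amplification + read channel for one sample. true_gt: list of allele
# vectors per site (length 1 or 2). Returns list(nref, nalt, dp, gt_amp).
sample_reads <- function(true_gt, ref, alt, depth, p) {
  n <- length(true_gt)
  nref <- integer(n)
  nalt <- integer(n)
  dp <- integer(n)
  for (i in seq_len(n)) {
    g <- true_gt[[i]]
    if (length(g) == 2) {
      if (is_het(g)) {
        u <- stats::runif(1)
        if (u < p$ado_rate / 2) g <- c(g[1], g[1])
        else if (u < p$ado_rate) g <- c(g[2], g[2])
      } else if (stats::runif(1) < p$false_allele_rate) {
        other <- if (g[1] == ref[i]) alt[i] else ref[i]
        g <- c(g[1], other)
      }
    }
    d <- depth[i]
    if (d > 0) {
      src <- sample(g, d, replace = TRUE)
      mis <- stats::runif(d) < p$base_error
      if (any(mis)) {
        src[mis] <- vapply(src[mis], function(b) {
          sample(setdiff(BASES, b), 1)
        }, "")
      }
      nref[i] <- sum(src == ref[i])
      nalt[i] <- sum(src == alt[i])
      dp[i] <- d
    }
  }
  list(nref = nref, nalt = nalt, dp = dp)
}

vcf_field <- function(nref, nalt, dp, haploid = FALSE) {
  gt <- character(length(nref))
  gt[nref > 0 & nalt > 0] <- if (haploid) "./." else "0/1"
  gt[nref > 0 & nalt == 0] <- if (haploid) "0" else "0/0"
  gt[nref == 0 & nalt > 0] <- if (haploid) "1" else "1/1"
  gt[nref == 0 & nalt == 0] <- if (haploid) "." else "./."
  paste0(gt, ":", nref, ",", nalt, ":", dp)
}

write_vcf_text <- function(path, chrom, pos, ref, alt, sample_fields) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pgtlink-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(sample_fields)), collapse = "\t"))
  body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT:AD:DP",
                sep = "\t")
  for (s in sample_fields) body <- paste(body, s, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a PGT-M family with known truth
#'
#' Draws parental haplotypes over a grid of biallelic SNVs around the
#' causal mutation (the carrier heterozygous at every linkage site and at
#' the mutation, with the mutant allele on the disease haplotype), runs one
#' meiosis per gamete with Poisson crossovers, applies the single-cell
#' amplification noise channel and shallow read sampling, and writes a
#' multi-sample VCF, a sample sheet, a recombination-map file and a truth
#' JSON into `dir`.
#'
#' @param params A [sim_params()].
#' @param dir Output directory (created if needed).
#' @return List with file paths (`vcf`, `sheet`, `map`, `truth_json`) and
#'   the in-memory `truth`: carrier haplotypes, per-source origin vectors
#'   and breakpoints, true genotypes at the mutation, embryo disease
#'   status and sex.
#' @export
simulate_family <- function(params, dir = tempfile("fam")) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  w <- as.integer(p$window_mb * 1e6)
  lo <- p$mutation_pos - w
  hi <- p$mutation_pos + w
  pos <- sort(sample(setdiff(seq(lo, hi), p$mutation_pos), p$n_sites))
  pos <- sort(unique(c(pos, p$mutation_pos)))
  n <- length(pos)
  mut_i <- match(p$mutation_pos, pos)
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "")

  x_linked <- p$inheritance == "x_linked"

  # carrier haplotypes: row 1 = disease-carrying, row 2 = normal
  flip <- stats::runif(n) < 0.5
  carrier_haps <- rbind(ifelse(flip, ref, alt), ifelse(flip, alt, ref))
  carrier_haps[, mut_i] <- c(alt[mut_i], ref[mut_i])

  # other parent: het with prob other_het, else a random homozygote;
  # homozygous reference at the mutation site
  o_het <- stats::runif(n) < p$other_het
  o_hom <- ifelse(stats::runif(n) < 0.5, ref, alt)
  o_flip <- stats::runif(n) < 0.5
  other_haps <- rbind(ifelse(o_het, ifelse(o_flip, ref, alt), o_hom),
                      ifelse(o_het, ifelse(o_flip, alt, ref), o_hom))
  other_haps[, mut_i] <- ref[mut_i]
  if (x_linked) other_haps <- other_haps[1, , drop = FALSE]  # father's one X

  father_haps <- if (p$carrier == "father") carrier_haps else other_haps
  mother_haps <- if (p$carrier == "mother") carrier_haps else other_haps

  carrier_gamete <- function() meiosis(carrier_haps, pos, p$rate_per_mb)
  other_gamete <- function() {
    if (x_linked) list(alleles = other_haps[1, ], origin = rep(1L, n),
                       breakpoints = numeric())
    else meiosis(other_haps, pos, p$rate_per_mb)
  }

  embryo_ids <- if (p$n_embryos > 0) sprintf("E%02d", seq_len(p$n_embryos))
                else character()
  sperm_ids <- if (p$n_sperm > 0) sprintf("S%02d", seq_len(p$n_sperm))
               else character()

  truth <- list(pos = pos, ref = ref, alt = alt,
                mutation_index = mut_i,
                carrier = p$carrier, inheritance = p$inheritance,
                disease_hap = carrier_haps[1, ], normal_hap = carrier_haps[2, ],
                origins = list(), transmitted = list(), breakpoints = list(),
                disease_status = character(), embryo_sex = character())

  samples <- list()  # sample_id -> list(gt = list per site, haploid, role, ...)

  add_sample <- function(id, role, gt, haploid = FALSE, sex = NA,
                         linked = NA) {
    samples[[id]] <<- list(role = role, gt = gt, haploid = haploid,
                           sex = sex, linked = linked)
  }

  parent_gts <- function(haps) lapply(seq_len(n), function(i) haps[, i])
  add_sample("FATHER", "father", parent_gts(father_haps),
             haploid = x_linked, sex = "M")
  add_sample("MOTHER", "mother", parent_gts(mother_haps), sex = "F")

  make_embryo <- function(force_affected = FALSE, forced_sex = NULL) {
    repeat {
      gc <- carrier_gamete()
      if (!force_affected || gc$origin[mut_i] == 1L) break
    }
    sex <- forced_sex %||% sample(c("M", "F"), 1)
    male_x <- x_linked && sex == "M"
    go <- if (male_x) NULL else other_gamete()
    gt <- lapply(seq_len(n), function(i) {
      if (male_x) gc$alleles[i] else c(gc$alleles[i], go$alleles[i])
    })
    list(gt = gt, gc = gc, sex = sex)
  }

  for (e in seq_along(embryo_ids)) {
    emb <- make_embryo()
    add_sample(embryo_ids[e], "embryo", emb$gt,
               haploid = x_linked && emb$sex == "M", sex = emb$sex)
    truth$origins[[embryo_ids[e]]] <- ifelse(emb$gc$origin == 1L, "D", "N")
    truth$transmitted[[embryo_ids[e]]] <- emb$gc$alleles
    truth$breakpoints[[embryo_ids[e]]] <- emb$gc$breakpoints
    truth$disease_status[embryo_ids[e]] <-
      if (emb$gc$origin[mut_i] == 1L) "disease" else "normal"
    truth$embryo_sex[embryo_ids[e]] <- emb$sex

    if (p$with_polar_bodies) {
      # PB2 carries the egg chromatid's sister (same transmitted alleles
      # in this model); PB1 carries the remaining homolog pair.
      pb2_id <- paste0(embryo_ids[e], "_PB2")
      pb1_id <- paste0(embryo_ids[e], "_PB1")
      add_sample(pb2_id, "polar_body",
                 lapply(seq_len(n), function(i) emb$gc$alleles[i]),
                 haploid = TRUE, linked = embryo_ids[e])
      add_sample(pb1_id, "polar_body", parent_gts(carrier_haps),
                 linked = embryo_ids[e])
      truth$origins[[pb2_id]] <- ifelse(emb$gc$origin == 1L, "D", "N")
    }
  }

  if (p$with_proband) {
    prob <- make_embryo(force_affected = TRUE,
                        forced_sex = if (x_linked) "M" else NULL)
    add_sample("PROBAND", "proband", prob$gt,
               haploid = x_linked && prob$sex == "M", sex = prob$sex)
    truth$origins[["PROBAND"]] <- ifelse(prob$gc$origin == 1L, "D", "N")
  }

  for (s in seq_along(sperm_ids)) {
    gc <- carrier_gamete()
    add_sample(sperm_ids[s], "sperm",
               lapply(seq_len(n), function(i) gc$alleles[i]), haploid = TRUE)
    truth$origins[[sperm_ids[s]]] <- ifelse(gc$origin == 1L, "D", "N")
    truth$breakpoints[[sperm_ids[s]]] <- gc$breakpoints
  }

  depth_of <- function(role) {
    d <- if (role %in% c("father", "mother", "proband")) {
      rep(p$parent_depth, n)
    } else {
      # index-based draw: sample() would expand a length-one range to 1:x
      p$depth_range[sample.int(length(p$depth_range), n, replace = TRUE)]
    }
    d[mut_i] <- max(d[mut_i], p$mutation_depth)
    d
  }
  fields <- list()
  counts <- list()
  for (id in names(samples)) {
    sm <- samples[[id]]
    rc <- sample_reads(sm$gt, ref, alt, depth_of(sm$role), p)
    counts[[id]] <- rc
    fields[[id]] <- vcf_field(rc$nref, rc$nalt, rc$dp, haploid = sm$haploid)
  }

  vcf_path <- file.path(dir, "family.vcf")
  write_vcf_text(vcf_path, p$chrom, pos, ref, alt, fields)

  sheet <- data.frame(
    sample_id = names(samples),
    role = vapply(samples, `[[`, "", "role"),
    sex = vapply(samples, function(s) as.character(s$sex %||% NA), ""),
    linked_embryo = vapply(samples, function(s) as.character(s$linked %||% NA), ""),
    affected = ifelse(vapply(samples, `[[`, "", "role") == "proband",
                      "TRUE", NA),
    stringsAsFactors = FALSE)
  sheet_path <- file.path(dir, "samples.tsv")
  write_tsv(sheet, sheet_path)

  map_path <- file.path(dir, "recomb_map.tsv")
  writeLines(paste(p$chrom, lo - 10L, hi + 10L,
                   format(p$rate_per_mb * 100, scientific = FALSE),
                   sep = "\t"), map_path)

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")

  invisible(list(vcf = vcf_path, sheet = sheet_path, map = map_path,
                 truth_json = truth_path, truth = truth, params = p))
}

#' Inject genotyping errors into a simulated VCF
#'
#' Flips the genotype of a random subset of sites, each in one random
#' sample, to exercise the discordance filters of proband-free phasing.
#' The corrupted sample field is rewritten with all reads supporting the
#' flipped genotype.
#'
#' @param vcf_path Input VCF path.
#' @param fraction Fraction of sites to corrupt, in `[0, 0.5]`.
#' @param seed Integer seed.
#' @param out_path Output path (defaults to overwriting the input).
#' @param samples Candidate sample ids (default: all samples in the VCF).
#' @param sites Optional positions eligible for corruption (default all).
#' @return List with `path` and `corrupted`: data frame `chrom`, `pos`,
#'   `sample`, `old`, `new`.
#' @export
corrupt_sites <- function(vcf_path, fraction, seed, out_path = vcf_path,
                          samples = NULL, sites = NULL) {
  stopifnot(fraction >= 0, fraction <= 0.5)
  set.seed(seed)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  gt <- v@gt
  sample_ids <- colnames(gt)[-1]
  if (is.null(samples)) samples <- sample_ids
  pos <- as.integer(fix[, "POS"])
  eligible <- if (is.null(sites)) seq_along(pos) else which(pos %in% sites)
  n_corrupt <- round(fraction * length(eligible))
  chosen <- if (n_corrupt > 0)
    eligible[sample.int(length(eligible), n_corrupt)] else integer()
  rec <- data.frame(chrom = character(), pos = integer(), sample = character(),
                    old = character(), new = character(),
                    stringsAsFactors = FALSE)
  for (i in chosen) {
    sm <- sample(samples, 1)
    col <- which(colnames(gt) == sm)
    old <- gt[i, col]
    parts <- strsplit(old, ":", fixed = TRUE)[[1]]
    dp <- suppressWarnings(as.integer(parts[3]))
    if (is.na(dp) || dp == 0) dp <- 3L
    haploid <- !grepl("/", parts[1], fixed = TRUE)
    space <- if (haploid) c("0", "1") else c("0/0", "0/1", "1/1")
    cur <- parts[1]
    newgt <- sample(setdiff(space, cur), 1)
    ad <- switch(newgt,
                 "0" = c(dp, 0L), "1" = c(0L, dp),
                 "0/0" = c(dp, 0L), "1/1" = c(0L, dp),
                 "0/1" = c(ceiling(dp / 2), floor(dp / 2)))
    if (newgt == "0/1" && ad[2] == 0) ad <- c(1L, 1L)
    newfield <- paste0(newgt, ":", ad[1], ",", ad[2], ":", sum(ad))
    gt[i, col] <- newfield
    rec <- rbind(rec, data.frame(chrom = fix[i, "CHROM"], pos = pos[i],
                                 sample = sm, old = old, new = newfield,
                                 stringsAsFactors = FALSE))
  }
  lines <- c("##fileformat=VCFv4.2",
             "##source=pgtlink-simulator",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", colnames(gt)), collapse = "\t"),
             apply(cbind(fix[, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                 "FILTER", "INFO"), drop = FALSE], gt), 1,
                   function(r) paste(ifelse(is.na(r), ".", r), collapse = "\t")))
  writeLines(lines, out_path)
  list(path = out_path, corrupted = rec)
}
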