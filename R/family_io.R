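#' Causal-mutation specification
#'
#' @param chrom Chromosome name (must match the VCF).
#' @param pos 1-based position of the causal mutation.
#' @param ref,alt Reference and mutant allele labels (indels are atomic
#'   labels, e.g. `ref = "CA"`, `alt = "C"` for a deletion).
#' @param inheritance `"autosomal"` or `"x_linked"`.
#' @param carrier `"father"` or `"mother"`. Families where both parents
#'   carry (different) mutations are analyzed once per mutation.
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(chrom, pos, ref, alt,
                          inheritance = c("autosomal", "x_linked"),
                          carrier = c("father", "mother")) {
  inheritance <- match.arg(inheritance)
  carrier <- match.arg(carrier)
  stopifnot(nzchar(ref), nzchar(alt), ref != alt)
  if (inheritance == "x_linked" && carrier == "father") {
    stop("an X-linked carrier father would transmit the mutation to every ",
         "daughter and no son; this tool models maternal X-linked carriers")
  }
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 inheritance = inheritance, carrier = carrier),
            class = "mutation_spec")
}

#' Load a family's samples and genotype data
#'
#' Reads the sample sheet (tab-delimited: columns `sample_id`, `role`,
#' optional `sex`, `linked_embryo`, `affected`) and the multi-sample VCF.
#' Multi-allelic VCF records are skipped with a message. Per-sample ref/alt
#' allele depths are taken from the `AD` field; haploid samples are
#' detected from their `GT` field shape.
#'
#' @param sheet_path Sample sheet path.
#' @param vcf_path Multi-sample VCF path (plain text or bgzipped).
#' @param mutation Optional [mutation_spec()]; when given, carrier-specific
#'   design invariants (sperm only with a paternal carrier, polar bodies
#'   only with a maternal carrier) are enforced here.
#' @return An object of class `family_data`: the design (roles, ids) plus
#'   site table and per-sample depth matrices.
#' @export
load_family <- function(sheet_path, vcf_path, mutation = NULL) {
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  need <- c("sample_id", "role")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  roles <- c("father", "mother", "embryo", "proband", "polar_body", "sperm")
  if (!all(sheet$role %in% roles)) {
    stop("unknown role(s) in sample sheet: ",
         paste(setdiff(sheet$role, roles), collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids in sheet")
  father_id <- sheet$sample_id[sheet$role == "father"]
  mother_id <- sheet$sample_id[sheet$role == "mother"]
  embryo_ids <- sheet$sample_id[sheet$role == "embryo"]
  proband_id <- sheet$sample_id[sheet$role == "proband"]
  sperm_ids <- sheet$sample_id[sheet$role == "sperm"]
  pb <- sheet[sheet$role == "polar_body", , drop = FALSE]
  if (length(father_id) != 1 || length(mother_id) != 1) {
    stop("the sample sheet must declare exactly one father and one mother")
  }
  if (length(embryo_ids) == 0) stop("the sample sheet declares no embryos")
  if (length(proband_id) > 1) stop("at most one proband sample is supported")
  if (nrow(pb) > 0 &&
      (!"linked_embryo" %in% names(sheet) ||
       any(is.na(pb$linked_embryo) | !pb$linked_embryo %in% embryo_ids))) {
    stop("every polar body must be linked to an embryo via 'linked_embryo'")
  }
  if (!is.null(mutation)) {
    stopifnot(inherits(mutation, "mutation_spec"))
    if (length(sperm_ids) > 0 && mutation$carrier != "father") {
      stop("sperm samples are only valid with a paternal carrier")
    }
    if (nrow(pb) > 0 && mutation$carrier != "mother") {
      stop("polar-body samples are only valid with a maternal carrier")
    }
  }

  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(sheet$sample_id, vcf_samples)
  if (length(missing) > 0) {
    stop("sheet sample(s) absent from the VCF: ",
         paste(missing, collapse = ", "))
  }
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE) | is.na(fix[, "ALT"])
  if (any(multi)) {
    message("skipping ", sum(multi), " multi-allelic or ALT-less site(s)")
  }
  keep <- which(!multi)
  gt <- vcfR::extract.gt(v, "GT")[keep, sheet$sample_id, drop = FALSE]
  ad <- vcfR::extract.gt(v, "AD")[keep, sheet$sample_id, drop = FALSE]
  nref <- apply(ad, 2, function(x) {
    suppressWarnings(as.integer(vapply(strsplit(x, ",", fixed = TRUE),
                                       function(p) p[1] %||% NA_character_, "")))
  })
  nalt <- apply(ad, 2, function(x) {
    suppressWarnings(as.integer(vapply(strsplit(x, ",", fixed = TRUE),
                                       function(p) if (length(p) > 1) p[2]
                                       else NA_character_, "")))
  })
  nref[is.na(nref)] <- 0L
  nalt[is.na(nalt)] <- 0L
  haploid <- vapply(sheet$sample_id, function(s) {
    g <- gt[, s]
    g <- g[!is.na(g) & g != "."]
    length(g) > 0 && mean(!grepl("[/|]", g)) > 0.5
  }, logical(1))

  sex <- if ("sex" %in% names(sheet)) {
    stats::setNames(sheet$sex, sheet$sample_id)
  } else {
    stats::setNames(rep(NA_character_, nrow(sheet)), sheet$sample_id)
  }
  affected <- if ("affected" %in% names(sheet)) {
    stats::setNames(toupper(sheet$affected) %in% "TRUE", sheet$sample_id)
  } else {
    stats::setNames(rep(TRUE, nrow(sheet)), sheet$sample_id)
  }

  design <- list(father_id = father_id, mother_id = mother_id,
                 embryo_ids = embryo_ids,
                 proband = if (length(proband_id) == 1)
                   list(id = proband_id, affected = affected[[proband_id]])
                 else NULL,
                 polar_bodies = if (nrow(pb) > 0)
                   split(pb$sample_id, pb$linked_embryo) else NULL,
                 sperm_ids = sperm_ids, sex = sex)

  structure(list(design = design,
                 sites = data.frame(chrom = fix[keep, "CHROM"],
                                    pos = as.integer(fix[keep, "POS"]),
                                    ref = fix[keep, "REF"],
                                    alt = fix[keep, "ALT"],
                                    stringsAsFactors = FALSE),
                 nref = nref, nalt = nalt, haploid = haploid),
            class = "family_data")
}

#' @export
print.family_data <- function(x, ...) {
  d <- x$design
  cat("family_data:", length(d$embryo_ids), "embryo(s),",
      length(d$sperm_ids), "sperm,",
      if (is.null(d$proband)) "no proband" else "proband present", "-",
      nrow(x$sites), "biallelic sites\n")
  invisible(x)
}

# Posterior matrices for every sample at the window sites.
# Returns list(post = list per sample, point = matrix of genotype strings).
family_posteriors <- function(fam, idx, mutation, amp, base_error,
                              point_mass = 0.6) {
  sites <- fam$sites[idx, , drop = FALSE]
  ids <- names(fam$haploid)
  post <- list()
  point <- matrix(NA_character_, length(idx), length(ids),
                  dimnames = list(NULL, ids))
  for (id in ids) {
    ploidy <- if (fam$haploid[[id]]) "haploid" else "diploid"
    pp <- posteriors_from_counts(fam$nref[idx, id], fam$nalt[idx, id],
                                 base_error, amp, ploidy)
    post[[id]] <- pp
    point[, id] <- point_genotypes(pp, sites$ref, sites$alt, point_mass)
  }
  list(post = post, point = point, sites = sites)
}

# Evidence pair for the mutation site from an embryo's genotype posterior:
# mutant-allele presence supports disease.
mutation_site_evidence <- function(post_row) {
  if (length(post_row) == 3) {
    c(post_row[["het"]] + post_row[["hom_alt"]], post_row[["hom_ref"]])
  } else {
    c(post_row[["alt"]], post_row[["ref"]])
  }
}

#' Run a linkage analysis for every embryo
#'
#' Executes the full pipeline for one causal mutation: per-sample genotype
#' posteriors in the window, carrier-haplotype phasing according to the
#' configured mode, per-site haplotype-origin evidence, recombination-aware
#' chaining, Bayes posterior, five-category classification and error
#' probability.
#'
#' @param fam A [load_family()] object.
#' @param mutation A [mutation_spec()].
#' @param map A [load_recomb_map()] object.
#' @param config An [analysis_config()]; its `mode` selects phasing inputs
#'   and site selection.
#' @param amp An [amplification_model()] for the AD-based genotype model.
#' @param base_error Per-read miscall probability.
#' @param point_mass Posterior-mass floor for the point genotypes used in
#'   phasing (default 0.6). Under a dropout model a homozygote's posterior
#'   is bounded by roughly `(1-f)/(1-f+ado)` times the prior odds and never
#'   approaches 1, so the floor must sit below that ceiling; miscalls the
#'   floor lets through are exactly what the phasing discordance filter
#'   removes.
#' @param whitelist Integer positions for `"p_plus_10sites"` mode.
#' @return Data frame with one row per embryo: `embryo_id`, `mode`,
#'   `p_disease`, `category`, `error_probability`, `n_sites_used`,
#'   `region_span_bp`. Attribute `"audit"` holds the per-site table
#'   (embryo, side, pos, evidence pair, transition); attribute `"phase"`
#'   the haplotype pair used.
#' @export
run_analysis <- function(fam, mutation, map, config = analysis_config(),
                         amp = amplification_model(), base_error = 0.01,
                         point_mass = 0.6, whitelist = NULL) {
  stopifnot(inherits(fam, "family_data"), inherits(mutation, "mutation_spec"),
            inherits(map, "recomb_map"), inherits(config, "analysis_config"))
  d <- fam$design
  mode <- config$mode
  carrier_id <- if (mutation$carrier == "father") d$father_id else d$mother_id
  other_id <- if (mutation$carrier == "father") d$mother_id else d$father_id
  x_linked <- mutation$inheritance == "x_linked"

  if (mode %in% c("bayes_p_plus", "p_plus_10sites", "bayes_p_plus_pb") &&
      is.null(d$proband)) {
    stop("mode ", mode, " requires a proband sample")
  }
  if (mode == "p_plus_10sites" && is.null(whitelist)) {
    stop("mode p_plus_10sites requires a site whitelist")
  }
  if (mode == "bayes_p_plus_pb" && is.null(d$polar_bodies)) {
    stop("mode bayes_p_plus_pb requires polar-body samples")
  }
  if (mode == "bayes_p_plus_pb" && mutation$carrier != "mother") {
    stop("polar-body filtering requires a maternal carrier")
  }
  if (mode == "bayes_p_minus_sperm") {
    if (length(d$sperm_ids) == 0) stop("mode bayes_p_minus_sperm requires ",
                                       "sperm samples")
    if (mutation$carrier != "father") stop("sperm phasing requires a ",
                                           "paternal carrier")
  }

  on_chrom <- fam$sites$chrom == mutation$chrom
  in_window <- abs(fam$sites$pos - mutation$pos) <= config$window_mb * 1e6
  idx <- which(on_chrom & in_window)
  if (length(idx) == 0) stop("no VCF sites within the analysis window")
  mut_row <- which(fam$sites$pos[idx] == mutation$pos)
  if (length(mut_row) != 1 ||
      fam$sites$ref[idx[mut_row]] != mutation$ref ||
      fam$sites$alt[idx[mut_row]] != mutation$alt) {
    stop("the causal mutation ", mutation$chrom, ":", mutation$pos, " ",
         mutation$ref, ">", mutation$alt,
         " was not found as a matching biallelic VCF record")
  }

  fp <- family_posteriors(fam, idx, mutation, amp, base_error, point_mass)
  sites <- fp$sites
  pos <- sites$pos
  n <- length(pos)

  # transmitted-allele matrix builder for a set of haploid/diploid sources
  transmitted_matrix <- function(src_ids, kinds) {
    m <- matrix(NA_character_, length(src_ids), n,
                dimnames = list(src_ids, as.character(pos)))
    for (k in seq_along(src_ids)) {
      id <- src_ids[k]
      for (i in seq_len(n)) {
        cg <- gt_alleles(fp$point[i, carrier_id])
        if (length(cg) != 2 || anyNA(cg) || !is_het(cg)) next
        sg <- gt_alleles(fp$point[i, id])
        if (anyNA(sg)) next
        t <- deduce_transmitted_allele(
          cg, gt_alleles(fp$point[i, other_id]), sg,
          inheritance = mutation$inheritance, sample_kind = kinds[k],
          sample_sex = d$sex[[id]] %||% NA_character_)
        m[k, i] <- as.character(t)
      }
    }
    m
  }

  mutation_carrier_of <- function(src_ids) {
    out <- stats::setNames(rep(NA, length(src_ids)), src_ids)
    for (id in src_ids) {
      g <- gt_alleles(fp$point[mut_row, id])
      if (anyNA(g)) next
      out[id] <- mutation$alt %in% g
    }
    out
  }

  embryo_excl <- NULL
  if (mode %in% c("bayes_p_plus", "p_plus_10sites", "bayes_p_plus_pb")) {
    pair <- phase_with_proband(
      carrier_gts = fp$point[, carrier_id],
      other_gts = fp$point[, other_id],
      proband_gts = fp$point[, d$proband$id],
      sites = pos, proband_affected = d$proband$affected,
      carrier_id = carrier_id)
    if (mode == "bayes_p_plus_pb") {
      emb_t <- transmitted_matrix(d$embryo_ids,
                                  rep("embryo", length(d$embryo_ids)))
      pb2_ids <- vapply(d$embryo_ids, function(e) {
        pbs <- d$polar_bodies[[e]] %||% character()
        hap <- pbs[fam$haploid[pbs]]
        if (length(hap) >= 1) hap[1] else NA_character_
      }, "")
      pb_t <- matrix(NA_character_, length(d$embryo_ids), n,
                     dimnames = list(d$embryo_ids, as.character(pos)))
      for (e in d$embryo_ids) {
        if (is.na(pb2_ids[[e]])) next
        cg_ok <- !is.na(fp$point[, carrier_id])
        for (i in which(cg_ok)) {
          cg <- gt_alleles(fp$point[i, carrier_id])
          if (!is_het(cg)) next
          a <- fp$point[i, pb2_ids[[e]]]
          if (!is.na(a) && a %in% cg) pb_t[e, i] <- a
        }
      }
      pair <- augment_with_polar_bodies(pair, emb_t, pb_t)
      embryo_excl <- attr(pair, "embryo_exclusions")
    }
  } else if (mode == "bayes_p_minus") {
    if (length(d$embryo_ids) < 4) {
      stop("proband-free phasing requires at least 4 embryos; got ",
           length(d$embryo_ids))
    }
    tm <- transmitted_matrix(d$embryo_ids,
                             rep("embryo", length(d$embryo_ids)))
    pair <- phase_without_proband(tm, mutation_carrier_of(d$embryo_ids),
                                  carrier_gts = fp$point[, carrier_id],
                                  carrier_id = carrier_id)
  } else {  # bayes_p_minus_sperm
    if (length(d$sperm_ids) < 4) {
      stop("proband-free phasing requires at least 4 sperm cells; got ",
           length(d$sperm_ids))
    }
    tm <- transmitted_matrix(d$sperm_ids, rep("sperm", length(d$sperm_ids)))
    pair <- phase_without_proband(tm, mutation_carrier_of(d$sperm_ids),
                                  carrier_gts = fp$point[, carrier_id],
                                  carrier_id = carrier_id)
  }

  # align phase to window sites
  ph_i <- match(as.character(pos), as.character(pair$phase$site))
  disease_allele <- pair$phase$disease_allele[ph_i]
  alt_is_disease <- !is.na(disease_allele) & disease_allele == sites$alt
  phase_defined <- !is.na(disease_allele) &
    (disease_allele == sites$alt | disease_allele == sites$ref)

  carrier_post <- fp$post[[carrier_id]]
  other_post <- fp$post[[other_id]]
  carrier_het <- if (ncol(carrier_post) == 3) carrier_post[, "het"]
                 else rep(0, n)

  calls <- NULL
  audit <- NULL
  for (eid in d$embryo_ids) {
    e_post <- fp$post[[eid]]
    e_dp <- fam$nref[idx, eid] + fam$nalt[idx, eid]
    pdef <- phase_defined
    if (!is.null(embryo_excl) && nrow(embryo_excl) > 0) {
      bad <- embryo_excl$site[embryo_excl$embryo_id == eid]
      pdef <- pdef & !(as.character(pos) %in% bad)
    }
    sel <- collect_linkage_sites(pos, mutation$pos, embryo_depth = e_dp,
                                 carrier_het_prob = carrier_het,
                                 phase_defined = pdef,
                                 window_mb = config$window_mb,
                                 min_reads = config$min_reads,
                                 het_floor = config$het_floor,
                                 whitelist = if (mode == "p_plus_10sites")
                                   whitelist else NULL)
    used <- c(sel$upstream, sel$downstream)
    male_x <- x_linked && identical(d$sex[[eid]], "M")
    ev <- if (length(used) > 0) {
      if (male_x) {
        site_evidence_matrix_xmale(carrier_post[used, , drop = FALSE],
                                   e_post[used, , drop = FALSE],
                                   alt_is_disease[used])
      } else if (x_linked && ncol(other_post) == 2) {
        o3 <- cbind(hom_ref = other_post[used, "ref"], het = 0,
                    hom_alt = other_post[used, "alt"])
        site_evidence_matrix(carrier_post[used, , drop = FALSE], o3,
                             e_post[used, , drop = FALSE],
                             alt_is_disease[used])
      } else {
        site_evidence_matrix(carrier_post[used, , drop = FALSE],
                             other_post[used, , drop = FALSE],
                             e_post[used, , drop = FALSE],
                             alt_is_disease[used])
      }
    } else matrix(numeric(), 0, 2)
    rownames(ev) <- NULL

    build_chain <- function(sel_idx) {
      if (length(sel_idx) == 0) return(empty_chain())
      m <- match(sel_idx, used)
      p_site <- pos[sel_idx]
      r <- recombination_probability(map, mutation$chrom,
                                     c(mutation$pos, p_site[-length(p_site)]),
                                     p_site)
      linkage_chain(ev[m, 1], ev[m, 2], r, pos = p_site,
                    mutation_pos = mutation$pos)
    }
    up <- build_chain(sel$upstream)
    down <- build_chain(sel$downstream)

    mut_dp <- e_dp[mut_row]
    mut_ev <- if (mut_dp >= config$min_reads)
      mutation_site_evidence(e_post[mut_row, ]) else NULL

    p <- posterior_disease(up, down, mut_ev, config)
    cat_ <- classify(as.numeric(p), config)
    errp <- error_probability(as.numeric(p), cat_)
    span_pos <- c(pos[used], mutation$pos)
    calls <- rbind(calls, data.frame(
      embryo_id = eid, mode = mode, p_disease = as.numeric(p),
      category = cat_, error_probability = as.numeric(errp),
      n_sites_used = length(used) + as.integer(!is.null(mut_ev)),
      region_span_bp = max(span_pos) - min(span_pos),
      stringsAsFactors = FALSE))
    if (length(used) > 0) {
      side <- c(rep("upstream", length(sel$upstream)),
                rep("downstream", length(sel$downstream)))
      trans <- c(up$transitions, down$transitions)
      ord <- match(used, c(sel$upstream, sel$downstream))
      audit <- rbind(audit, data.frame(
        embryo_id = eid, side = side[ord], pos = pos[used],
        p_site_disease = ev[, 1], p_site_normal = ev[, 2],
        transition = trans[ord], stringsAsFactors = FALSE))
    }
  }
  rownames(calls) <- NULL
  attr(calls, "audit") <- audit
  attr(calls, "phase") <- pair
  calls
}

#' Write analysis reports
#'
#' Emits the calls table as TSV and JSON, the per-site audit table as TSV,
#' and a run log echoing the configuration. TSV/JSON outputs are
#' deterministic for identical inputs; only the log carries a timestamp.
#'
#' @param calls Result of [run_analysis()].
#' @param out_dir Output directory (created if needed).
#' @param config Optional [analysis_config()] echoed into the log.
#' @return Named list of file paths.
#' @export
write_reports <- function(calls, out_dir, config = NULL) {
  stopifnot(is.data.frame(calls), nrow(calls) > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(calls_tsv = file.path(out_dir, "calls.tsv"),
                calls_json = file.path(out_dir, "calls.json"),
                audit_tsv = file.path(out_dir, "audit.tsv"),
                log = file.path(out_dir, "run_log.txt"))
  write_tsv(calls, paths$calls_tsv)
  jsonlite::write_json(calls, paths$calls_json, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  audit <- attr(calls, "audit")
  if (!is.null(audit)) write_tsv(audit, paths$audit_tsv)
  log_lines <- c(
    paste0("pgtlink ", as.character(utils::packageVersion("pgtlink"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("embryos: ", nrow(calls)),
    if (!is.null(config)) paste0("mode: ", config$mode),
    if (!is.null(config)) paste0("window_mb: ", config$window_mb),
    if (!is.null(config)) paste0("min_reads: ", config$min_reads))
  writeLines(log_lines, paths$log)
  invisible(paths)
}
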