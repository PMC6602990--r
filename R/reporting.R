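#' Combine embryo calls from several analysis modes
#'
#' Stacks per-mode call tables (all from one family) into a long table and
#' summarizes each mode: median linkage-site count, minimum and maximum
#' error probability, and the number of embryos whose category differs
#' from the first mode.
#'
#' @param calls_by_mode Named list of [run_analysis()] results; all tables
#'   must cover the same embryo set.
#' @return An object of class `mode_comparison`: the long data frame with
#'   attribute `"summary"`.
#' @export
compare_modes <- function(calls_by_mode) {
  stopifnot(is.list(calls_by_mode), length(calls_by_mode) >= 2)
  sets <- lapply(calls_by_mode, function(x) sort(x$embryo_id))
  if (!all(vapply(sets, identical, logical(1), sets[[1]]))) {
    stop("modes were run on different embryo sets; cannot compare")
  }
  long <- do.call(rbind, c(calls_by_mode, list(make.row.names = FALSE)))
  ref_mode <- long$mode[1]
  ref <- long[long$mode == ref_mode, ]
  summary <- do.call(rbind, lapply(split(long, long$mode), function(sub) {
    m <- match(sub$embryo_id, ref$embryo_id)
    data.frame(mode = sub$mode[1],
               n_embryos = nrow(sub),
               median_n_sites = stats::median(sub$n_sites_used),
               min_error_probability = min(sub$error_probability),
               max_error_probability = max(sub$error_probability),
               n_category_changes = sum(sub$category != ref$category[m]),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(long, summary = summary, class = c("mode_comparison",
                                               "data.frame"))
}

#' @export
print.mode_comparison <- function(x, ...) {
  print.data.frame(x, ...)
  cat("\nSummary per mode:\n")
  print.data.frame(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}

# base-graphics violin: density polygon around a vertical axis
draw_violin <- function(values, at, width = 0.4, col = "grey80") {
  values <- values[is.finite(values)]
  if (length(values) < 2 || stats::sd(values) == 0) {
    graphics::segments(at - width / 2, mean(values), at + width / 2,
                       mean(values))
    return(invisible())
  }
  d <- stats::density(values)
  sc <- width / max(d$y)
  graphics::polygon(c(at + d$y * sc, rev(at - d$y * sc)),
                    c(d$x, rev(d$x)), col = col, border = "grey40")
}

#' Plot mode-comparison summaries
#'
#' Writes three figures: a boxplot of linkage-site counts per mode, a
#' strip chart of error probabilities per mode on a log axis, and (when a
#' per-site audit table is supplied) a violin of each embryo's per-site
#' disease-origin evidence.
#'
#' @param comparison A [compare_modes()] object (a single [run_analysis()]
#'   table also works for the first two plots).
#' @param out_dir Output directory.
#' @param audit Optional per-site audit table (attribute `"audit"` of a
#'   [run_analysis()] result) for the evidence violin.
#' @return Character vector of the figure paths written.
#' @export
plot_summaries <- function(comparison, out_dir, audit = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  f1 <- file.path(out_dir, "site_counts.png")
  grDevices::png(f1, width = 700, height = 500)
  graphics::boxplot(n_sites_used ~ mode, data = comparison,
                    ylab = "linkage sites used", xlab = "mode",
                    main = "Linkage-site counts per mode")
  grDevices::dev.off()
  paths <- c(paths, f1)

  f2 <- file.path(out_dir, "error_probabilities.png")
  grDevices::png(f2, width = 700, height = 500)
  ep <- pmax(comparison$error_probability, 1e-12)
  modes <- factor(comparison$mode)
  graphics::stripchart(split(ep, modes), vertical = TRUE, log = "y",
                       pch = 19, method = "jitter", jitter = 0.08,
                       ylab = "error probability (log scale)",
                       main = "Error probability per mode",
                       ylim = range(c(ep, 1e-12, 1)))
  grDevices::dev.off()
  paths <- c(paths, f2)

  if (!is.null(audit) && nrow(audit) > 0) {
    f3 <- file.path(out_dir, "site_evidence.png")
    grDevices::png(f3, width = 800, height = 500)
    embryos <- unique(audit$embryo_id)
    graphics::plot(NULL, xlim = c(0.5, length(embryos) + 0.5), ylim = c(0, 1),
                   xaxt = "n", xlab = "embryo",
                   ylab = "P(site from disease haplotype)",
                   main = "Per-site haplotype-origin evidence")
    graphics::axis(1, at = seq_along(embryos), labels = embryos)
    for (k in seq_along(embryos)) {
      draw_violin(audit$p_site_disease[audit$embryo_id == embryos[k]], k)
    }
    grDevices::dev.off()
    paths <- c(paths, f3)
  }
  paths
}
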