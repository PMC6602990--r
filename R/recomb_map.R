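#' Load a recombination-rate map
#'
#' Reads a tab-delimited table of per-interval recombination rates in the
#' style of the deCODE genetic map: one row per genomic interval with a
#' constant rate. Coordinates are 1-based inclusive (VCF convention).
#'
#' @param path Path to a tab-delimited file with columns
#'   `chrom`, `start`, `end`, `rate`. A header line is optional and is
#'   detected automatically. Lines starting with `#` are ignored.
#' @param units Units of the `rate` column: `"cM_per_Mb"` (centimorgans per
#'   megabase, converted to probability per megabase by dividing by 100) or
#'   `"prob_per_Mb"` (already a recombination probability per megabase).
#' @param default_rate Recombination probability per megabase used for
#'   positions not covered by any interval. The default 0.01/Mb corresponds
#'   to the genome-wide average of roughly 1 cM/Mb.
#' @return An object of class `recomb_map`: a list with `intervals`
#'   (data frame `chrom`, `start`, `end`, `rate_per_mb`, sorted by start
#'   within chromosome) and `default_rate_per_mb`.
#' @seealso [recombination_probability()]
#' @examples
#' f <- tempfile()
#' writeLines("chr11\t5000000\t6000000\t1.2", f)
#' m <- load_recomb_map(f, units = "cM_per_Mb")
#' m$intervals$rate_per_mb  # 0.012
#' @export
load_recomb_map <- function(path, units = c("cM_per_Mb", "prob_per_Mb"),
                            default_rate = 0.01) {
  units <- match.arg(units)
  if (!is.numeric(default_rate) || length(default_rate) != 1 ||
      is.na(default_rate) || default_rate < 0) {
    stop("'default_rate' must be a single non-negative number")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]

  intervals <- data.frame(chrom = character(), start = integer(),
                          end = integer(), rate_per_mb = numeric(),
                          stringsAsFactors = FALSE)
  if (length(lines) > 0) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    # header detection: first row's start column is not numeric
    first <- suppressWarnings(as.numeric(fields[[1]][2]))
    row0 <- if (is.na(first)) 2L else 1L
    if (row0 > length(fields)) fields <- list() else fields <- fields[row0:length(fields)]
    n <- length(fields)
    if (n > 0) {
      for (i in seq_len(n)) {
        f <- fields[[i]]
        if (length(f) < 4) {
          stop("malformed recombination-map row at line ", i + row0 - 1L,
               ": expected 4 tab-separated columns")
        }
      }
      chrom <- vapply(fields, `[`, "", 1L)
      start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
      end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
      rate <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
      bad <- which(is.na(start) | is.na(end) | is.na(rate))
      if (length(bad) > 0) {
        stop("malformed recombination-map row at line ", bad[1] + row0 - 1L,
             ": non-numeric start/end/rate")
      }
      if (any(start >= end)) stop("recombination-map interval with start >= end")
      if (any(rate < 0)) stop("negative recombination rate in map")
      if (units == "cM_per_Mb") rate <- rate / 100
      intervals <- data.frame(chrom = chrom, start = start, end = end,
                              rate_per_mb = rate, stringsAsFactors = FALSE)
      intervals <- intervals[order(intervals$chrom, intervals$start), ,
                             drop = FALSE]
      rownames(intervals) <- NULL
      # non-overlap invariant per chromosome (1-based inclusive coordinates)
      for (chr in unique(intervals$chrom)) {
        sub <- intervals[intervals$chrom == chr, , drop = FALSE]
        if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
          stop("overlapping recombination-map intervals on ", chr)
        }
      }
    }
  }
  structure(list(intervals = intervals, default_rate_per_mb = default_rate),
            class = "recomb_map")
}

#' @export
print.recomb_map <- function(x, ...) {
  cat("recomb_map:", nrow(x$intervals), "intervals on",
      length(unique(x$intervals$chrom)), "chromosome(s);",
      "default", x$default_rate_per_mb, "/Mb\n")
  invisible(x)
}

# Rate (probability/Mb) at single positions; vectorized over pos.
rate_at <- function(map, chrom, pos) {
  out <- rep(map$default_rate_per_mb, length(pos))
  sub <- map$intervals[map$intervals$chrom == chrom, , drop = FALSE]
  if (nrow(sub) > 0) {
    idx <- findInterval(pos, sub$start)
    hit <- idx >= 1 & idx <= nrow(sub)
    hit[hit] <- pos[hit] <= sub$end[idx[hit]]
    out[hit] <- sub$rate_per_mb[idx[hit]]
  }
  out
}

#' Recombination probability between two positions
#'
#' Converts the physical distance between two sites into a per-meiosis
#' recombination probability: the map rate (probability/Mb) looked up at the
#' midpoint of the two positions, multiplied by the distance in Mb, clamped
#' to `[0, 0.5]`. Identical positions return exactly 0. The linear
#' rate-times-distance form is taken as valid only in the small-distance
#' regime of a few Mb around the mutation, hence the 0.5 cap (a single
#' interval cannot recombine with probability above one half).
#'
#' @param map A [load_recomb_map()] object.
#' @param chrom Chromosome name (single value; both positions must lie on it).
#' @param pos_a,pos_b 1-based positions (equal-length vectors are accepted
#'   and processed pairwise).
#' @return Numeric vector of recombination probabilities in `[0, 0.5]`.
#' @export
recombination_probability <- function(map, chrom, pos_a, pos_b) {
  stopifnot(inherits(map, "recomb_map"))
  if (length(chrom) != 1) {
    stop("'chrom' must be a single chromosome; cross-chromosome ",
         "recombination probabilities are undefined")
  }
  if (length(pos_a) != length(pos_b)) {
    if (length(pos_a) == 1) pos_a <- rep(pos_a, length(pos_b))
    else if (length(pos_b) == 1) pos_b <- rep(pos_b, length(pos_a))
    else stop("pos_a and pos_b must have matching lengths")
  }
  mid <- floor((pos_a + pos_b) / 2)
  rate <- rate_at(map, chrom, mid)
  p <- rate * abs(pos_a - pos_b) / 1e6
  pmin(pmax(p, 0), 0.5)
}
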