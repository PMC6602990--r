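# Internal numeric and genotype helpers.

# log(exp(a) + exp(b)) robust to -Inf and large-magnitude inputs.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Canonical unordered genotype string, e.g. c("G","A") -> "A/G".
gt_string <- function(alleles) {
  if (length(alleles) == 0 || anyNA(alleles)) return(NA_character_)
  paste(sort(alleles), collapse = "/")
}

# Split "A/G" (or haploid "A") into an allele vector; NA stays NA.
gt_alleles <- function(gt) {
  if (is.na(gt)) return(NA_character_)
  strsplit(gt, "/", fixed = TRUE)[[1]]
}

is_het <- function(alleles) length(alleles) == 2 && alleles[1] != alleles[2]

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
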