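# Brute-force helpers for the sequence-analysis modules.

# Naive all-offsets window scan: translate every codon via Biostrings'
# genetic code and test each window by explicit counting.
scan_oracle <- function(seq, rule, window = 10L, min_count = 6L) {
  resset <- list(kr = c("K", "R"), p = "P", ed = c("E", "D"))[[rule]]
  n <- nchar(seq) / 3
  hits <- list()
  for (s in seq_len(max(0, n - window + 1L))) {
    aa <- vapply(s:(s + window - 1L), function(i) {
      cod <- substr(seq, 3 * i - 2, 3 * i)
      if (grepl("[^ACGT]", cod)) NA_character_
      else unname(Biostrings::GENETIC_CODE[cod])
    }, "")
    if (any(is.na(aa))) next
    cnt <- sum(aa %in% resset)
    if (cnt >= min_count)
      hits[[length(hits) + 1L]] <- c(start = s, n_matched = cnt)
  }
  if (!length(hits))
    return(data.frame(start = integer(), n_matched = integer()))
  as.data.frame(do.call(rbind, hits))
}

# Random CDS assembled codon-wise, enriched for the rule residues so that
# qualifying windows actually occur.
random_cds <- function(n_codons, enrich = NULL, enrich_p = 0.25) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  codons <- sample(sense, n_codons, replace = TRUE)
  if (!is.null(enrich)) {
    rich <- names(gc)[gc %in% enrich]
    pick <- stats::runif(n_codons) < enrich_p
    codons[pick] <- sample(rich, sum(pick), replace = TRUE)
  }
  paste(codons, collapse = "")
}

# Interval-merge oracle for collapse_windows.
merge_oracle <- function(starts, window = 10L) {
  if (!length(starts)) return(integer())
  iv <- sort(starts)
  covered <- sort(unique(unlist(lapply(iv, function(s) s:(s + window - 1L)))))
  brk <- c(0L, which(diff(covered) > 1L), length(covered))
  vapply(seq_len(length(brk) - 1L),
         function(k) covered[brk[k] + 1L], 1L)
}
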