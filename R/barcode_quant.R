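#' Count reporter barcodes in a read set
#'
#' Extracts the 8-nt barcode at a fixed offset within each read and counts
#' exact matches against the design table.  No error correction is
#' attempted: a read whose extracted barcode is not in the design is
#' tallied as unmatched.
#'
#' @param reads character vector of read sequences (one sample).
#' @param design data.frame with columns `barcode` (unique 8-nt sequences),
#'   `reporter`, and optionally `group` (median-normalization key).
#' @param offset 0-based position of the barcode within the read.
#' @return data.frame `barcode`, `count` (one row per design barcode); the
#'   number of unmatched reads is attached as attribute `"n_unmatched"`.
#' @export
count_barcodes <- function(reads, design, offset = 0L) {
  stopifnot(all(c("barcode", "reporter") %in% names(design)))
  if (anyDuplicated(design$barcode))
    stop("design contains duplicate barcodes")
  if (any(nchar(design$barcode) != 8L))
    stop("barcodes must be exactly 8 nt")
  bclen <- 8L
  if (length(reads) && any(nchar(reads) < offset + bclen))
    stop("reads shorter than offset + barcode length")
  bc <- substr(reads, offset + 1L, offset + bclen)
  counts <- table(factor(bc, levels = design$barcode))
  out <- data.frame(barcode = design$barcode, count = as.integer(counts))
  attr(out, "n_unmatched") <- sum(!bc %in% design$barcode)
  out
}

#' Reporter mRNA levels from cDNA and gDNA barcode counts
#'
#' For every barcode passing the count threshold in both assays, the
#' mRNA level is `log2(cDNA / gDNA)`.  Levels are averaged per reporter
#' (standard error over its retained barcodes), then median-normalized
#' within each design group (each set of 5' UTR variants of one insert and
#' sample): the group's median reporter level is subtracted, so a level of
#' 0 is the group-typical reporter.
#'
#' @param cdna_counts,gdna_counts data.frames `barcode`, `count` (as from
#'   [count_barcodes()]).
#' @param design design table, see [count_barcodes()]; an absent `group`
#'   column puts all reporters in one normalization group.
#' @param min_count barcodes with fewer counts than this in either assay
#'   are discarded.
#' @return data.frame `reporter`, `group`, `n_barcodes`, `level`
#'   (median-normalized mean log2 cDNA/gDNA), `se`;
#'   reporters with no retained barcode are omitted and listed in
#'   attribute `"missing_reporters"`.
#' @export
mrna_levels <- function(cdna_counts, gdna_counts, design, min_count = 100L) {
  if (anyDuplicated(design$barcode))
    stop("design contains duplicate barcodes")
  if (is.null(design$group)) design$group <- "all"
  m <- merge(merge(design, cdna_counts, by = "barcode"),
             gdna_counts, by = "barcode", suffixes = c("_cdna", "_gdna"))
  m <- m[m$count_cdna >= min_count & m$count_gdna >= min_count, ,
         drop = FALSE]
  m$level <- log2(m$count_cdna / m$count_gdna)
  reporters <- unique(design[, c("reporter", "group")])
  per <- lapply(seq_len(nrow(reporters)), function(k) {
    v <- m$level[m$reporter == reporters$reporter[k]]
    if (length(v) == 0) return(NULL)
    data.frame(reporter = reporters$reporter[k],
               group = reporters$group[k],
               n_barcodes = length(v), level = mean(v),
               se = if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
                    else NA_real_)
  })
  out <- do.call(rbind, per)
  missing <- setdiff(reporters$reporter,
                     if (is.null(out)) character() else out$reporter)
  if (is.null(out))
    out <- data.frame(reporter = character(), group = character(),
                      n_barcodes = integer(), level = numeric(),
                      se = numeric())
  for (g in unique(out$group)) {
    sel <- out$group == g
    out$level[sel] <- out$level[sel] - stats::median(out$level[sel])
  }
  rownames(out) <- NULL
  attr(out, "missing_reporters") <- missing
  out
}
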