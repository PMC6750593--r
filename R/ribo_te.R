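#' P-site coverage tracks from aligned-read records
#'
#' Assigns each read to the 13th nucleotide from its 5' end (the inferred
#' P-site position for yeast ribosome footprints) and accumulates
#' per-nucleotide counts in CDS coordinates.  Reads whose assigned position
#' falls outside the transcript are dropped and tallied.
#'
#' @param alignments data.frame with columns `transcript`, `pos` (1-based
#'   5'-most aligned nucleotide) and optionally `len` (read length,
#'   unused by the assignment itself).
#' @param transcript_lengths named integer vector of CDS lengths (nt).
#' @param offset nucleotides added to the 5' position (12 places the count
#'   on the 13th nucleotide).
#' @return named list of integer coverage vectors, one per transcript in
#'   `transcript_lengths`; the number of dropped reads is attached as
#'   attribute `"n_dropped"`.
#' @export
psite_coverage <- function(alignments, transcript_lengths, offset = 12L) {
  stopifnot(all(c("transcript", "pos") %in% names(alignments)),
            !is.null(names(transcript_lengths)))
  psite <- alignments$pos + offset
  len <- transcript_lengths[alignments$transcript]
  ok <- !is.na(len) & psite >= 1L & psite <= len
  tracks <- lapply(names(transcript_lengths), function(tx) {
    sel <- ok & alignments$transcript == tx
    tabulate(psite[sel], nbins = transcript_lengths[[tx]])
  })
  names(tracks) <- names(transcript_lengths)
  attr(tracks, "n_dropped") <- sum(!ok)
  tracks
}

#' Metagene density profile around stall (or control) windows
#'
#' For every region, extracts a fixed window of `window_len` nucleotides
#' starting `flank` nt 5' of the region start, normalizes it by its own
#' mean coverage, and averages the normalized coverage position-wise
#' across regions.  The offset axis is anchored so the first nucleotide of
#' the region is at offset +1.  Windows that extend beyond their
#' transcript or have zero mean coverage are excluded.
#'
#' @param tracks named list of per-nucleotide coverage vectors.
#' @param regions data.frame with columns `transcript` (or `gene`) and
#'   `start_nt` (1-based first nucleotide of the region).
#' @param flank nucleotides included 5' of the region start.
#' @param window_len total normalization window length, nt.
#' @return data.frame `offset`, `density` (mean normalized coverage),
#'   with the number of contributing windows as attribute `"n_windows"`.
#' @export
metagene_profile <- function(tracks, regions, flank = 50L,
                             window_len = 150L) {
  txcol <- if ("transcript" %in% names(regions)) "transcript" else "gene"
  stopifnot("start_nt" %in% names(regions))
  acc <- matrix(NA_real_, nrow(regions), window_len)
  used <- 0L
  for (k in seq_len(nrow(regions))) {
    trk <- tracks[[regions[[txcol]][k]]]
    if (is.null(trk)) next
    from <- regions$start_nt[k] - flank
    to <- from + window_len - 1L
    if (from < 1L || to > length(trk)) next
    w <- trk[from:to]
    mw <- mean(w)
    if (mw == 0) next
    used <- used + 1L
    acc[used, ] <- w / mw
  }
  if (used == 0L) stop("no usable windows: all regions were out of bounds or had zero coverage")
  prof <- colMeans(acc[seq_len(used), , drop = FALSE])
  out <- data.frame(offset = seq.int(1L - flank, window_len - flank),
                    density = prof)
  attr(out, "n_windows") <- used
  out
}

#' Translation efficiency from rpkm tables
#'
#' TE per gene is the ratio of ribosome-footprint rpkm to mRNA rpkm.  Only
#' genes with at least `min_rpkm` in both samples are retained.
#'
#' @param ribo,rna data.frames with columns `gene` and `rpkm`.
#' @param min_rpkm retention threshold applied to each sample.
#' @return data.frame `gene`, `ribo_rpkm`, `rna_rpkm`, `te`.
#' @export
compute_te <- function(ribo, rna, min_rpkm = 5) {
  stopifnot(all(c("gene", "rpkm") %in% names(ribo)),
            all(c("gene", "rpkm") %in% names(rna)))
  m <- merge(ribo, rna, by = "gene", suffixes = c("_ribo", "_rna"))
  m <- m[m$rpkm_ribo >= min_rpkm & m$rpkm_rna >= min_rpkm, , drop = FALSE]
  data.frame(gene = m$gene, ribo_rpkm = m$rpkm_ribo, rna_rpkm = m$rpkm_rna,
             te = m$rpkm_ribo / m$rpkm_rna, row.names = NULL)
}

#' Translation efficiency of the mRNA region 5' of the stall
#'
#' Restricts ribosome-footprint and mRNA coverage to CDS nucleotides
#' `1 .. 3 * (boundary - 1)`, where the boundary codon is the gene's first
#' stall-region start, or `control_boundary` for genes without a stall
#' (the median stall location on stall-containing genes).  Genes with
#' fewer than `min_reads` in the region in either assay are excluded; TE
#' is the library-size-normalized ratio of region counts.
#'
#' @param tracks_ribo,tracks_rna named lists of coverage vectors.
#' @param boundaries data.frame with columns `gene` and `stall_codon`
#'   (NA for genes without a stall).
#' @param min_reads minimum region reads per assay.
#' @param control_boundary boundary codon for stall-free genes.
#' @return data.frame `gene`, `stall` (logical), `ribo_reads`,
#'   `rna_reads`, `te`.
#' @export
te_upstream <- function(tracks_ribo, tracks_rna, boundaries,
                        min_reads = 100L, control_boundary = 215L) {
  stopifnot(all(c("gene", "stall_codon") %in% names(boundaries)))
  lib_ribo <- sum(vapply(tracks_ribo, sum, 1))
  lib_rna <- sum(vapply(tracks_rna, sum, 1))
  rows <- lapply(seq_len(nrow(boundaries)), function(k) {
    g <- boundaries$gene[k]
    b <- boundaries$stall_codon[k]
    stall <- !is.na(b)
    if (!stall) b <- control_boundary
    if (b <= 1L) {
      warning("gene ", g, ": boundary codon <= 1, skipped")
      return(NULL)
    }
    tr_r <- tracks_ribo[[g]]; tr_m <- tracks_rna[[g]]
    if (is.null(tr_r) || is.null(tr_m)) return(NULL)
    n <- min(3L * (b - 1L), length(tr_r), length(tr_m))
    cr <- sum(tr_r[seq_len(n)]); cm <- sum(tr_m[seq_len(n)])
    if (cr < min_reads || cm < min_reads) return(NULL)
    data.frame(gene = g, stall = stall, ribo_reads = cr, rna_reads = cm,
               te = (cr / lib_ribo) / (cm / lib_rna))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), stall = logical(),
                      ribo_reads = numeric(), rna_reads = numeric(),
                      te = numeric())
  rownames(out) <- NULL
  out
}

#' Compare translation efficiency between stall and no-stall gene groups
#'
#' Reports the difference of group mean log2 TE (no-stall minus stall; a
#' positive value means stall-containing genes are translated less
#' efficiently) together with a two-sided Wilcoxon rank-sum p-value.  The
#' difference of group medians is included as an alternative summary.
#'
#' @param te data.frame with columns `te` and logical `stall`.
#' @return list `delta_log2_te` (difference of means),
#'   `delta_log2_te_median`, `p_value`, `n_stall`, `n_no_stall`.
#' @export
compare_te_groups <- function(te) {
  stopifnot(all(c("te", "stall") %in% names(te)))
  a <- log2(te$te[!te$stall])   # no-stall group
  b <- log2(te$te[te$stall])    # stall group
  if (length(a) == 0 || length(b) == 0)
    stop("both gene groups must be non-empty")
  p <- if (length(unique(c(a, b))) == 1L) 1 else
    stats::wilcox.test(a, b, exact = FALSE)$p.value
  list(delta_log2_te = mean(a) - mean(b),
       delta_log2_te_median = stats::median(a) - stats::median(b),
       p_value = p,
       n_stall = length(b), n_no_stall = length(a))
}
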