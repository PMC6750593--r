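## Residue sets for the window rules: polybasic (Lys/Arg), polyproline,
## and the acidic (Glu/Asp) control.
.rule_residues <- list(kr = c("K", "R"), p = "P", ed = c("E", "D"))

.as_cds_string <- function(cds) {
  if (methods::is(cds, "DNAString") || methods::is(cds, "DNAStringSet"))
    cds <- as.character(cds)
  if (!is.character(cds) || length(cds) != 1L)
    stop("cds must be a single nucleotide sequence")
  toupper(cds)
}

.translate_codons <- function(seq) {
  n <- nchar(seq)
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])  # NA for ambiguous codons
  list(codons = codons, aa = aa)
}

#' Scan a coding sequence for stall-encoding 10-codon windows
#'
#' Slides a `window`-codon frame across the CDS at single-codon stride and
#' reports every offset whose translated residues contain at least
#' `min_count` residues from the rule's set: lysine/arginine
#' (`rule = "kr"`, polybasic stalls), proline (`"p"`), or the
#' glutamate/aspartate control (`"ed"`).  Windows containing a codon with
#' ambiguous nucleotides never qualify.
#'
#' @param cds a single CDS as a character string or `DNAString(Set)` of
#'   length 1; length must be a multiple of 3.
#' @param rule `"kr"`, `"p"` or `"ed"`.
#' @param gene gene identifier carried into the output.
#' @param window window length in codons.
#' @param min_count minimum matching residues per window.
#' @return data.frame with one row per qualifying window: `gene`, `start`
#'   (1-based codon index), `window`, `rule`, `n_matched`.
#' @examples
#' scan_windows(strrep("AAG", 10), "kr", gene = "lys10")
#' @export
scan_windows <- function(cds, rule = c("kr", "p", "ed"), gene = NA_character_,
                         window = 10L, min_count = 6L) {
  rule <- match.arg(rule)
  seq <- .as_cds_string(cds)
  if (nchar(seq) %% 3 != 0)
    stop("CDS length of gene '", gene, "' (", nchar(seq),
         " nt) is not a multiple of 3")
  tr <- .translate_codons(seq)
  n <- length(tr$aa)
  empty <- data.frame(gene = character(), start = integer(),
                      window = integer(), rule = character(),
                      n_matched = integer())
  if (n < window) return(empty)
  hit <- as.integer(tr$aa %in% .rule_residues[[rule]])
  bad <- as.integer(is.na(tr$aa))
  ## rolling window sums at stride one codon
  csum <- cumsum(c(0L, hit))
  cbad <- cumsum(c(0L, bad))
  starts <- seq_len(n - window + 1L)
  cnt <- csum[starts + window] - csum[starts]
  nbad <- cbad[starts + window] - cbad[starts]
  keep <- cnt >= min_count & nbad == 0L
  if (!any(keep)) return(empty)
  data.frame(gene = gene, start = starts[keep], window = as.integer(window),
             rule = rule, n_matched = cnt[keep])
}

#' Collapse qualifying windows into maximal stall regions
#'
#' Merges overlapping or directly adjacent qualifying windows from one gene
#' into maximal non-overlapping regions; each region is reported by the
#' start codon of its first window.
#'
#' @param windows data.frame from [scan_windows()] (one gene; any rule mix).
#' @return data.frame `gene`, `region_start`, `region_end` (last codon
#'   covered by any member window), `n_windows`.
#' @export
collapse_windows <- function(windows) {
  if (nrow(windows) == 0)
    return(data.frame(gene = character(), region_start = integer(),
                      region_end = integer(), n_windows = integer()))
  if (length(unique(windows$gene)) > 1L)
    stop("collapse_windows expects windows from a single gene")
  w <- windows[order(windows$start), , drop = FALSE]
  ends <- w$start + w$window - 1L
  reg_start <- w$start[1]; reg_end <- ends[1]; nwin <- 1L
  out <- list()
  for (k in seq_len(nrow(w))[-1]) {
    if (w$start[k] <= reg_end + 1L) {   # overlap or adjacency
      reg_end <- max(reg_end, ends[k]); nwin <- nwin + 1L
    } else {
      out[[length(out) + 1L]] <- c(reg_start, reg_end, nwin)
      reg_start <- w$start[k]; reg_end <- ends[k]; nwin <- 1L
    }
  }
  out[[length(out) + 1L]] <- c(reg_start, reg_end, nwin)
  out <- do.call(rbind, out)
  data.frame(gene = w$gene[1], region_start = out[, 1],
             region_end = out[, 2], n_windows = out[, 3])
}

#' Scan a whole CDS set and summarize stall content per gene
#'
#' Applies [scan_windows()] with one or more rules to every coding sequence
#' (dropping genes flagged as "Dubious"), collapses qualifying windows into
#' regions per gene, and counts the genes carrying at least one region.
#' Sequences whose length is not a multiple of 3 are rejected with a
#' warning naming the gene.
#'
#' @param cds a named character vector, a `DNAStringSet`, or the path to a
#'   FASTA file (read with `Biostrings::readDNAStringSet`); names carry the
#'   gene ids.
#' @param rules character vector of window rules; a gene counts as
#'   stall-containing if any rule yields a window.
#' @param status optional character/logical vector (parallel to `cds`)
#'   marking genes to exclude; entries equal to `"Dubious"` (or `TRUE`)
#'   are dropped.  If `NULL`, a `"Dubious"` token in the FASTA header is
#'   honoured.
#' @param window,min_count window geometry, see [scan_windows()].
#' @return list with `windows` (all qualifying windows), `regions`
#'   (collapsed regions with a `first` flag on each gene's most 5'
#'   region), `genes` (per-gene summary with `first_region_start`),
#'   `n_genes_with_stall`, and `rejected` (ids of skipped sequences).
#' @export
annotate_cds_set <- function(cds, rules = c("kr", "p"), status = NULL,
                             window = 10L, min_count = 6L) {
  if (is.character(cds) && length(cds) == 1L && file.exists(cds))
    cds <- Biostrings::readDNAStringSet(cds)
  seqs <- if (methods::is(cds, "DNAStringSet")) as.character(cds) else cds
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every CDS must carry a gene id in its name")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate gene ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  if (is.null(status)) status <- grepl("Dubious", names(seqs))
  if (is.character(status)) status <- grepl("Dubious", status)
  keep <- !status
  seqs <- stats::setNames(seqs[keep], ids[keep])

  rejected <- character()
  win_list <- list()
  reg_list <- list()
  for (g in names(seqs)) {
    if (nchar(seqs[[g]]) %% 3 != 0) { rejected <- c(rejected, g); next }
    w <- do.call(rbind, lapply(rules, function(r)
      scan_windows(seqs[[g]], r, gene = g,
                   window = window, min_count = min_count)))
    if (nrow(w)) {
      win_list[[g]] <- w
      reg_list[[g]] <- collapse_windows(w)
    }
  }
  if (length(rejected))
    warning("rejected (length not a multiple of 3): ",
            paste(rejected, collapse = ", "))
  windows <- if (length(win_list)) do.call(rbind, win_list) else
    data.frame(gene = character(), start = integer(), window = integer(),
               rule = character(), n_matched = integer())
  regions <- if (length(reg_list)) do.call(rbind, reg_list) else
    data.frame(gene = character(), region_start = integer(),
               region_end = integer(), n_windows = integer())
  rownames(windows) <- rownames(regions) <- NULL
  if (nrow(regions))
    regions$first <- !duplicated(regions$gene)
  else regions$first <- logical()
  genes <- data.frame(
    gene = names(seqs)[!(names(seqs) %in% rejected)])
  first <- regions[regions$first, c("gene", "region_start")]
  genes$first_region_start <-
    first$region_start[match(genes$gene, first$gene)]
  genes$n_regions <- vapply(genes$gene, function(g)
    sum(regions$gene == g), 1L)
  list(windows = windows, regions = regions, genes = genes,
       n_genes_with_stall = sum(genes$n_regions > 0),
       rejected = rejected)
}

#' Write collapsed stall regions as BED intervals on the CDS
#'
#' Converts codon-indexed regions to 0-based half-open nucleotide
#' coordinates on the coding sequence (`3 * (codon - 1)`).
#'
#' @param regions data.frame from [annotate_cds_set()]/[collapse_windows()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$gene,
                    start = 3L * (regions$region_start - 1L),
                    end = 3L * regions$region_end,
                    name = paste0(regions$gene, "_stall"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
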