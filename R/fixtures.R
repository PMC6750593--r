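## Synthetic-data generators.  Every generator is deterministic under
## (seed, parameters) and returns its ground truth alongside the data, so
## the analysis modules can be tested round-trip without any downloads.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(code)
}

.codons_for <- function(residues) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc %in% residues]
}

#' Synthetic CDS set with implanted stall-encoding windows
#'
#' Generates coding sequences whose background codons are drawn uniformly
#' from the sense codons, rejection-checked so that no accidental window
#' qualifies under any scanning rule, and implants in a random subset of
#' genes one 10-codon window that satisfies its rule with exactly
#' `min_count` matching residues (placed at the first and last window
#' codon, so the implanted offset is the unique qualifying one).
#'
#' @param n_genes number of genes.
#' @param len_range codon-length range (uniform draw per gene, stop codon
#'   appended on top).
#' @param stall_prob probability that a gene receives an implant.
#' @param rules rules to implant, sampled uniformly per stall gene.
#' @param seed integer seed; identical (seed, parameters) give identical
#'   output.
#' @param window,min_count window geometry matching [scan_windows()].
#' @return list `seqs` (named character vector of CDSs) and `truth`
#'   (data.frame `gene`, `stall_start` codon or NA, `rule`).
#' @export
synth_cds_set <- function(n_genes = 10L, len_range = c(120L, 400L),
                          stall_prob = 0.5, rules = c("kr", "p"),
                          seed = 1L, window = 10L, min_count = 6L) {
  stopifnot(stall_prob >= 0, stall_prob <= 1,
            len_range[1] >= window + 2L)
  sense <- .codons_for(setdiff(unique(Biostrings::GENETIC_CODE), "*"))
  neutral <- .codons_for(setdiff(unique(Biostrings::GENETIC_CODE),
                                 c("K", "R", "P", "E", "D", "*")))
  all_rules <- c("kr", "p", "ed")
  .with_seed(seed, {
    genes <- sprintf("gene%03d", seq_len(n_genes))
    truth <- data.frame(gene = genes, stall_start = NA_integer_,
                        rule = NA_character_)
    seqs <- character(n_genes)
    for (i in seq_len(n_genes)) {
      len <- sample(len_range[1]:len_range[2], 1L)
      codons <- sample(sense, len, replace = TRUE)
      implant <- stats::runif(1) < stall_prob
      pos <- NA_integer_
      rule <- NA_character_
      if (implant) {
        rule <- sample(rules, 1L)
        pos <- sample(seq(2L, len - window), 1L)
        slots <- c(1L, window,
                   sample(setdiff(seq_len(window), c(1L, window)),
                          min_count - 2L))
        w <- sample(neutral, window, replace = TRUE)
        w[slots] <- sample(.codons_for(.rule_residues[[rule]]),
                           min_count, replace = TRUE)
        codons[pos:(pos + window - 1L)] <- w
      }
      ## rejection check: rewrite any accidental qualifying window
      repeat {
        seq <- paste(codons, collapse = "")
        acc <- do.call(rbind, lapply(all_rules, function(r)
          scan_windows(seq, r, gene = genes[i],
                       window = window, min_count = min_count)))
        if (!is.na(pos)) acc <- acc[!(acc$start == pos & acc$rule == rule), ,
                                    drop = FALSE]
        if (nrow(acc) == 0) break
        bad <- acc$start[1]
        redraw <- setdiff(bad:(bad + window - 1L),
                          if (is.na(pos)) integer() else
                            pos:(pos + window - 1L))
        codons[redraw] <- sample(neutral, length(redraw), replace = TRUE)
      }
      seqs[i] <- paste0(seq, "TAA")
      truth$stall_start[i] <- pos
      truth$rule[i] <- rule
    }
    list(seqs = stats::setNames(seqs, genes), truth = truth)
  })
}

#' Synthetic rpkm tables with a known group TE offset
#'
#' Emulates a two-group translation-efficiency comparison: mRNA rpkm is
#' log-normal, log2 TE is normal with the no-stall group centred at 0 and
#' the stall group shifted down by `offset_log2`, and footprint rpkm is
#' their product.
#'
#' @param n_stall,n_control genes per group.
#' @param offset_log2 true difference of group mean log2 TE (no-stall
#'   minus stall).
#' @param sd_log2 within-group SD of log2 TE.
#' @param mean_log2_rpkm,sd_log2_rpkm location/scale of mRNA rpkm (log2).
#' @param seed integer seed.
#' @return list `ribo`, `rna` (data.frames `gene`, `rpkm`), `groups`
#'   (data.frame `gene`, `stall`), `truth` (the generator parameters).
#' @export
synth_te_tables <- function(n_stall = 1000L, n_control = 3500L,
                            offset_log2 = 0.23, sd_log2 = 0.5,
                            mean_log2_rpkm = 6, sd_log2_rpkm = 1.5,
                            seed = 1L) {
  stopifnot(n_stall >= 2, n_control >= 2)
  .with_seed(seed, {
    n <- n_stall + n_control
    genes <- sprintf("g%05d", seq_len(n))
    stall <- c(rep(TRUE, n_stall), rep(FALSE, n_control))
    rna <- 2^stats::rnorm(n, mean_log2_rpkm, sd_log2_rpkm)
    lte <- stats::rnorm(n, ifelse(stall, -offset_log2, 0), sd_log2)
    list(ribo = data.frame(gene = genes, rpkm = rna * 2^lte),
         rna = data.frame(gene = genes, rpkm = rna),
         groups = data.frame(gene = genes, stall = stall),
         truth = list(offset_log2 = offset_log2, sd_log2 = sd_log2,
                      n_stall = n_stall, n_control = n_control,
                      seed = seed))
  })
}

#' Synthetic coverage tracks with a density bump downstream of a region
#'
#' Generates Poisson coverage with, optionally, a Gaussian-shaped bump of
#' extra density centred `bump_offset` nt after each region start —
#' mimicking the elevated ribosome density a few codons into a stall.
#'
#' @param n_regions number of transcripts (one region each).
#' @param tx_len transcript length, nt.
#' @param start_nt region start (same on every transcript).
#' @param base_mean mean background coverage per nucleotide.
#' @param bump_height peak extra coverage in multiples of `base_mean`
#'   (0 for flat tracks).
#' @param bump_offset bump centre relative to the region start (+1 = first
#'   region nucleotide).
#' @param bump_sd Gaussian width of the bump, nt.
#' @param seed integer seed.
#' @return list `tracks` (named list of coverage vectors) and `regions`
#'   (data.frame `transcript`, `start_nt`).
#' @export
synth_coverage_tracks <- function(n_regions = 50L, tx_len = 600L,
                                  start_nt = 301L, base_mean = 20,
                                  bump_height = 4, bump_offset = 24L,
                                  bump_sd = 6, seed = 1L) {
  .with_seed(seed, {
    ids <- sprintf("tx%03d", seq_len(n_regions))
    pos <- seq_len(tx_len)
    centre <- start_nt + bump_offset - 1L
    shape <- exp(-(pos - centre)^2 / (2 * bump_sd^2))
    lam <- base_mean * (1 + bump_height * shape)
    tracks <- lapply(ids, function(id) stats::rpois(tx_len, lam))
    names(tracks) <- ids
    list(tracks = tracks,
         regions = data.frame(transcript = ids, start_nt = start_nt))
  })
}

#' Synthetic barcoded read sets with known cDNA/gDNA ratios
#'
#' Draws gDNA counts from a uniform multinomial over the design barcodes
#' and cDNA counts from a multinomial whose barcode weights are the gDNA
#' shares scaled by each reporter's true mRNA ratio, then assembles reads
#' with the barcode at a fixed offset padded with random nucleotides.
#'
#' @param design design table (`barcode`, `reporter`, optional `group`).
#' @param ratios named numeric vector of true cDNA/gDNA ratios per
#'   reporter.
#' @param depth expected reads per barcode per assay.
#' @param read_len read length, nt.
#' @param offset 0-based barcode offset within the read.
#' @param seed integer seed.
#' @return list `cdna_reads`, `gdna_reads` (character vectors), `truth`
#'   (design with the true ratio per barcode).
#' @export
synth_barcode_reads <- function(design, ratios, depth = 1e4, read_len = 50L,
                                offset = 0L, seed = 1L) {
  stopifnot(all(design$reporter %in% names(ratios)), all(ratios > 0),
            read_len >= offset + 8L)
  .with_seed(seed, {
    nb <- nrow(design)
    total <- round(depth * nb)
    g_counts <- as.vector(stats::rmultinom(1, total, rep(1, nb)))
    w <- g_counts * ratios[design$reporter]
    c_counts <- as.vector(stats::rmultinom(1, total, w))
    pad <- function(n, k) vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
            collapse = ""), "")
    mk_reads <- function(counts) {
      bc <- rep(design$barcode, counts)
      n <- length(bc)
      left <- if (offset > 0) pad(n, offset) else ""
      right_len <- read_len - offset - 8L
      right <- if (right_len > 0) pad(n, right_len) else ""
      sample(paste0(left, bc, right))  # shuffle read order
    }
    list(cdna_reads = mk_reads(c_counts), gdna_reads = mk_reads(g_counts),
         truth = cbind(design,
                       true_ratio = unname(ratios[design$reporter])))
  })
}
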