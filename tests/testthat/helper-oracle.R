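# Brute-force event-enumeration oracle and random-state generator.
#
# The oracle re-derives the enabled event set equation by equation: for
# every reaction rule it loops over every mRNA, ribosome and site and
# tests the rule's written precondition directly.  It is deliberately
# structured differently from ribocollide::enabled_events() (per-equation
# loops instead of per-molecule enumeration) so the two can check each
# other.

events_oracle <- function(state, params) {
  p <- params
  fp <- p$footprint
  rows <- list()
  add <- function(rule, mrna = NA_integer_, rib_a = NA_integer_,
                  site = NA_integer_, prop) {
    if (prop > 0)
      rows[[length(rows) + 1L]] <<- data.frame(
        rule = rule, mrna = mrna, rib_a = rib_a, site = site,
        propensity = prop)
  }

  ## transcription from the DNA template
  add("TRANSCRIBE", prop = p$k_transcription)

  for (m in state$mrnas) {
    rib <- m$ribosomes
    bonded <- function(i) any(rib$a == i)
    rib_at <- function(i) which(rib$a == i)

    ## initiation: capped, start clear, start codon unbonded, r1 intact
    if (m$cap && !m$start_blocked && !bonded(1) &&
        m$backbone[1] == "intact")
      add("INITIATE", m$id, prop = p$k_init)

    ## elongation: entry-site free, target codon unbonded, source backbone
    ## intact (the trailing-bond variant fires at the same rate)
    for (k in seq_len(nrow(rib))) {
      a <- rib$a[k]
      if (a < p$L_m && !rib$hit_front[k] && m$backbone[a] == "intact" &&
          (a + fp > p$L_m || !bonded(a + fp)))
        add("ELONGATE", m$id, rib_a = a, prop = p$elongation_rates[a])
    }

    ## termination at the final codon (with or without a trailing bond)
    for (k in rib_at(p$L_m))
      add("TERMINATE", m$id, rib_a = p$L_m, prop = p$k_term)

    ## collision: a pair at exactly footprint distance, both bond sites
    ## free; propensity is the elongation rate at the trailing A site
    for (k in seq_len(nrow(rib))) {
      lead <- rib_at(rib$a[k] + fp)
      if (length(lead) == 1L && !rib$hit_front[k] && !rib$hit_back[lead])
        add("COLLIDE", m$id, rib_a = rib$a[k],
            prop = p$elongation_rates[rib$a[k]])
    }

    ## deadenylation 3'->5': residue j removable once j+1 is gone; the
    ## terminal residue starts the process
    for (j in seq_len(p$L_p))
      if (m$polyA[j] == "intact" &&
          (j == p$L_p || m$polyA[j + 1] == "exocleaved"))
        add("DEADENYLATE", m$id, site = j, prop = p$k_deadenylation)

    ## decapping after complete deadenylation
    if (m$cap && p$L_p > 0 && m$polyA[1] == "exocleaved")
      add("DECAP", m$id, prop = p$k_decapping)

    ## 5'-3' exonucleolysis: upstream backbone gone (or position 1 on a
    ## decapped mRNA), site intact, codon unbonded
    for (i in seq_len(p$L_m)) {
      open5 <- if (i == 1L) !m$cap else m$backbone[i - 1] == "exocleaved"
      if (open5 && m$backbone[i] == "intact" && !bonded(i))
        add("EXO53", m$id, site = i, prop = p$k_exo_53)
    }

    ## 3'-5' exonucleolysis: downstream backbone gone (or the final codon
    ## after complete deadenylation), site intact, codon unbonded
    for (i in seq_len(p$L_m)) {
      open3 <- if (i == p$L_m) p$L_p > 0 && m$polyA[1] == "exocleaved"
               else m$backbone[i + 1] == "exocleaved"
      if (open3 && m$backbone[i] == "intact" && !bonded(i))
        add("EXO35", m$id, site = i, prop = p$k_exo_35)
    }

    ## abortive termination by collision status (intact A-site backbone),
    ## and the uniform-rate variant from endonucleolytically cut A sites
    for (k in seq_len(nrow(rib))) {
      a <- rib$a[k]
      hb <- rib$hit_back[k]; hf <- rib$hit_front[k]
      if (m$backbone[a] == "intact") {
        if (!hb && !hf) add("ABORT_NO_HIT", m$id, rib_a = a,
                            prop = p$k_abort_no_hit)
        if (hb && !hf) add("ABORT_BACK_HIT", m$id, rib_a = a,
                           prop = p$k_abort_back_hit)
        if (!hb && hf) add("ABORT_FRONT_HIT", m$id, rib_a = a,
                           prop = p$k_abort_front_hit)
        if (hb && hf) add("ABORT_BOTH_HIT", m$id, rib_a = a,
                          prop = p$k_abort_both_hit)
      } else if (m$backbone[a] == "endocleaved") {
        add("ABORT_TRUNCATED", m$id, rib_a = a, prop = p$k_abort_truncated)
      }
    }

    ## endonucleolytic cleavage L_c codons 5' of the A site, on capped
    ## mRNAs, by collision status
    for (k in seq_len(nrow(rib))) {
      a <- rib$a[k]
      hb <- rib$hit_back[k]; hf <- rib$hit_front[k]
      if (m$cap && a > p$L_c && m$backbone[a - p$L_c] == "intact") {
        if (!hb && !hf) add("CLEAVE_NO_HIT", m$id, rib_a = a,
                            prop = p$k_cleave_no_hit)
        if (hb && !hf) add("CLEAVE_BACK_HIT", m$id, rib_a = a,
                           prop = p$k_cleave_back_hit)
        if (!hb && hf) add("CLEAVE_FRONT_HIT", m$id, rib_a = a,
                           prop = p$k_cleave_front_hit)
        if (hb && hf) add("CLEAVE_BOTH_HIT", m$id, rib_a = a,
                          prop = p$k_cleave_both_hit)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(rule = character(), mrna = integer(),
                      rib_a = integer(), site = integer(),
                      propensity = numeric())
  out
}

# Canonicalize an event table for set comparison.
sort_events <- function(ev) {
  ev <- ev[order(ev$rule, ev$mrna, ev$rib_a, ev$site), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Random internally consistent system state on a small lattice.
random_state <- function(params, n_mrna = 2L) {
  p <- params
  st <- list(time = 0, next_id = n_mrna + 1L, mrnas = list(),
             counters = c(initiations = 0, full = 0, aborted = 0,
                          transcribed = n_mrna))
  for (id in seq_len(n_mrna)) {
    m <- new_mrna(p, 0, id)
    ## ribosomes: random positions with footprint exclusion
    pos <- integer()
    cand <- 1L
    while (cand <= p$L_m) {
      if (stats::runif(1) < 0.35) pos <- c(pos, cand)
      cand <- cand + if (length(pos) && cand == pos[length(pos)])
        p$footprint + sample(0:4, 1L) else sample(1:6, 1L)
    }
    pos <- pos[pos <= p$L_m]
    rib <- data.frame(a = pos, hit_back = logical(length(pos)),
                      hit_front = logical(length(pos)))
    ## bond a random subset of exact-footprint pairs
    if (nrow(rib) >= 2) for (k in seq_len(nrow(rib) - 1L))
      if (rib$a[k + 1] - rib$a[k] == p$footprint && stats::runif(1) < 0.5) {
        rib$hit_front[k] <- TRUE
        rib$hit_back[k + 1] <- TRUE
      }
    m$ribosomes <- rib
    m$start_blocked <- any(rib$a <= 9L)
    ## poly(A): random exocleaved suffix
    ndead <- sample(0:p$L_p, 1L)
    if (ndead > 0) m$polyA[(p$L_p - ndead + 1L):p$L_p] <- "exocleaved"
    ## one endonucleolytic cut (possibly at a ribosome A site) -> cap lost
    if (stats::runif(1) < 0.4) {
      cut <- if (nrow(rib) && stats::runif(1) < 0.5)
        sample(rib$a, 1L) else sample(seq_len(p$L_m), 1L)
      m$backbone[cut] <- "endocleaved"
      m$cap <- FALSE
    }
    ## decapped mRNAs may have a 5' exocleaved prefix up to the first
    ## bonded codon or cut site
    if (!m$cap && stats::runif(1) < 0.6) {
      stopat <- min(c(which(m$backbone != "intact"), rib$a, p$L_m + 1L))
      nexo <- sample(0:(stopat - 1L), 1L)
      if (nexo > 0) m$backbone[seq_len(nexo)] <- "exocleaved"
    }
    st$mrnas[[id]] <- m
  }
  st
}
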