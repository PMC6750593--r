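## R-level representation of the rule-defined CTMC.
##
## This layer is the readable reference for the reaction rules: states are
## explicit (full backbone / poly(A) site vectors, a ribosome table per
## mRNA), and `enabled_events()` / `apply_event()` are pure functions on
## them.  The compiled engine in src/ implements the same rules with a
## compressed state for production runs; the test suite cross-checks the
## two on small systems.

RULE_IDS <- c("TRANSCRIBE", "INITIATE", "ELONGATE", "TERMINATE", "COLLIDE",
              "DEADENYLATE", "DECAP", "EXO53", "EXO35",
              "ABORT_NO_HIT", "ABORT_BACK_HIT", "ABORT_FRONT_HIT",
              "ABORT_BOTH_HIT", "ABORT_TRUNCATED",
              "CLEAVE_NO_HIT", "CLEAVE_BACK_HIT", "CLEAVE_FRONT_HIT",
              "CLEAVE_BOTH_HIT")

#' Create a fresh, fully intact capped mRNA
#'
#' @param params a `"model_params"` list.
#' @param time birth time, s.
#' @param id integer mRNA id.
#' @return an mRNA state list: cap flag, start-region flag, backbone state
#'   vector (`"intact"`/`"endocleaved"`/`"exocleaved"`), poly(A) state
#'   vector (`"intact"`/`"exocleaved"`), a ribosome table with columns
#'   `a` (A-site codon), `hit_back`, `hit_front`, and birth/death times.
#' @export
new_mrna <- function(params, time = 0, id = 1L) {
  list(id = as.integer(id), birth = time, death = NA_real_,
       cap = TRUE, start_blocked = FALSE,
       backbone = rep("intact", params$L_m),
       polyA = rep("intact", params$L_p),
       ribosomes = data.frame(a = integer(), hit_back = logical(),
                              hit_front = logical()))
}

#' Create an initial system state
#'
#' One DNA template is always present.  When transcription is switched off
#' (`k_transcription = 0`) the state starts with a single fresh mRNA that
#' is then tracked for the whole simulation; otherwise it starts empty and
#' mRNAs are produced by transcription.
#'
#' @param params a `"model_params"` list.
#' @return a system state list (`time`, `mrnas`, event counters).
#' @export
new_system_state <- function(params) {
  st <- list(time = 0, next_id = 1L, mrnas = list(),
             counters = c(initiations = 0, full = 0, aborted = 0,
                          transcribed = 0))
  if (params$k_transcription == 0) {
    st$mrnas[[1]] <- new_mrna(params, 0, 1L)
    st$next_id <- 2L
    st$counters["transcribed"] <- 1
  }
  st
}

.collision_combo <- function(hit_back, hit_front) {
  ifelse(hit_back & hit_front, "BOTH",
         ifelse(hit_back, "BACK", ifelse(hit_front, "FRONT", "NO")))
}

.mk_events <- function(rule, mrna, rib_a, site, propensity) {
  data.frame(rule = rule, mrna = mrna, rib_a = rib_a, site = site,
             propensity = propensity)
}

#' Enumerate all enabled reaction events in a state
#'
#' Applies the preconditions of every reaction rule (transcription,
#' initiation, elongation, termination, collision, deadenylation,
#' decapping, 5'-3' and 3'-5' exonucleolysis, the four collision-status
#' abort rules, abort from a truncated A site, and the four
#' collision-status cleavage rules) to every molecule and site, and
#' returns the enabled events with their propensities.  Only events with
#' strictly positive propensity are returned; enumeration is a pure
#' function of the state.
#'
#' @param state a system state from [new_system_state()] / [apply_event()].
#' @param params a `"model_params"` list.
#' @return data.frame with columns `rule`, `mrna` (id), `rib_a` (A-site
#'   codon of the ribosome the rule acts on, or NA), `site` (backbone or
#'   poly(A) position, or NA) and `propensity` (1/s).
#' @export
enabled_events <- function(state, params) {
  p <- params
  fp <- p$footprint
  out <- list(.mk_events(character(), integer(), integer(), integer(),
                         numeric()))
  add <- function(rule, mrna, rib_a = NA_integer_, site = NA_integer_,
                  prop) {
    if (length(prop) && any(prop > 0)) {
      keep <- prop > 0
      out[[length(out) + 1L]] <<-
        .mk_events(rule[keep], mrna, rib_a[keep], site[keep], prop[keep])
    }
  }

  ## transcription from the single DNA template
  add("TRANSCRIBE", NA_integer_, prop = p$k_transcription)

  for (m in state$mrnas) {
    rb <- m$ribosomes
    rb <- rb[order(rb$a), , drop = FALSE]
    n <- nrow(rb)
    bonded <- rb$a

    ## initiation: capped, start clear, codon 1 unbonded, r1 intact
    if (m$cap && !m$start_blocked && !(1L %in% bonded) &&
        m$backbone[1] == "intact")
      add("INITIATE", m$id, prop = p$k_init)

    ## deadenylation: 3'->5', position j needs p_{j+1} removed (or j = L_p)
    if (p$L_p > 0) {
      j <- seq_len(p$L_p)
      ok <- m$polyA == "intact" &
        (j == p$L_p | c(m$polyA[-1], "exocleaved") == "exocleaved")
      for (jj in which(ok))
        add("DEADENYLATE", m$id, site = jj, prop = p$k_deadenylation)
    }

    ## decapping: after complete deadenylation
    if (m$cap && (p$L_p == 0 || m$polyA[1] == "exocleaved"))
      add("DECAP", m$id, prop = p$k_decapping)

    ## 5'-3' exonucleolysis: r_{i-1} removed (or i = 1 with cap absent),
    ## r_i intact, codon i unbonded
    i <- seq_len(p$L_m)
    prev_exo <- c(NA, m$backbone[-p$L_m] == "exocleaved")
    ok53 <- m$backbone == "intact" & !(i %in% bonded) &
      ifelse(i == 1L, !m$cap, prev_exo)
    for (ii in which(ok53)) add("EXO53", m$id, site = ii, prop = p$k_exo_53)

    ## 3'-5' exonucleolysis: r_{i+1} removed (or i = L_m after complete
    ## deadenylation), r_i intact, codon i unbonded
    next_exo <- c(m$backbone[-1] == "exocleaved", NA)
    ok35 <- m$backbone == "intact" & !(i %in% bonded) &
      ifelse(i == p$L_m, p$L_p == 0 || m$polyA[1] == "exocleaved", next_exo)
    for (ii in which(ok35)) add("EXO35", m$id, site = ii, prop = p$k_exo_35)

    if (n > 0) {
      lead_a <- c(rb$a[-1], NA)  # A site of the next ribosome 3'-ward
      for (k in seq_len(n)) {
        a <- rb$a[k]
        combo <- .collision_combo(rb$hit_back[k], rb$hit_front[k])
        src_intact <- m$backbone[a] == "intact"
        gap <- if (is.na(lead_a[k])) Inf else lead_a[k] - a

        if (a == p$L_m) {
          add("TERMINATE", m$id, rib_a = a, prop = p$k_term)
        } else if (src_intact && gap > fp) {
          add("ELONGATE", m$id, rib_a = a, prop = p$elongation_rates[a])
        } else if (gap == fp && !rb$hit_front[k]) {
          add("COLLIDE", m$id, rib_a = a, prop = p$elongation_rates[a])
        }

        if (src_intact) {
          add(paste0("ABORT_", combo, "_HIT"), m$id, rib_a = a,
              prop = p[[paste0("k_abort_", tolower(combo), "_hit")]])
        } else if (m$backbone[a] == "endocleaved") {
          add("ABORT_TRUNCATED", m$id, rib_a = a, prop = p$k_abort_truncated)
        }

        if (m$cap && a > p$L_c && m$backbone[a - p$L_c] == "intact") {
          add(paste0("CLEAVE_", combo, "_HIT"), m$id, rib_a = a,
              prop = p[[paste0("k_cleave_", tolower(combo), "_hit")]])
        }
      }
    }
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev
}

#' Apply one enabled event to a state
#'
#' Executes the state update of a single reaction rule: ribosome moves
#' (clearing the start region when a ribosome elongates away from the
#' ninth codon, and dissolving the collision bond with a trailing
#' ribosome), collisions (bond formation between the trailing ribosome's
#' entry site and the leading ribosome's exit site), normal and abortive
#' termination (ribosome removal, protein counting, bond dissolution),
#' decay chemistry (deadenylation, decapping, exonucleolysis; the first
#' 5'-3' exonucleolysis event records the mRNA death time), and
#' endonucleolytic cleavage (backbone cut `L_c` codons 5' of the A site,
#' immediate decapping, and dissolution of the collision bond named by the
#' rule variant).  When a ribosome whose A site is still within the first
#' nine codons is removed, the start region is cleared again so the mRNA
#' remains initiable.
#'
#' @param state a system state.
#' @param event one row of the data.frame from [enabled_events()] (or an
#'   equivalent list with `rule`, `mrna`, `rib_a`, `site`).
#' @param params a `"model_params"` list.
#' @param time event time, s (used for mRNA birth/death bookkeeping).
#' @return the updated state.
#' @export
apply_event <- function(state, event, params, time = state$time) {
  rule <- as.character(event$rule)
  state$time <- time
  p <- params

  if (rule == "TRANSCRIBE") {
    id <- state$next_id
    state$mrnas[[length(state$mrnas) + 1L]] <- new_mrna(p, time, id)
    state$next_id <- id + 1L
    state$counters["transcribed"] <- state$counters["transcribed"] + 1
    return(state)
  }

  mi <- which(vapply(state$mrnas, function(m) m$id, 1L) == event$mrna)
  if (length(mi) != 1L) stop("stale event: mRNA ", event$mrna, " not found")
  m <- state$mrnas[[mi]]
  rb <- m$ribosomes[order(m$ribosomes$a), , drop = FALSE]
  k <- if (!is.na(event$rib_a)) which(rb$a == event$rib_a) else integer()

  clear_bonds <- function(rb, k, back = TRUE, front = TRUE) {
    if (back && rb$hit_back[k]) {
      rb$hit_back[k] <- FALSE
      rb$hit_front[which(rb$a == rb$a[k] - p$footprint)] <- FALSE
    }
    if (front && rb$hit_front[k]) {
      rb$hit_front[k] <- FALSE
      rb$hit_back[which(rb$a == rb$a[k] + p$footprint)] <- FALSE
    }
    rb
  }
  remove_rib <- function(rb, k) {
    rb <- clear_bonds(rb, k)
    a <- rb$a[k]
    rb <- rb[-k, , drop = FALSE]
    if (a <= 9L) m$start_blocked <<- FALSE
    rb
  }

  switch(rule,
    INITIATE = {
      rb <- rbind(data.frame(a = 1L, hit_back = FALSE, hit_front = FALSE), rb)
      m$start_blocked <- TRUE
      state$counters["initiations"] <- state$counters["initiations"] + 1
    },
    ELONGATE = {
      rb <- clear_bonds(rb, k, front = FALSE)
      if (rb$a[k] == 9L) m$start_blocked <- FALSE
      rb$a[k] <- rb$a[k] + 1L
    },
    TERMINATE = {
      rb <- remove_rib(rb, k)
      state$counters["full"] <- state$counters["full"] + 1
    },
    COLLIDE = {
      rb$hit_front[k] <- TRUE
      rb$hit_back[which(rb$a == rb$a[k] + p$footprint)] <- TRUE
    },
    DEADENYLATE = m$polyA[event$site] <- "exocleaved",
    DECAP = m$cap <- FALSE,
    EXO53 = {
      m$backbone[event$site] <- "exocleaved"
      if (event$site == 1L && is.na(m$death)) m$death <- time
    },
    EXO35 = m$backbone[event$site] <- "exocleaved",
    ABORT_NO_HIT = ,
    ABORT_BACK_HIT = ,
    ABORT_FRONT_HIT = ,
    ABORT_BOTH_HIT = ,
    ABORT_TRUNCATED = {
      rb <- remove_rib(rb, k)
      state$counters["aborted"] <- state$counters["aborted"] + 1
    },
    CLEAVE_NO_HIT = ,
    CLEAVE_BACK_HIT = ,
    CLEAVE_FRONT_HIT = ,
    CLEAVE_BOTH_HIT = {
      m$backbone[rb$a[k] - p$L_c] <- "endocleaved"
      m$cap <- FALSE
      ## the cleavage rule dissolves the collision bond it was conditioned
      ## on: the front bond for a front-hit ribosome, the back bond for a
      ## back-hit or doubly hit ribosome
      if (rule == "CLEAVE_FRONT_HIT")
        rb <- clear_bonds(rb, k, back = FALSE)
      else if (rule %in% c("CLEAVE_BACK_HIT", "CLEAVE_BOTH_HIT"))
        rb <- clear_bonds(rb, k, front = FALSE)
    },
    stop("unknown rule: ", rule)
  )
  m$ribosomes <- rb
  state$mrnas[[mi]] <- m
  state
}

#' Reference stochastic simulation in pure R
#'
#' A direct-method Gillespie sampler driven entirely by
#' [enabled_events()] and [apply_event()].  It is orders of magnitude
#' slower than [simulate_qc()] and is intended for validating the compiled
#' engine on small systems, not for production sweeps.
#'
#' @param params a `"model_params"` list.
#' @param duration biological time to simulate, s.
#' @param seed integer seed.
#' @param max_events hard cap on the number of events.
#' @return a list with the final `state`, the elapsed `time`, and the event
#'   counters.
#' @export
simulate_qc_reference <- function(params, duration, seed = 1L,
                                  max_events = 1e6) {
  set.seed(seed)
  state <- new_system_state(params)
  n <- 0
  repeat {
    ev <- enabled_events(state, params)
    tot <- sum(ev$propensity)
    if (tot <= 0) break
    dt <- stats::rexp(1, tot)
    if (state$time + dt > duration) { state$time <- duration; break }
    pick <- if (nrow(ev) == 1L) 1L else
      sample.int(nrow(ev), 1L, prob = ev$propensity)
    state <- apply_event(state, ev[pick, ], params, state$time + dt)
    n <- n + 1
    if (n >= max_events) break
  }
  bound <- sum(vapply(state$mrnas, function(m) nrow(m$ribosomes), 1L))
  list(state = state, time = state$time, counters = state$counters,
       n_events = n, n_bound = bound)
}
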