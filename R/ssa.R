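#' Run one exact stochastic simulation of the quality-control model
#'
#' Direct-method Gillespie simulation of the full rule set: translation
#' (initiation, elongation with 10-codon steric exclusion, termination),
#' ribosome collisions at exact footprint distance, collision-status
#' dependent abortive termination and endonucleolytic cleavage, abort from
#' truncated (cleaved) A sites, and canonical decay (3'-5' deadenylation,
#' decapping, 5'-3' exonucleolysis).  When `k_transcription` is zero the
#' simulation tracks a single mRNA present from time 0 (the no-decay sweep
#' mode); otherwise it starts with one DNA template and an empty mRNA pool.
#'
#' An mRNA's death time is the time of its first 5'-3' exonucleolysis
#' event; mRNAs still alive (death unrecorded) when the simulation ends are
#' censored.
#'
#' @param params a `"model_params"` list from [make_params()].
#' @param duration biological time to simulate, s.
#' @param seed integer seed; identical `(params, duration, seed)` give an
#'   identical trajectory.
#' @param track_events if `TRUE`, record the full event log (time, rule,
#'   mRNA, site).  Only sensible for small runs.
#' @param max_events hard cap on the number of reaction events; hitting it
#'   truncates the run and is flagged in the returned object.
#' @return a `"qc_trajectory"` list: parameter snapshot, seed,
#'   `simulated_duration`, counters (`n_initiations`, `n_full_proteins`,
#'   `n_aborted`, `n_transcribed`, `n_bound_end`), per-mRNA `mrna_births` /
#'   `mrna_deaths` (NA = censored), flags, and optionally `events`.
#' @examples
#' p <- make_params("tj", n_stall = 0, k_transcription = 0,
#'                  k_deadenylation = 0, k_init = 0.01)
#' tr <- simulate_qc(p, duration = 1e4, seed = 1)
#' protein_synthesis_rate(tr)  # close to k_init: initiation-limited
#' @export
simulate_qc <- function(params, duration, seed = 1L, track_events = FALSE,
                        max_events = 5e8) {
  validate_params(params)
  stopifnot(duration > 0)
  set.seed(as.integer(seed))
  res <- .ssa_run_cpp(params, duration, params$k_transcription == 0,
                      track_events, max_events)
  traj <- list(
    params = params, seed = as.integer(seed),
    simulated_duration = res$t_end,
    n_events = res$n_events,
    n_initiations = res$n_initiations,
    n_full_proteins = res$n_full,
    n_aborted = res$n_aborted,
    n_transcribed = res$n_transcribed,
    n_bound_end = res$n_bound_end,
    mrna_births = res$mrna_births,
    mrna_deaths = res$mrna_deaths,
    hit_event_cap = res$hit_event_cap,
    exhausted = res$exhausted,
    events = if (track_events) {
      ev <- res$events
      ev$rule <- c("TRANSCRIBE", "INITIATE", "ELONGATE", "TERMINATE",
                   "COLLIDE", "DEADENYLATE", "DECAP", "EXO53",
                   "ABORT_NO_HIT", "ABORT_BACK_HIT", "ABORT_FRONT_HIT",
                   "ABORT_BOTH_HIT", "ABORT_TRUNCATED",
                   "CLEAVE_NO_HIT", "CLEAVE_BACK_HIT", "CLEAVE_FRONT_HIT",
                   "CLEAVE_BOTH_HIT")[ev$rule]
      ev
    } else NULL
  )
  if (traj$hit_event_cap)
    warning("event cap (", format(max_events), ") reached at t = ",
            signif(res$t_end, 6), " s; trajectory truncated")
  structure(traj, class = "qc_trajectory")
}

#' @export
print.qc_trajectory <- function(x, ...) {
  cat("Stochastic quality-control trajectory\n")
  cat(sprintf("  presets %s/%s, k_init = %.3g/s, seed %d\n",
              x$params$abort_model, x$params$cleave_model,
              x$params$k_init, x$seed))
  cat(sprintf("  simulated %.4g s (%g events)\n",
              x$simulated_duration, x$n_events))
  cat(sprintf("  proteins: %g full, %g aborted (of %g initiations; %g still bound)\n",
              x$n_full_proteins, x$n_aborted, x$n_initiations, x$n_bound_end))
  nd <- sum(!is.na(x$mrna_deaths))
  cat(sprintf("  mRNAs: %g transcribed, %d dead, %d censored\n",
              x$n_transcribed, nd, length(x$mrna_deaths) - nd))
  invisible(x)
}

#' Replicate simulations with deterministic seed derivation
#'
#' Runs `n_reps` independent trajectories with seeds
#' `base_seed + 0, 1, ..., n_reps - 1` and summarizes the observables
#' (protein synthesis rate, mean mRNA lifetime over dead mRNAs, protein /
#' abort / mRNA counts) as a mean and standard error across replicates.
#'
#' @param params a `"model_params"` list.
#' @param duration biological time per replicate, s.
#' @param n_reps number of replicates (>= 2).
#' @param base_seed integer; replicate `r` uses seed `base_seed + r - 1`.
#' @param max_events passed to [simulate_qc()].
#' @return data.frame with one row per observable (`observable`, `mean`,
#'   `se`, `n_reps`); the per-replicate table is attached as attribute
#'   `"replicates"`.
#' @export
run_replicates <- function(params, duration, n_reps = 4L, base_seed = 1L,
                           max_events = 5e8) {
  stopifnot(n_reps >= 2)
  reps <- lapply(seq_len(n_reps) - 1L, function(k) {
    tr <- simulate_qc(params, duration, seed = base_seed + k,
                      max_events = max_events)
    lt <- tr$mrna_deaths - tr$mrna_births
    data.frame(
      seed = base_seed + k,
      psr = protein_synthesis_rate(tr),
      lifetime = if (any(!is.na(lt))) mean(lt, na.rm = TRUE) else NA_real_,
      n_full = tr$n_full_proteins, n_aborted = tr$n_aborted,
      n_transcribed = tr$n_transcribed,
      n_dead = sum(!is.na(lt)), n_censored = sum(is.na(lt)))
  })
  reps <- do.call(rbind, reps)
  obs <- c("psr", "lifetime", "n_full", "n_aborted", "n_transcribed",
           "n_dead", "n_censored")
  summ <- data.frame(
    observable = obs,
    mean = vapply(obs, function(o) mean(reps[[o]], na.rm = TRUE), 1),
    se = vapply(obs, function(o) {
      v <- reps[[o]][!is.na(reps[[o]])]
      if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, 1),
    n_reps = n_reps, row.names = NULL)
  attr(summ, "replicates") <- reps
  summ
}
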