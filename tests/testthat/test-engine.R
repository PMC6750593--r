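# Engine-level tests: determinism, degenerate inputs, statistical
# exactness against closed forms and exponential sojourn laws, counter
# conservation, and agreement between the compiled engine and the pure-R
# reference sampler.

test_that("identical (params, duration, seed) give identical trajectories", {
  p <- make_params("csat", k_a = 0.5, k_init = 0.1, k_transcription = 0,
                   k_deadenylation = 0)
  a <- simulate_qc(p, 5e3, seed = 11)
  b <- simulate_qc(p, 5e3, seed = 11)
  expect_identical(a$n_events, b$n_events)
  expect_identical(a$n_full_proteins, b$n_full_proteins)
  expect_identical(a$n_aborted, b$n_aborted)
  c <- simulate_qc(p, 5e3, seed = 12)
  expect_false(identical(a$n_events, c$n_events))
})

test_that("no initiation means no proteins of either kind", {
  p <- make_params("csat", k_a = 0.5, k_init = 0)
  tr <- simulate_qc(p, 1e4, seed = 3)
  expect_equal(tr$n_full_proteins, 0)
  expect_equal(tr$n_aborted, 0)
  expect_equal(protein_synthesis_rate(tr), 0)
})

test_that("initiation-limited throughput approaches k_init", {
  ## no stall, no decay, low initiation: every initiation completes and
  ## the protein flux is set by initiation alone
  p <- make_params("tj", n_stall = 0L, k_transcription = 0,
                   k_deadenylation = 0, k_init = 0.01)
  tr <- simulate_qc(p, 1e5, seed = 5)
  psr <- protein_synthesis_rate(tr)
  se <- sqrt(tr$n_full_proteins) / tr$simulated_duration
  expect_lt(abs(psr - 0.01), 3 * se)
})

test_that("canonical decay reproduces the sequential-step mean lifetime", {
  ## deadenylation (Erlang over L_p residues) + decapping + exonucleolysis
  p <- make_params("tj", k_init = 0)
  closed <- p$L_p / p$k_deadenylation + 1 / p$k_decapping + 1 / p$k_exo_53
  tr <- simulate_qc(p, 6e5, seed = 8)
  s <- mrna_lifetime_stats(tr)
  expect_gt(s$n_dead, 400)
  expect_lt(abs(s$mean - closed), 3 * s$sd / sqrt(s$n_dead))

  ## generalization: random decay parameter triples against the same
  ## closed form
  set.seed(19)
  for (k in 1:2) {
    kd <- stats::runif(1, 0.02, 0.08)
    kc <- stats::runif(1, 0.005, 0.05)
    kx <- stats::runif(1, 0.5, 2)
    lp <- sample(20:60, 1)
    pk <- make_params("tj", k_init = 0, k_deadenylation = kd,
                      k_decapping = kc, k_exo_53 = kx, L_p = lp)
    cf <- lp / kd + 1 / kc + 1 / kx
    trk <- simulate_qc(pk, 3e5, seed = 20 + k)
    sk <- mrna_lifetime_stats(trk)
    expect_lt(abs(sk$mean - cf), 3 * sk$sd / sqrt(sk$n_dead))
  }
})

test_that("sojourn times in the single-ribosome toy are exponential", {
  ## 12-codon uniform lattice, decay off.  While a lone ribosome sits at a
  ## codon inside the start footprint, elongation at k_elong is the only
  ## enabled event, so those sojourns are Exp(10); while the mRNA is
  ## empty, initiation is the only enabled event, so the waits are
  ## Exp(k_init).  Occupancy is reconstructed from the event log.
  p <- make_params("tj", L_m = 12L, n_stall = 0L, k_transcription = 0,
                   k_deadenylation = 0, k_init = 0.2)
  tr <- simulate_qc(p, 8e4, seed = 31, track_events = TRUE)
  ev <- tr$events
  delta <- (ev$rule == "INITIATE") - (ev$rule == "TERMINATE")
  count <- cumsum(delta)

  ## sojourns at codons 1..8 of transits that start on an empty mRNA
  solo_init <- which(ev$rule == "INITIATE" & count == 1L)
  gaps <- unlist(lapply(solo_init, function(i) {
    idx <- i + 0:8
    if (max(idx) > nrow(ev)) return(NULL)
    if (!all(ev$rule[idx[-1]] == "ELONGATE")) return(NULL)
    diff(ev$time[idx])
  }))
  expect_gt(length(gaps), 5e3)
  expect_gt(suppressWarnings(stats::ks.test(gaps, "pexp", rate = 10))$p.value, 0.01)

  ## empty-mRNA waits: termination that empties the lattice -> initiation
  empty_at <- which(ev$rule == "TERMINATE" & count == 0L)
  waits <- unlist(lapply(empty_at, function(i) {
    if (i + 1L > nrow(ev)) return(NULL)
    ev$time[i + 1L] - ev$time[i]
  }))
  expect_gt(length(waits), 500)
  expect_gt(suppressWarnings(stats::ks.test(waits, "pexp", rate = 0.2))$p.value, 0.01)
})

test_that("inter-protein times under low-initiation traffic are Exp(k_init)", {
  p <- make_params("tj", n_stall = 0L, k_transcription = 0,
                   k_deadenylation = 0, k_init = 0.01)
  tr <- simulate_qc(p, 2e5, seed = 37, track_events = TRUE)
  tt <- tr$events$time[tr$events$rule == "TERMINATE"]
  expect_gt(length(tt), 1e3)
  expect_gt(suppressWarnings(stats::ks.test(diff(tt), "pexp", rate = 0.01))$p.value, 0.01)
})

test_that("protein and mRNA bookkeeping balances exactly", {
  cfgs <- list(
    make_params(model_preset("csat", "csec"), k_a = 0.5, k_cleave = 0.005,
                k_init = 0.3),
    make_params(model_preset("sat", "sec"), k_a = 0.02, k_cleave = 0.002,
                k_init = 0.1),
    make_params("cat", k_a = 0.5, k_init = 0.4, k_transcription = 0,
                k_deadenylation = 0))
  for (i in seq_along(cfgs)) {
    tr <- simulate_qc(cfgs[[i]], 2e4, seed = 40 + i, track_events = TRUE)
    expect_equal(tr$n_initiations,
                 tr$n_full_proteins + tr$n_aborted + tr$n_bound_end)
    nd <- sum(!is.na(tr$mrna_deaths))
    expect_equal(tr$n_transcribed, nd + sum(is.na(tr$mrna_deaths)))
    expect_equal(tr$n_transcribed, length(tr$mrna_births))
    ## the event log retells the counters
    expect_equal(sum(tr$events$rule == "INITIATE"), tr$n_initiations)
    expect_equal(sum(tr$events$rule == "TERMINATE"), tr$n_full_proteins)
    expect_equal(sum(grepl("^ABORT", tr$events$rule)), tr$n_aborted)
    expect_equal(sum(tr$events$rule == "TRANSCRIBE") +
                   (cfgs[[i]]$k_transcription == 0), tr$n_transcribed)
    ## death = first 5'-3' exonucleolysis event of the mRNA
    exo1 <- tr$events[tr$events$rule == "EXO53" & tr$events$site == 1, ]
    expect_equal(sort(exo1$time), sort(tr$mrna_deaths[!is.na(tr$mrna_deaths)]))
  }
})

test_that("compiled engine agrees with the pure-R reference sampler", {
  ## small lattice with stalling and aborts, decay off
  p <- make_params("sat", k_a = 0.1, k_init = 0.05, L_m = 30L, L_p = 5L,
                   stall_start = 21L, n_stall = 2L,
                   k_transcription = 0, k_deadenylation = 0)
  cpp <- t(vapply(1:20, function(s) {
    tr <- simulate_qc(p, 400, seed = 100 + s)
    c(tr$n_full_proteins, tr$n_aborted)
  }, c(0, 0)))
  ref <- t(vapply(1:6, function(s) {
    r <- simulate_qc_reference(p, 400, seed = 200 + s)
    unname(r$counters[c("full", "aborted")])
  }, c(0, 0)))
  for (j in 1:2) {
    se <- sqrt(stats::var(cpp[, j]) / nrow(cpp) +
                 stats::var(ref[, j]) / nrow(ref))
    expect_lt(abs(mean(cpp[, j]) - mean(ref[, j])), 3.5 * se)
  }

  ## canonical decay only: lifetimes from both samplers match the
  ## closed form
  pd <- make_params("tj", k_init = 0, L_p = 10L, k_transcription = 0.01)
  cf <- pd$L_p / pd$k_deadenylation + 1 / pd$k_decapping + 1
  rr <- simulate_qc_reference(pd, 8e3, seed = 9)
  lt <- vapply(rr$state$mrnas, function(m) m$death - m$birth, 1)
  lt <- lt[!is.na(lt)]   # censored mRNAs excluded
  expect_gt(length(lt), 20)
  expect_lt(abs(mean(lt) - cf), 3 * stats::sd(lt) / sqrt(length(lt)))
})

test_that("event cap truncates loudly and zero-propensity states end early", {
  p <- make_params("tj", k_init = 0.2, k_transcription = 0,
                   k_deadenylation = 0)
  expect_warning(tr <- simulate_qc(p, 1e5, seed = 2, max_events = 500),
                 "event cap")
  expect_true(tr$hit_event_cap)
  expect_lt(tr$simulated_duration, 1e5)

  ## single mRNA, no initiation, no decay: nothing can ever fire
  p0 <- make_params("tj", k_init = 0, k_transcription = 0,
                    k_deadenylation = 0)
  tr0 <- simulate_qc(p0, 1e4, seed = 2)
  expect_true(tr0$exhausted)
  expect_equal(tr0$n_events, 0)
})
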