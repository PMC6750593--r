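# Rule-level tests: hand-enumerated event sets for canonical states,
# state-update postconditions, and equivalence of the event enumeration
# with the per-equation brute-force oracle on randomized states.

test_that("canonical states enumerate exactly the hand-derived events", {
  p <- make_params("tj")

  ## no mRNA yet: only transcription
  st <- list(time = 0, next_id = 1L, mrnas = list(),
             counters = c(initiations = 0, full = 0, aborted = 0,
                          transcribed = 0))
  ev <- enabled_events(st, p)
  expect_equal(ev$rule, "TRANSCRIBE")
  expect_equal(ev$propensity, 0.001)

  ## one fresh capped mRNA: initiation plus terminal-residue deadenylation
  st <- apply_event(st, ev[1, ], p, time = 5)
  ev <- enabled_events(st, p)
  expect_setequal(ev$rule, c("TRANSCRIBE", "INITIATE", "DEADENYLATE"))
  expect_equal(ev$site[ev$rule == "DEADENYLATE"], p$L_p)
  expect_equal(ev$propensity[ev$rule == "DEADENYLATE"], 0.03)
  expect_equal(ev$propensity[ev$rule == "INITIATE"], p$k_init)

  ## two unbonded ribosomes at exact footprint distance: the trailer can
  ## only collide (at its own codon's elongation rate), the leader can
  ## elongate
  st$mrnas[[1]]$ribosomes <-
    data.frame(a = c(390L, 400L), hit_back = FALSE, hit_front = FALSE)
  ev <- enabled_events(st, p)
  expect_equal(ev$propensity[ev$rule == "COLLIDE"], 10)
  expect_equal(ev$rib_a[ev$rule == "COLLIDE"], 390)
  expect_equal(ev$rib_a[ev$rule == "ELONGATE"], 400)
  expect_false(390 %in% ev$rib_a[ev$rule == "ELONGATE"])
})

test_that("collision, elongation and cleavage update the state as written", {
  p <- make_params(model_preset("csat", "csec"), k_a = 0.5,
                   k_cleave = 0.001)
  st <- new_system_state(make_params("tj", k_transcription = 0))
  st$counters["transcribed"] <- 1
  st$mrnas[[1]]$ribosomes <-
    data.frame(a = c(390L, 400L), hit_back = FALSE, hit_front = FALSE)

  ## collision bonds the pair without moving anyone
  st2 <- apply_event(st, list(rule = "COLLIDE", mrna = 1L, rib_a = 390L,
                              site = NA), p)
  rb <- st2$mrnas[[1]]$ribosomes
  expect_equal(rb$a, c(390L, 400L))
  expect_true(rb$hit_front[1])
  expect_true(rb$hit_back[2])
  expect_false(rb$hit_back[1] || rb$hit_front[2])

  ## elongation of the back-hit leader dissolves the bond on both sides
  st3 <- apply_event(st2, list(rule = "ELONGATE", mrna = 1L, rib_a = 400L,
                               site = NA), p)
  rb <- st3$mrnas[[1]]$ribosomes
  expect_equal(rb$a, c(390L, 401L))
  expect_false(any(rb$hit_back | rb$hit_front))

  ## back-hit cleavage cuts L_c codons 5' of the A site, removes the cap,
  ## and dissolves the back bond (the cut lands on the trailer's A site)
  st4 <- apply_event(st2, list(rule = "CLEAVE_BACK_HIT", mrna = 1L,
                               rib_a = 400L, site = NA), p)
  m <- st4$mrnas[[1]]
  expect_equal(m$backbone[390], "endocleaved")
  expect_false(m$cap)
  expect_false(any(m$ribosomes$hit_back | m$ribosomes$hit_front))
  ## the stranded trailer aborts at the truncated-A-site rate; with the
  ## bond dissolved it may also re-collide (the collision rule carries no
  ## backbone condition), but it can never elongate or abort normally
  ev <- enabled_events(st4, p)
  trail <- ev[!is.na(ev$rib_a) & ev$rib_a == 390, ]
  expect_setequal(trail$rule, c("COLLIDE", "ABORT_TRUNCATED"))
  expect_equal(trail$propensity[trail$rule == "ABORT_TRUNCATED"], 1)
  expect_false("ELONGATE" %in% trail$rule)

  ## abort clears bonds with both neighbours and counts the protein as
  ## aborted
  st5 <- apply_event(st2, list(rule = "ABORT_BACK_HIT", mrna = 1L,
                               rib_a = 400L, site = NA), p)
  expect_equal(nrow(st5$mrnas[[1]]$ribosomes), 1L)
  expect_false(st5$mrnas[[1]]$ribosomes$hit_front)
  expect_equal(unname(st5$counters["aborted"]), 1)
})

test_that("start region stays consistent with early-codon occupancy", {
  p <- make_params("sat", k_a = 0.02, k_transcription = 0,
                   k_deadenylation = 0)
  st <- new_system_state(p)
  ev <- enabled_events(st, p)
  st <- apply_event(st, ev[ev$rule == "INITIATE", ], p)
  expect_true(st$mrnas[[1]]$start_blocked)
  ## no second initiation while a ribosome sits in the start footprint
  expect_false("INITIATE" %in% enabled_events(st, p)$rule)
  ## abort of the early ribosome re-opens the start region
  st2 <- apply_event(st, list(rule = "ABORT_NO_HIT", mrna = 1L,
                              rib_a = 1L, site = NA), p)
  expect_false(st2$mrnas[[1]]$start_blocked)
  expect_true("INITIATE" %in% enabled_events(st2, p)$rule)
  ## elongation past codon 9 also clears it
  for (a in 1:9)
    st <- apply_event(st, list(rule = "ELONGATE", mrna = 1L,
                               rib_a = a, site = NA), p)
  expect_false(st$mrnas[[1]]$start_blocked)
  expect_equal(st$mrnas[[1]]$ribosomes$a, 10L)
})

test_that("event enumeration matches the per-equation oracle on random states", {
  set.seed(404)
  p_base <- make_params(model_preset("csat", "csec"), k_a = 0.5,
                        k_cleave = 0.01, L_m = 30L, L_p = 6L,
                        stall_start = 21L, n_stall = 2L, L_c = 5L)
  presets <- list(p_base,
                  make_params(model_preset("sat", "sec"), k_a = 0.1,
                              k_cleave = 0.02, L_m = 30L, L_p = 6L,
                              stall_start = 21L, n_stall = 2L, L_c = 5L,
                              k_exo_35 = 0.5),
                  make_params(model_preset("cat", "none"), k_a = 0.2,
                              L_m = 25L, L_p = 4L, stall_start = 11L,
                              n_stall = 3L, L_c = 3L))
  for (rep in 1:60) {
    p <- presets[[(rep %% length(presets)) + 1L]]
    st <- random_state(p, n_mrna = 2L)
    got <- sort_events(enabled_events(st, p))
    want <- sort_events(events_oracle(st, p))
    expect_equal(got, want)
    ## enumeration is a pure function of state
    expect_equal(sort_events(enabled_events(st, p)), got)
  }
})

test_that("footprint exclusion survives random applied event sequences", {
  set.seed(77)
  p <- make_params(model_preset("csat", "csec"), k_a = 0.5,
                   k_cleave = 0.01, L_m = 30L, L_p = 4L,
                   stall_start = 21L, n_stall = 2L, L_c = 5L,
                   k_transcription = 0.01)
  for (rep in 1:10) {
    st <- new_system_state(p)
    for (step in 1:150) {
      ev <- enabled_events(st, p)
      if (nrow(ev) == 0) break
      pick <- sample.int(nrow(ev), 1L, prob = ev$propensity)
      st <- apply_event(st, ev[pick, ], p, st$time + 0.01)
      for (m in st$mrnas) {
        a <- sort(m$ribosomes$a)
        if (length(a) >= 2) expect_true(all(diff(a) >= p$footprint))
        ## bond flags only between pairs at exact footprint distance
        for (k in seq_len(nrow(m$ribosomes))) {
          if (m$ribosomes$hit_front[k])
            expect_true((m$ribosomes$a[k] + p$footprint) %in% m$ribosomes$a)
          if (m$ribosomes$hit_back[k])
            expect_true((m$ribosomes$a[k] - p$footprint) %in% m$ribosomes$a)
        }
      }
    }
  }
})
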