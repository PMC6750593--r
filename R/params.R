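#' Per-codon elongation rate profile with a multi-codon stall
#'
#' Builds the vector of per-codon elongation rates for an mRNA of `L_m`
#' codons carrying a stretch of `n_stall` tandem slowly translated codons.
#' Each slow codon is assigned the rate `n_stall * net_rate`, so that the
#' summed mean dwell time across the stall equals `1 / net_rate` regardless
#' of how many codons the stall is split into.  All remaining codons get the
#' background rate `k_default`.
#'
#' @param L_m mRNA coding length in codons.
#' @param stall_start 1-based codon index of the first slow codon.
#' @param n_stall number of tandem slow codons (0 for no stall).
#' @param net_rate net elongation rate across the whole stall, 1/s.
#' @param k_default elongation rate at all non-stall codons, 1/s.
#' @return numeric vector of length `L_m` of per-codon elongation rates (1/s).
#' @examples
#' r <- stall_profile(650, 401, 6, 0.1, 10)
#' r[400:407]  # 10, 0.6 x 6, 10
#' @export
stall_profile <- function(L_m, stall_start = 401L, n_stall = 6L,
                          net_rate = 0.1, k_default = 10) {
  stopifnot(L_m >= 1, n_stall >= 0, net_rate >= 0, k_default >= 0)
  rates <- rep(k_default, L_m)
  if (n_stall > 0) {
    if (stall_start < 1 || stall_start + n_stall - 1 > L_m)
      stop("stall window [", stall_start, ", ", stall_start + n_stall - 1,
           "] lies outside the coding region [1, ", L_m, "]")
    rates[stall_start:(stall_start + n_stall - 1)] <- n_stall * net_rate
  }
  rates
}

#' Model preset for abortive termination and endonucleolytic cleavage
#'
#' The quality-control reaction rules distinguish ribosomes by their
#' collision state: not collided ("no hit"), collided from behind by a
#' trailing ribosome ("back hit", the leading partner of a collision),
#' collided in front with a leading ribosome ("front hit", the trailing
#' partner), or both.  A preset selects which of the four abort rates and
#' which of the four cleavage rates are nonzero:
#'
#' * `"tj"`  traffic jam: no abortive termination at all.
#' * `"sat"` simple abortive termination: no-hit and back-hit ribosomes
#'   abort at `k_a` (collisions confer no extra risk).
#' * `"cat"` collide-and-abort: only the trailing partner of a collision
#'   (front-hit or both-hit) aborts.
#' * `"csat"` collision-stimulated abortive termination: only the leading
#'   partner of a collision (back-hit or both-hit) aborts.
#'
#' and for cleavage:
#'
#' * `"none"` no endonucleolytic cleavage.
#' * `"sec"`  simple endonucleolytic cleavage: no-hit and back-hit
#'   ribosomes trigger cleavage at `k_cleave`.
#' * `"csec"` collision-stimulated cleavage: only back-hit and both-hit
#'   ribosomes trigger cleavage.
#'
#' @param abort one of `"tj"`, `"sat"`, `"cat"`, `"csat"`.
#' @param cleave one of `"none"`, `"sec"`, `"csec"`.
#' @return a `"model_preset"` list with elements `abort` and `cleave`.
#' @export
model_preset <- function(abort = c("tj", "sat", "cat", "csat"),
                         cleave = c("none", "sec", "csec")) {
  abort <- match.arg(tolower(abort[1]), c("tj", "sat", "cat", "csat"))
  cleave <- match.arg(tolower(cleave[1]), c("none", "sec", "csec"))
  structure(list(abort = abort, cleave = cleave), class = "model_preset")
}

.abort_rates <- function(abort, k_a) {
  r <- c(no = 0, back = 0, front = 0, both = 0)
  switch(abort,
    tj   = r,
    sat  = { r[c("no", "back")] <- k_a; r },
    cat  = { r[c("front", "both")] <- k_a; r },
    csat = { r[c("back", "both")] <- k_a; r }
  )
}

.cleave_rates <- function(cleave, k_cleave) {
  r <- c(no = 0, back = 0, front = 0, both = 0)
  switch(cleave,
    none = r,
    sec  = { r[c("no", "back")] <- k_cleave; r },
    csec = { r[c("back", "both")] <- k_cleave; r }
  )
}

#' Construct a full parameter set for the translation / quality-control model
#'
#' Returns the complete, validated parameter list of the continuous-time
#' Markov chain: translation (initiation, elongation, termination),
#' canonical decay (per-residue deadenylation, decapping, 5'-3'
#' exonucleolysis), and the preset-controlled quality-control rates
#' (abortive termination and endonucleolytic cleavage by collision status).
#' Defaults reproduce the reference parameterization: a 650-codon mRNA with
#' a 60-residue poly(A) tail, elongation at 10/s, termination at 1/s,
#' deadenylation 0.03/s per residue, decapping 0.01/s, 5'-3' exonucleolysis
#' 1/s, transcription 0.001/s, a 10-codon ribosome footprint, cleavage
#' offset 10 codons 5' of the A site, and a 6-codon stall starting at codon
#' 401 with a net rate of 0.1/s across the stall.
#'
#' @param preset a [model_preset()], or a preset string like `"csat"`
#'   (cleavage preset then taken from `cleave`).
#' @param k_a nonzero abortive-termination rate used by the sat/cat/csat
#'   presets, 1/s.
#' @param k_cleave nonzero endonucleolytic cleavage rate used by the
#'   sec/csec presets, 1/s.
#' @param cleave cleavage preset string when `preset` is given as a string.
#' @param ... named overrides for any other parameter field
#'   (`k_transcription`, `k_init`, `k_elong_default`, `k_term`,
#'   `k_deadenylation`, `k_decapping`, `k_exo_53`, `k_exo_35`,
#'   `k_abort_truncated`, `L_m`, `L_p`, `L_c`, `stall_start`, `n_stall`,
#'   `net_stall_rate`, or the individual `k_abort_*` / `k_cleave_*` rates).
#'   Overrides are applied after the preset table, and
#'   `elongation_rates` is then re-derived unless supplied explicitly.
#' @return a `"model_params"` list.
#' @examples
#' p <- make_params("csat", k_a = 0.1)
#' p$k_abort_back_hit   # 0.1
#' p$k_abort_no_hit     # 0
#' @export
make_params <- function(preset = model_preset("tj", "none"),
                        k_a = 0.5, k_cleave = 0.001,
                        cleave = "none", ...) {
  if (is.character(preset)) preset <- model_preset(preset, cleave)
  stopifnot(inherits(preset, "model_preset"))
  if (preset$abort != "tj" && k_a <= 0)
    stop("preset '", preset$abort, "' requires k_a > 0")
  if (preset$cleave != "none" && k_cleave <= 0)
    stop("preset '", preset$cleave, "' requires k_cleave > 0")

  ab <- .abort_rates(preset$abort, k_a)
  cl <- .cleave_rates(preset$cleave, k_cleave)
  p <- list(
    abort_model        = preset$abort,
    cleave_model       = preset$cleave,
    k_transcription    = 0.001,
    k_init             = 0.1,
    k_elong_default    = 10,
    k_term             = 1,
    k_deadenylation    = 0.03,
    k_decapping        = 0.01,
    k_exo_53           = 1,
    k_exo_35           = 0,
    k_abort_no_hit     = unname(ab["no"]),
    k_abort_back_hit   = unname(ab["back"]),
    k_abort_front_hit  = unname(ab["front"]),
    k_abort_both_hit   = unname(ab["both"]),
    k_abort_truncated  = 1,
    k_cleave_no_hit    = unname(cl["no"]),
    k_cleave_back_hit  = unname(cl["back"]),
    k_cleave_front_hit = unname(cl["front"]),
    k_cleave_both_hit  = unname(cl["both"]),
    L_m                = 650L,
    L_p                = 60L,
    footprint          = 10L,
    L_c                = 10L,
    stall_start        = 401L,
    n_stall            = 6L,
    net_stall_rate     = 0.1
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), c(names(p), "elongation_rates"))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  if (is.null(p$elongation_rates))
    p$elongation_rates <- stall_profile(p$L_m, p$stall_start, p$n_stall,
                                        p$net_stall_rate, p$k_elong_default)
  validate_params(structure(p, class = "model_params"))
}

#' Validate a model parameter list
#'
#' Checks non-negativity of every rate, lattice geometry (`L_m >=`
#' footprint, stall window within the coding region), and the length of the
#' derived elongation-rate vector.
#'
#' @param p a `"model_params"` list.
#' @return `p`, invisibly unchanged, or an error.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  rates <- c("k_transcription", "k_init", "k_elong_default", "k_term",
             "k_deadenylation", "k_decapping", "k_exo_53", "k_exo_35",
             "k_abort_no_hit", "k_abort_back_hit", "k_abort_front_hit",
             "k_abort_both_hit", "k_abort_truncated",
             "k_cleave_no_hit", "k_cleave_back_hit", "k_cleave_front_hit",
             "k_cleave_both_hit", "net_stall_rate")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", nm, "' must be a single non-negative rate")
  }
  if (p$L_m < p$footprint) stop("L_m must be at least one ribosome footprint")
  if (p$L_p < 0) stop("L_p must be non-negative")
  if (p$L_c < 1) stop("L_c must be at least 1 codon")
  if (p$n_stall > 0 &&
      (p$stall_start < 1 || p$stall_start + p$n_stall - 1 > p$L_m))
    stop("stall window outside [1, L_m]")
  if (length(p$elongation_rates) != p$L_m)
    stop("elongation_rates must have length L_m")
  if (any(p$elongation_rates < 0)) stop("elongation rates must be >= 0")
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Translation / quality-control model parameters\n")
  cat("  presets: abort =", x$abort_model, "| cleave =", x$cleave_model, "\n")
  cat(sprintf("  mRNA: L_m = %d codons, poly(A) = %d nt, footprint = %d, L_c = %d\n",
              x$L_m, x$L_p, x$footprint, x$L_c))
  if (x$n_stall > 0)
    cat(sprintf("  stall: %d codon(s) at %d-%d, net rate %.3g/s (per codon %.3g/s)\n",
                x$n_stall, x$stall_start, x$stall_start + x$n_stall - 1,
                x$net_stall_rate, x$n_stall * x$net_stall_rate))
  else cat("  stall: none\n")
  cat(sprintf("  k_init = %.3g, k_elong = %.3g, k_term = %.3g (1/s)\n",
              x$k_init, x$k_elong_default, x$k_term))
  cat(sprintf("  decay: deadenylation %.3g, decapping %.3g, exo 5'-3' %.3g, exo 3'-5' %.3g (1/s)\n",
              x$k_deadenylation, x$k_decapping, x$k_exo_53, x$k_exo_35))
  cat(sprintf("  abort (no/back/front/both/truncated): %.3g %.3g %.3g %.3g %.3g\n",
              x$k_abort_no_hit, x$k_abort_back_hit, x$k_abort_front_hit,
              x$k_abort_both_hit, x$k_abort_truncated))
  cat(sprintf("  cleave (no/back/front/both): %.3g %.3g %.3g %.3g\n",
              x$k_cleave_no_hit, x$k_cleave_back_hit, x$k_cleave_front_hit,
              x$k_cleave_both_hit))
  invisible(x)
}

#' Load model parameters from a YAML or JSON config file
#'
#' The config may carry `abort` and `cleave` preset names, `k_a` and
#' `k_cleave`, and any parameter field accepted by [make_params()] as flat
#' keys.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return a `"model_params"` list.
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)  # yaml::read_yaml also parses plain JSON maps
  if (!is.list(cfg)) stop("config must be a mapping of parameter names")
  abort <- if (is.null(cfg$abort)) "tj" else cfg$abort
  cleave <- if (is.null(cfg$cleave)) "none" else cfg$cleave
  k_a <- if (is.null(cfg$k_a)) 0.5 else cfg$k_a
  k_cleave <- if (is.null(cfg$k_cleave)) 0.001 else cfg$k_cleave
  cfg[c("abort", "cleave", "k_a", "k_cleave")] <- NULL
  do.call(make_params,
          c(list(preset = model_preset(abort, cleave),
                 k_a = k_a, k_cleave = k_cleave), cfg))
}
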