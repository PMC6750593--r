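// Exact (direct-method) stochastic simulation of the translation /
// quality-control / mRNA-decay CTMC.
//
// The state kept here is a compressed but lossless encoding of the
// rule-level state: deadenylation and 5'-3' exonucleolysis proceed
// strictly sequentially, so the poly(A) tail is a count of remaining
// residues and the exonucleolysed backbone prefix is a front pointer; at
// most one endonucleolytic cut can occur per mRNA (cleavage requires the
// cap and removes it), so a single cut position suffices.  Ribosomes are
// kept position-sorted with their two collision-bond flags.
//
// Propensities are re-enumerated per step in a fixed order; the walk that
// sums them and the walk that picks the firing event share one code path,
// which keeps selection exactly consistent with the total.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <climits>
using namespace Rcpp;

enum Rule {
  R_TRANSCRIBE = 1, R_INITIATE, R_ELONGATE, R_TERMINATE, R_COLLIDE,
  R_DEADENYLATE, R_DECAP, R_EXO53,
  R_ABORT_NO, R_ABORT_BACK, R_ABORT_FRONT, R_ABORT_BOTH, R_ABORT_TRUNC,
  R_CLEAVE_NO, R_CLEAVE_BACK, R_CLEAVE_FRONT, R_CLEAVE_BOTH
};

struct Rib {
  int a;          // A-site codon, 1-based
  bool hb, hf;    // collided from back (leading partner) / front (trailing)
};

struct Mr {
  int rec;        // index into the birth/death record vectors
  bool cap, start_blocked;
  int polyA;      // intact poly(A) residues remaining
  int exo;        // length of the 5' exonucleolysed backbone prefix
  int endo;       // endonucleolytic cut position, 0 = none
  std::vector<Rib> ribs;  // ascending A site

  bool intact(int pos) const { return pos > exo && pos != endo; }
  bool codon_bonded(int pos) const {
    for (const Rib& r : ribs) {
      if (r.a == pos) return true;
      if (r.a > pos) return false;
    }
    return false;
  }
};

struct Pars {
  double k_tx, k_init, k_term, k_deaden, k_decap, k_exo53;
  double k_abort[4];   // index: (hb ? 1 : 0) | (hf ? 2 : 0)
  double k_abort_trunc;
  double k_cleave[4];
  int Lm, Lp, fp, Lc;
  std::vector<double> elong;
};

struct Ev { int rule; int rib; };  // rib index within the mRNA, or -1

// Enumerates the mRNA's enabled events in a fixed order.  With pick < 0 it
// returns the total propensity; otherwise it stops at the event where the
// cumulative propensity first exceeds pick (falling back to the last
// enabled event against round-off) and writes it to *out.
static double walk_mrna(const Mr& m, const Pars& P, double pick, Ev* out) {
  double acc = 0.0;
  Ev last = { 0, -1 };
  bool found = false;
  auto emit = [&](double p, int rule, int rib) {
    if (p <= 0.0 || found) return;
    acc += p;
    last.rule = rule; last.rib = rib;
    if (out && acc > pick) { *out = last; found = true; }
  };

  // initiation
  if (m.cap && !m.start_blocked && m.intact(1) &&
      !(m.ribs.size() && m.ribs[0].a == 1))
    emit(P.k_init, R_INITIATE, -1);
  // deadenylation (one eligible boundary residue)
  if (m.polyA > 0) emit(P.k_deaden, R_DEADENYLATE, -1);
  // decapping after complete deadenylation
  if (m.cap && m.polyA == 0) emit(P.k_decap, R_DECAP, -1);
  // 5'-3' exonucleolysis at the single eligible position exo + 1
  {
    int pos = m.exo + 1;
    if (pos <= P.Lm && pos != m.endo && (m.exo > 0 || !m.cap) &&
        !m.codon_bonded(pos))
      emit(P.k_exo53, R_EXO53, -1);
  }
  // per-ribosome rules
  int n = (int) m.ribs.size();
  for (int j = 0; j < n; ++j) {
    const Rib& r = m.ribs[j];
    int gap = (j + 1 < n) ? (m.ribs[j + 1].a - r.a) : INT_MAX;
    if (r.a == P.Lm) {
      emit(P.k_term, R_TERMINATE, j);
    } else {
      bool src_intact = m.intact(r.a);
      if (src_intact && gap > P.fp)
        emit(P.elong[r.a - 1], R_ELONGATE, j);
      else if (gap == P.fp && !r.hf)
        emit(P.elong[r.a - 1], R_COLLIDE, j);
    }
    int idx = (r.hb ? 1 : 0) | (r.hf ? 2 : 0);
    if (m.intact(r.a))
      emit(P.k_abort[idx], R_ABORT_NO + idx, j);
    else if (r.a == m.endo)
      emit(P.k_abort_trunc, R_ABORT_TRUNC, j);
    if (m.cap && r.a > P.Lc && m.intact(r.a - P.Lc))
      emit(P.k_cleave[idx], R_CLEAVE_NO + idx, j);
  }
  if (out && !found) *out = last;  // round-off fallback
  return acc;
}

struct Log {
  bool on;
  std::vector<double> t;
  std::vector<int> rule, mrna, site;
  void push(double tt, int r, int m, int s) {
    if (!on) return;
    t.push_back(tt); rule.push_back(r); mrna.push_back(m); site.push_back(s);
  }
};

// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(List params, double duration, bool single_mrna,
                 bool track_events, double max_events) {
  Pars P;
  P.k_tx = as<double>(params["k_transcription"]);
  P.k_init = as<double>(params["k_init"]);
  P.k_term = as<double>(params["k_term"]);
  P.k_deaden = as<double>(params["k_deadenylation"]);
  P.k_decap = as<double>(params["k_decapping"]);
  P.k_exo53 = as<double>(params["k_exo_53"]);
  if (as<double>(params["k_exo_35"]) != 0.0)
    stop("the compiled engine requires k_exo_35 = 0; use the reference sampler for 3'-5' exonucleolysis");
  P.k_abort[0] = as<double>(params["k_abort_no_hit"]);
  P.k_abort[1] = as<double>(params["k_abort_back_hit"]);
  P.k_abort[2] = as<double>(params["k_abort_front_hit"]);
  P.k_abort[3] = as<double>(params["k_abort_both_hit"]);
  P.k_abort_trunc = as<double>(params["k_abort_truncated"]);
  P.k_cleave[0] = as<double>(params["k_cleave_no_hit"]);
  P.k_cleave[1] = as<double>(params["k_cleave_back_hit"]);
  P.k_cleave[2] = as<double>(params["k_cleave_front_hit"]);
  P.k_cleave[3] = as<double>(params["k_cleave_both_hit"]);
  P.Lm = as<int>(params["L_m"]);
  P.Lp = as<int>(params["L_p"]);
  P.fp = as<int>(params["footprint"]);
  P.Lc = as<int>(params["L_c"]);
  P.elong = as<std::vector<double>>(params["elongation_rates"]);

  std::vector<Mr> ms;
  std::vector<double> births, deaths;
  double n_init = 0, n_full = 0, n_aborted = 0;
  Log log; log.on = track_events;

  auto transcribe = [&](double t) {
    Mr m;
    m.rec = (int) births.size();
    births.push_back(t); deaths.push_back(NA_REAL);
    m.cap = true; m.start_blocked = false;
    m.polyA = P.Lp; m.exo = 0; m.endo = 0;
    ms.push_back(m);
  };
  if (single_mrna) transcribe(0.0);

  double t = 0.0;
  long long nev = 0;
  const long long ev_cap = (long long) max_events;
  bool cap_hit = false, exhausted = false;
  std::vector<double> mtot;

  while (true) {
    mtot.resize(ms.size());
    double tot = P.k_tx;
    for (size_t i = 0; i < ms.size(); ++i) {
      mtot[i] = walk_mrna(ms[i], P, -1.0, nullptr);
      tot += mtot[i];
    }
    if (tot <= 0.0) { exhausted = true; break; }
    double dt = R::exp_rand() / tot;
    if (t + dt > duration) { t = duration; break; }
    t += dt;
    double pick = unif_rand() * tot;

    if (pick < P.k_tx) {
      transcribe(t);
      log.push(t, R_TRANSCRIBE, (int) births.size(), 0);
    } else {
      pick -= P.k_tx;
      size_t i = 0;
      for (; i + 1 < ms.size(); ++i) {
        if (pick < mtot[i]) break;
        pick -= mtot[i];
      }
      if (mtot[i] <= 0.0) {  // round-off fallback: last mRNA with events
        for (size_t j = ms.size(); j-- > 0;)
          if (mtot[j] > 0.0) { i = j; break; }
      }
      Mr& m = ms[i];
      Ev ev;
      walk_mrna(m, P, pick, &ev);

      auto clear_back = [&](int j) {       // dissolve bond with trailer
        if (m.ribs[j].hb) { m.ribs[j].hb = false; m.ribs[j - 1].hf = false; }
      };
      auto clear_front = [&](int j) {      // dissolve bond with leader
        if (m.ribs[j].hf) { m.ribs[j].hf = false; m.ribs[j + 1].hb = false; }
      };
      auto remove_rib = [&](int j) {
        clear_back(j); clear_front(j);
        if (m.ribs[j].a <= 9) m.start_blocked = false;
        m.ribs.erase(m.ribs.begin() + j);
      };

      int site = (ev.rib >= 0) ? m.ribs[ev.rib].a : 0;
      switch (ev.rule) {
      case R_INITIATE: {
        Rib r; r.a = 1; r.hb = r.hf = false;
        m.ribs.insert(m.ribs.begin(), r);
        m.start_blocked = true;
        n_init += 1; site = 1;
        break;
      }
      case R_ELONGATE:
        clear_back(ev.rib);
        if (m.ribs[ev.rib].a == 9) m.start_blocked = false;
        m.ribs[ev.rib].a += 1;
        break;
      case R_TERMINATE:
        remove_rib(ev.rib);
        n_full += 1;
        break;
      case R_COLLIDE:
        m.ribs[ev.rib].hf = true;
        m.ribs[ev.rib + 1].hb = true;
        break;
      case R_DEADENYLATE:
        m.polyA -= 1; site = m.polyA + 1;
        break;
      case R_DECAP:
        m.cap = false;
        break;
      case R_EXO53:
        m.exo += 1; site = m.exo;
        if (m.exo == 1) deaths[m.rec] = t;
        break;
      case R_ABORT_NO: case R_ABORT_BACK: case R_ABORT_FRONT:
      case R_ABORT_BOTH: case R_ABORT_TRUNC:
        remove_rib(ev.rib);
        n_aborted += 1;
        break;
      case R_CLEAVE_NO: case R_CLEAVE_BACK: case R_CLEAVE_FRONT:
      case R_CLEAVE_BOTH:
        m.endo = m.ribs[ev.rib].a - P.Lc;
        m.cap = false;
        // the rule dissolves the bond it was conditioned on: the front
        // bond for a front-hit ribosome, the back bond otherwise
        if (ev.rule == R_CLEAVE_FRONT) clear_front(ev.rib);
        else if (ev.rule != R_CLEAVE_NO) clear_back(ev.rib);
        break;
      default:
        stop("internal error: stale event");
      }
      log.push(t, ev.rule, m.rec + 1, site);

      // an mRNA with no ribosomes and zero propensity is chemically inert
      if (m.ribs.empty() && walk_mrna(m, P, -1.0, nullptr) <= 0.0)
        ms.erase(ms.begin() + i);
    }

    nev += 1;
    if (nev >= ev_cap) { cap_hit = true; break; }
    if ((nev & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  double bound = 0;
  for (const Mr& m : ms) bound += (double) m.ribs.size();

  List out = List::create(
    _["t_end"] = t,
    _["n_events"] = (double) nev,
    _["n_initiations"] = n_init,
    _["n_full"] = n_full,
    _["n_aborted"] = n_aborted,
    _["n_transcribed"] = (double) births.size(),
    _["n_bound_end"] = bound,
    _["mrna_births"] = wrap(births),
    _["mrna_deaths"] = wrap(deaths),
    _["hit_event_cap"] = cap_hit,
    _["exhausted"] = exhausted);
  if (track_events)
    out["events"] = DataFrame::create(
      _["time"] = wrap(log.t), _["rule"] = wrap(log.rule),
      _["mrna"] = wrap(log.mrna), _["site"] = wrap(log.site));
  return out;
}
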