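// Discrete-time two-species exclusion process on a codon lattice.
//
// Site values: 0 empty, 1 covered by a scanning ribosome, 2 by an
// elongating ribosome.  A particle is an extended object covering the
// contiguous 1-based sites [front - D + 1, front], where `front` is its
// leading (3'-most) edge and D its footprint.  All randomness comes from
// R's own generator (unif_rand), so set.seed() on the R side makes every
// run reproducible.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Pars {
  int L1, L2, L3, Dsig, Deps;
  double m_sig, m_eps, t_init, t_reinit, lambda, delta_eps, P_sig, P_eps;
  bool collision;
  int L, start, stop, fin; // derived 1-based indices; fin = exit site
};

struct Particle {
  int id;
  int kind;   // 0 scanning, 1 elongating
  int front;  // 1-based leading edge
  bool paused; // elongating: initiation pause not yet released
  bool leaky;  // scanning: failed its one initiation draw at the start
};

struct Counters {
  int64_t loaded = 0, exited = 0, initiated = 0, terminated = 0,
          reinitiated = 0, collided = 0, sig_spont = 0, eps_spont = 0;
};

struct State {
  std::vector<int8_t> sites;    // sites[i] is 1-based site i+1
  std::vector<Particle> parts;  // sorted by ascending front
  Counters cnt;
  int next_id = 1;
};

Pars read_pars(const List& par) {
  Pars p;
  p.L1 = as<int>(par["L1"]);
  p.L2 = as<int>(par["L2"]);
  p.L3 = as<int>(par["L3"]);
  p.Dsig = as<int>(par["D_sigma"]);
  p.Deps = as<int>(par["D_eps"]);
  p.m_sig = as<double>(par["m_sigma"]);
  p.m_eps = as<double>(par["m_eps"]);
  p.t_init = as<double>(par["t_init"]);
  p.t_reinit = as<double>(par["t_reinit"]);
  p.lambda = as<double>(par["lambda_load"]);
  p.delta_eps = as<double>(par["delta_eps"]);
  p.P_sig = as<double>(par["P_sigma_spont"]);
  p.P_eps = as<double>(par["P_eps_spont"]);
  p.collision = as<bool>(par["collision_dissociation"]);
  p.L = p.L1 + p.L2 + p.L3;
  p.start = p.L1 + 1;
  p.stop = p.L1 + p.L2;
  p.fin = p.L;
  return p;
}

inline void paint(State& st, int from, int to, int8_t val) {
  for (int s = from; s <= to; ++s) st.sites[s - 1] = val;
}

inline int footprint(const Pars& p, const Particle& q) {
  return q.kind == 0 ? p.Dsig : p.Deps;
}

// clear a particle's footprint and drop it from the registry
void remove_particle(State& st, const Pars& p, size_t idx) {
  const Particle& q = st.parts[idx];
  paint(st, q.front - footprint(p, q) + 1, q.front, 0);
  st.parts.erase(st.parts.begin() + idx);
}

// Routine 1: load a scanning ribosome onto the first D_sigma sites.
void r_load(State& st, const Pars& p) {
  if (p.lambda <= 0) return;
  for (int s = 0; s < p.Dsig; ++s)
    if (st.sites[s] != 0) return;
  if (unif_rand() < p.lambda) {
    Particle q{st.next_id++, 0, p.Dsig, false, false};
    st.parts.insert(st.parts.begin(), q); // smallest front on the lattice
    paint(st, 1, p.Dsig, 1);
    ++st.cnt.loaded;
  }
}

// Routine 2: scanning -> elongating conversion at the uORF start site.
// Each scanning ribosome faces exactly one initiation draw per arrival:
// a ribosome that fails it is marked leaky and scans on untested, so the
// nominal t_init is the realized per-ribosome initiation efficiency.
// The leading edge stays at the start site; when D_eps > D_sigma the
// extra trailing sites must be free, otherwise the draw is deferred.
void r_initiate(State& st, const Pars& p) {
  for (size_t i = 0; i < st.parts.size(); ++i) {
    Particle& q = st.parts[i];
    if (q.kind != 0 || q.front != p.start || q.leaky) continue;
    if (p.Deps > p.Dsig) {
      for (int s = p.start - p.Deps + 1; s <= p.start - p.Dsig; ++s)
        if (st.sites[s - 1] != 0) return; // deferred this tact
    }
    if (p.t_init > 0 && unif_rand() < p.t_init) {
      paint(st, q.front - p.Dsig + 1, q.front, 0);
      q.kind = 1;
      q.paused = p.delta_eps < 1.0;
      paint(st, q.front - p.Deps + 1, q.front, 2);
      ++st.cnt.initiated;
    } else {
      q.leaky = true;
    }
    return; // exclusion: at most one particle fronts the start site
  }
}

// Routine 3: an elongating ribosome at the uORF stop site reinitiates
// (becomes scanning) with probability t_reinit, else terminates.
void r_terminate(State& st, const Pars& p) {
  for (size_t i = 0; i < st.parts.size(); ++i) {
    Particle& q = st.parts[i];
    if (q.kind != 1 || q.front != p.stop) continue;
    bool can_convert = true;
    if (p.Dsig > p.Deps) {
      for (int s = p.stop - p.Dsig + 1; s <= p.stop - p.Deps; ++s)
        if (st.sites[s - 1] != 0) { can_convert = false; break; }
    }
    if (p.t_reinit <= 0) {
      remove_particle(st, p, i);
      ++st.cnt.terminated;
    } else if (!can_convert) {
      // reinitiation possible in principle but geometrically blocked:
      // defer the whole outcome to a later tact
    } else if (unif_rand() < p.t_reinit) {
      paint(st, q.front - p.Deps + 1, q.front, 0);
      q.kind = 0;
      q.paused = false;
      q.leaky = false; // resumed scanning is past the start; flag unused
      paint(st, q.front - p.Dsig + 1, q.front, 1);
      ++st.cnt.reinitiated;
    } else {
      remove_particle(st, p, i);
      ++st.cnt.terminated;
    }
    return;
  }
}

// Routine 4: a scanning ribosome fronting the last lattice site exits
// and is registered (this count defines r_out).
int r_exit(State& st, const Pars& p) {
  for (size_t i = 0; i < st.parts.size(); ++i) {
    const Particle& q = st.parts[i];
    if (q.kind == 0 && q.front == p.fin) {
      remove_particle(st, p, i);
      ++st.cnt.exited;
      return 1;
    }
  }
  return 0;
}

// Routine 5: one movement attempt per particle, visited in decreasing
// front order so no particle moves twice and a trailing particle may
// enter a site vacated this same tact.
void r_move(State& st, const Pars& p) {
  for (int i = (int)st.parts.size() - 1; i >= 0; --i) {
    Particle& q = st.parts[i];
    if (q.kind == 0) {
      if (q.front >= p.fin) continue;          // nowhere to go
      if (st.sites[q.front] != 0) continue;    // site front+1 occupied
      if (unif_rand() < p.m_sig) {
        st.sites[q.front] = 1;
        st.sites[q.front - p.Dsig] = 0;
        ++q.front;
      }
    } else {
      if (q.front >= p.stop) continue;         // elongation ends at the stop
      int8_t ahead = st.sites[q.front];
      if (ahead == 2) continue;                // blocked by an elongating ribosome
      double pm = q.paused ? p.delta_eps * p.m_eps : p.m_eps;
      if (pm > 0 && unif_rand() < pm) {
        if (ahead == 1) {
          if (!p.collision) continue;          // blocked, no dissociation
          // the scanning ribosome whose trailing edge sits at front+1 is
          // the next particle up the lattice
          remove_particle(st, p, i + 1);
          ++st.cnt.collided;
        }
        st.sites[q.front] = 2;
        st.sites[q.front - p.Deps] = 0;
        ++q.front;
        q.paused = false;
      }
    }
  }
}

// Routine 6: spontaneous dissociation.
void r_spont(State& st, const Pars& p) {
  if (p.P_sig <= 0 && p.P_eps <= 0) return;
  for (int i = (int)st.parts.size() - 1; i >= 0; --i) {
    const Particle& q = st.parts[i];
    if (q.kind == 0) {
      if (p.P_sig > 0 && unif_rand() < p.P_sig) {
        remove_particle(st, p, i);
        ++st.cnt.sig_spont;
      }
    } else {
      if (p.P_eps > 0 && unif_rand() < p.P_eps) {
        remove_particle(st, p, i);
        ++st.cnt.eps_spont;
      }
    }
  }
}

// one tact = routines 1..6 in order; `mask` restricts which run (tests)
int do_tact(State& st, const Pars& p, int mask) {
  int ex = 0;
  if (mask & 1) r_load(st, p);
  if (mask & 2) r_initiate(st, p);
  if (mask & 4) r_terminate(st, p);
  if (mask & 8) ex = r_exit(st, p);
  if (mask & 16) r_move(st, p);
  if (mask & 32) r_spont(st, p);
  return ex;
}

// structural + bookkeeping audit; stops on the first violation.
// The conservation ledger only closes for runs begun on an empty lattice,
// so it is optional.
void audit(const State& st, const Pars& p, int64_t tact_no, bool ledger) {
  std::vector<int8_t> proj(p.L, 0);
  int n_scan = 0, n_elong = 0;
  int prev_front = 0;
  for (size_t i = 0; i < st.parts.size(); ++i) {
    const Particle& q = st.parts[i];
    int D = footprint(p, q);
    if (q.front - D + 1 < 1 || q.front > p.L)
      stop("audit: particle footprint outside the lattice at tact %s",
           std::to_string(tact_no));
    if (q.kind == 1 && (q.front < p.start || q.front > p.stop))
      stop("audit: elongating ribosome outside the uORF at tact %s",
           std::to_string(tact_no));
    if (q.front - D + 1 <= prev_front)
      stop("audit: overlapping or unsorted particles at tact %s",
           std::to_string(tact_no));
    prev_front = q.front;
    for (int s = q.front - D + 1; s <= q.front; ++s)
      proj[s - 1] = q.kind == 0 ? 1 : 2;
    if (q.kind == 0) ++n_scan; else ++n_elong;
  }
  for (int s = 0; s < p.L; ++s)
    if (proj[s] != st.sites[s])
      stop("audit: site string does not match the particle registry at tact %s",
           std::to_string(tact_no));
  if (!ledger) return;
  const Counters& c = st.cnt;
  if (c.loaded != c.exited + c.collided + c.sig_spont +
                  (c.initiated - c.reinitiated) + n_scan)
    stop("audit: scanning-ribosome ledger does not close at tact %s",
         std::to_string(tact_no));
  if (c.initiated != c.terminated + c.reinitiated + c.eps_spont + n_elong)
    stop("audit: elongating-ribosome ledger does not close at tact %s",
         std::to_string(tact_no));
}

List counters_list(const Counters& c) {
  return List::create(
      _["loaded"] = (double)c.loaded,
      _["exited"] = (double)c.exited,
      _["initiated"] = (double)c.initiated,
      _["terminated"] = (double)c.terminated,
      _["reinitiated"] = (double)c.reinitiated,
      _["collision_dissociated"] = (double)c.collided,
      _["sigma_spont_dissociated"] = (double)c.sig_spont,
      _["eps_spont_dissociated"] = (double)c.eps_spont);
}

DataFrame particles_df(const State& st) {
  int n = st.parts.size();
  IntegerVector id(n), kind(n), front(n);
  LogicalVector paused(n), leaky(n);
  for (int i = 0; i < n; ++i) {
    id[i] = st.parts[i].id;
    kind[i] = st.parts[i].kind;
    front[i] = st.parts[i].front;
    paused[i] = st.parts[i].paused;
    leaky[i] = st.parts[i].leaky;
  }
  return DataFrame::create(_["id"] = id, _["kind"] = kind,
                           _["front"] = front, _["paused"] = paused,
                           _["leaky"] = leaky);
}

State state_from_list(const List& state, const Pars& p) {
  State st;
  IntegerVector sites = state["sites"];
  if ((int)sites.size() != p.L) stop("state/parameter lattice length mismatch");
  st.sites.assign(sites.begin(), sites.end());
  DataFrame parts = as<DataFrame>(state["particles"]);
  IntegerVector id = parts["id"], kind = parts["kind"], front = parts["front"];
  LogicalVector paused = parts["paused"], leaky = parts["leaky"];
  for (int i = 0; i < id.size(); ++i)
    st.parts.push_back(Particle{id[i], kind[i], front[i], paused[i] == TRUE,
                                leaky[i] == TRUE});
  NumericVector cn = state["counters"];
  st.cnt.loaded = (int64_t)cn["loaded"];
  st.cnt.exited = (int64_t)cn["exited"];
  st.cnt.initiated = (int64_t)cn["initiated"];
  st.cnt.terminated = (int64_t)cn["terminated"];
  st.cnt.reinitiated = (int64_t)cn["reinitiated"];
  st.cnt.collided = (int64_t)cn["collision_dissociated"];
  st.cnt.sig_spont = (int64_t)cn["sigma_spont_dissociated"];
  st.cnt.eps_spont = (int64_t)cn["eps_spont_dissociated"];
  st.next_id = as<int>(state["next_id"]);
  return st;
}

List state_to_list(const State& st) {
  IntegerVector sites(st.sites.begin(), st.sites.end());
  return List::create(_["sites"] = sites,
                      _["particles"] = particles_df(st),
                      _["counters"] = counters_list(st.cnt),
                      _["next_id"] = st.next_id);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_run")]]
List cpp_run(List par, double n_tacts, double burn_in, bool occupancy,
             bool checks, int n_batches) {
  Pars p = read_pars(par);
  State st;
  st.sites.assign(p.L, 0);
  int64_t nt = (int64_t)n_tacts, nb = (int64_t)burn_in;
  int64_t n_eff = nt - nb;
  if (n_eff <= 0) stop("burn_in must be smaller than n_tacts");
  if (n_batches > n_eff) n_batches = (int)n_eff;

  std::vector<double> batch_exits(n_batches, 0.0), batch_loads(n_batches, 0.0);
  std::vector<double> occ_scan, occ_elong;
  if (occupancy) {
    occ_scan.assign(p.L, 0.0);
    occ_elong.assign(p.L, 0.0);
  }
  int64_t loads_pre = 0, exits_pre = 0;

  for (int64_t t = 0; t < nt; ++t) {
    int64_t loaded_before = st.cnt.loaded;
    int ex = do_tact(st, p, 63);
    if (t >= nb) {
      int b = (int)((t - nb) * n_batches / n_eff);
      batch_exits[b] += ex;
      batch_loads[b] += (double)(st.cnt.loaded - loaded_before);
      if (occupancy)
        for (int s = 0; s < p.L; ++s) {
          if (st.sites[s] == 1) occ_scan[s] += 1.0;
          else if (st.sites[s] == 2) occ_elong[s] += 1.0;
        }
    } else {
      exits_pre += ex;
      loads_pre += st.cnt.loaded - loaded_before;
    }
    if (checks && ((t + 1) % 10000 == 0)) audit(st, p, t + 1, true);
  }
  if (checks) audit(st, p, nt, true);

  double tot_exits = 0, tot_loads = 0;
  for (int b = 0; b < n_batches; ++b) {
    tot_exits += batch_exits[b];
    tot_loads += batch_loads[b];
  }
  double r_out = tot_exits / (double)n_eff;
  double load_rate = tot_loads / (double)n_eff;
  double se = NA_REAL;
  if (n_batches >= 2) {
    double bl = (double)n_eff / n_batches, m = 0, v = 0;
    std::vector<double> rates(n_batches);
    for (int b = 0; b < n_batches; ++b) {
      rates[b] = batch_exits[b] / bl;
      m += rates[b];
    }
    m /= n_batches;
    for (int b = 0; b < n_batches; ++b) v += (rates[b] - m) * (rates[b] - m);
    v /= (n_batches - 1);
    se = std::sqrt(v / n_batches);
  }

  RObject occ = R_NilValue;
  if (occupancy) {
    NumericVector os(occ_scan.begin(), occ_scan.end());
    NumericVector oe(occ_elong.begin(), occ_elong.end());
    os = os / (double)n_eff;
    oe = oe / (double)n_eff;
    occ = List::create(_["scanning"] = os, _["elongating"] = oe);
  }

  return List::create(
      _["counters"] = counters_list(st.cnt),
      _["r_out"] = r_out,
      _["r_out_se"] = se,
      _["realized_load_rate"] = load_rate,
      _["batch_exits"] = NumericVector(batch_exits.begin(), batch_exits.end()),
      _["occupancy"] = occ,
      _["state"] = state_to_list(st));
}

//' @noRd
// [[Rcpp::export(name = "cpp_advance")]]
List cpp_advance(List state, List par, int n, int mask, bool checks) {
  Pars p = read_pars(par);
  State st = state_from_list(state, p);
  int exits = 0;
  for (int t = 0; t < n; ++t) {
    exits += do_tact(st, p, mask);
    if (checks) audit(st, p, t + 1, false);
  }
  List out = state_to_list(st);
  out["exits"] = exits;
  return out;
}
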