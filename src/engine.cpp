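// Event-driven engine for the spiking cart-pole agent.
//
// The R layer owns all model definitions (network wiring, parameter tables,
// training logic); this file provides the fast inner loops: lazy-decay
// integrate-and-fire neuron updates, the synaptic event queue, the 50 ms
// window simulation, eligibility-tag bookkeeping, the frozen-policy episode
// runner (including the cart-pole dynamics), and the all-inputs sweep.
//
// Conventions: neuron ids and synapse ids are 0-based internally, 1-based at
// the R boundary. Channels: 0 = AM2, 1 = NM2, 2 = GA, 3 = GA2.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const int N_CHAN = 4;

struct CellP {
  double v_rest, v_thresh, v_block, tau_ar, w_rr, tau_rr, dv_ahp, tau_ahp;
};

struct ChanP {
  double e_syn, tau, sign;
};

struct Neuron {
  double vsyn[N_CHAN];
  double vahp, vthr, last_t, refr_until, last_spike;
};

struct Ev {
  double t;
  long seq;     // insertion order: deterministic tie-break for equal times
  int post, chan;
  double w;
};

struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.seq > b.seq;
  }
};

// Minimal xorshift64* stream for tie-breaking inside C++ episode loops;
// keeps the R RNG untouched and episode runs reproducible from one integer.
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed * 2685821657736338717ULL + 1442695040888963407ULL) {
    if (s == 0) s = 88172645463325252ULL;
  }
  double unif() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return (double)(s >> 11) * (1.0 / 9007199254740992.0);
  }
};

struct Session {
  int n;                       // number of neurons
  std::vector<CellP> cellp;    // per cell type
  ChanP chanp[N_CHAN];
  std::vector<int> ctype;      // per neuron, 0-based index into cellp
  // synapses (structure fixed after construction)
  std::vector<int> pre, post, chan;
  std::vector<double> w, delay;
  std::vector<int> plastic_idx;  // genome position -> synapse id
  std::vector<int> plastic_pos;  // synapse id -> genome position or -1
  std::vector<std::vector<int> > out_adj;     // per neuron: outgoing synapse ids
  std::vector<std::vector<int> > in_plastic;  // per neuron: incoming plastic synapse ids
  // dynamic state
  std::vector<Neuron> st;
  double tnow;
  long seq;
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> q;
  std::vector<int> win_count;   // per-neuron spikes in the current window
  // plasticity bookkeeping
  bool tagging_on;
  double windhebb, lenhebb;
  std::vector<double> tag_expiry;     // per genome position, -inf = no tag
  std::vector<double> recept_target;  // per neuron: target summed plastic input
  std::vector<double> init_trans;     // per neuron: plastic transmission total at build
  std::vector<double> cur_trans;      // per neuron: current plastic transmission total
};

static void reset_neuron(Neuron& nr, const CellP& c) {
  for (int k = 0; k < N_CHAN; ++k) nr.vsyn[k] = 0.0;
  nr.vahp = 0.0;
  nr.vthr = c.v_thresh;
  nr.last_t = 0.0;
  nr.refr_until = -1e300;
  nr.last_spike = -1e300;
}

static void session_reset_state(Session& S) {
  for (int i = 0; i < S.n; ++i) reset_neuron(S.st[i], S.cellp[S.ctype[i]]);
  S.tnow = 0.0;
  S.seq = 0;
  S.q = std::priority_queue<Ev, std::vector<Ev>, EvCmp>();
  std::fill(S.win_count.begin(), S.win_count.end(), 0);
}

static void session_clear_tags(Session& S) {
  std::fill(S.tag_expiry.begin(), S.tag_expiry.end(), -1e300);
}

static inline double membrane(const Neuron& nr, const CellP& c, const ChanP* chanp) {
  double vm = c.v_rest - nr.vahp;
  for (int k = 0; k < N_CHAN; ++k) vm += chanp[k].sign * nr.vsyn[k];
  return vm;
}

static inline void decay_neuron(Neuron& nr, const CellP& c, const ChanP* chanp, double t) {
  double dt = t - nr.last_t;
  if (dt > 0) {
    for (int k = 0; k < N_CHAN; ++k)
      if (nr.vsyn[k] != 0.0) nr.vsyn[k] *= std::exp(-dt / chanp[k].tau);
    if (nr.vahp != 0.0) nr.vahp *= std::exp(-dt / c.tau_ahp);
    nr.vthr = c.v_thresh + (nr.vthr - c.v_thresh) * std::exp(-dt / c.tau_rr);
  }
  nr.last_t = t;
}

// Deliver one synaptic event; returns true if the neuron fired.
static inline bool deliver(Neuron& nr, const CellP& c, const ChanP* chanp,
                           int ch, double wgt, double t) {
  decay_neuron(nr, c, chanp, t);
  double vm = membrane(nr, c, chanp);
  double dv = wgt * (1.0 - (vm - c.v_rest) / (chanp[ch].e_syn - c.v_rest));
  nr.vsyn[ch] += dv;
  if (nr.vsyn[ch] < 0.0) nr.vsyn[ch] = 0.0;
  vm = membrane(nr, c, chanp);
  bool fired = (vm >= nr.vthr && vm <= c.v_block && t >= nr.refr_until);
  if (fired) {
    nr.last_spike = t;
    nr.vahp += c.dv_ahp;
    nr.vthr += c.w_rr * (c.v_block - nr.vthr);
    nr.refr_until = t + c.tau_ar;
    for (int k = 0; k < N_CHAN; ++k) nr.vsyn[k] = 0.0;
  }
  return fired;
}

// Simulate [tnow, tnow + wlen); each stimulated neuron receives one external
// AM2 event per offset (a short burst). Spikes update win_count; fired
// neurons enqueue their outgoing events and (if tagging is on) refresh
// eligibility tags.
static void run_window(Session& S, const std::vector<int>& stim, double stim_w,
                       double wlen, const std::vector<double>& offsets) {
  double t1 = S.tnow + wlen;
  std::fill(S.win_count.begin(), S.win_count.end(), 0);
  for (size_t k = 0; k < offsets.size(); ++k)
    for (size_t i = 0; i < stim.size(); ++i) {
      Ev e; e.t = S.tnow + offsets[k]; e.seq = S.seq++;
      e.post = stim[i]; e.chan = 0; e.w = stim_w;
      S.q.push(e);
    }
  while (!S.q.empty() && S.q.top().t < t1) {
    Ev e = S.q.top(); S.q.pop();
    Neuron& nr = S.st[e.post];
    bool fired = deliver(nr, S.cellp[S.ctype[e.post]], S.chanp, e.chan, e.w, e.t);
    if (fired) {
      S.win_count[e.post]++;
      const std::vector<int>& out = S.out_adj[e.post];
      for (size_t j = 0; j < out.size(); ++j) {
        int si = out[j];
        Ev o; o.t = e.t + S.delay[si]; o.seq = S.seq++;
        o.post = S.post[si]; o.chan = S.chan[si]; o.w = S.w[si];
        S.q.push(o);
      }
      if (S.tagging_on) {
        const std::vector<int>& inc = S.in_plastic[e.post];
        for (size_t j = 0; j < inc.size(); ++j) {
          int si = inc[j];
          double dpre = e.t - S.st[S.pre[si]].last_spike;
          if (dpre > 0 && dpre <= S.windhebb)
            S.tag_expiry[S.plastic_pos[si]] = e.t + S.lenhebb;
        }
      }
    }
  }
  S.tnow = t1;
}

// ---------------------------------------------------------------------------
// Exported session interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP sess_new(List net, NumericMatrix cell_params, IntegerVector cell_type,
              NumericMatrix chan_params) {
  Session* S = new Session();
  IntegerVector pre = net["pre"], post = net["post"], chan = net["chan"];
  NumericVector w = net["weight"], delay = net["delay"];
  LogicalVector plastic = net["plastic"];
  int ns = pre.size();
  S->n = cell_type.size();
  S->cellp.resize(cell_params.nrow());
  for (int i = 0; i < cell_params.nrow(); ++i) {
    CellP c;
    c.v_rest = cell_params(i, 0); c.v_thresh = cell_params(i, 1);
    c.v_block = cell_params(i, 2); c.tau_ar = cell_params(i, 3);
    c.w_rr = cell_params(i, 4); c.tau_rr = cell_params(i, 5);
    c.dv_ahp = cell_params(i, 6); c.tau_ahp = cell_params(i, 7);
    S->cellp[i] = c;
  }
  for (int k = 0; k < N_CHAN; ++k) {
    S->chanp[k].e_syn = chan_params(k, 0);
    S->chanp[k].tau = chan_params(k, 1);
    S->chanp[k].sign = chan_params(k, 2);
  }
  S->ctype.resize(S->n);
  for (int i = 0; i < S->n; ++i) S->ctype[i] = cell_type[i] - 1;
  S->pre.resize(ns); S->post.resize(ns); S->chan.resize(ns);
  S->w.resize(ns); S->delay.resize(ns); S->plastic_pos.assign(ns, -1);
  S->out_adj.assign(S->n, std::vector<int>());
  S->in_plastic.assign(S->n, std::vector<int>());
  for (int s = 0; s < ns; ++s) {
    S->pre[s] = pre[s] - 1; S->post[s] = post[s] - 1; S->chan[s] = chan[s] - 1;
    S->w[s] = w[s]; S->delay[s] = delay[s];
    S->out_adj[S->pre[s]].push_back(s);
    if (plastic[s]) {
      S->plastic_pos[s] = S->plastic_idx.size();
      S->plastic_idx.push_back(s);
      S->in_plastic[S->post[s]].push_back(s);
    }
  }
  int np = S->plastic_idx.size();
  S->tag_expiry.assign(np, -1e300);
  S->recept_target.assign(S->n, 0.0);
  S->init_trans.assign(S->n, 0.0);
  S->cur_trans.assign(S->n, 0.0);
  for (int g = 0; g < np; ++g) {
    int si = S->plastic_idx[g];
    S->recept_target[S->post[si]] += S->w[si];
    S->init_trans[S->pre[si]] += S->w[si];
    S->cur_trans[S->pre[si]] += S->w[si];
  }
  S->st.resize(S->n);
  S->win_count.assign(S->n, 0);
  S->tagging_on = false;
  S->windhebb = 20.0; S->lenhebb = 1000.0;
  session_reset_state(*S);
  XPtr<Session> ptr(S, true);
  return ptr;
}

// [[Rcpp::export]]
void sess_reset(SEXP sp) {
  XPtr<Session> S(sp);
  session_reset_state(*S);
}

// [[Rcpp::export]]
void sess_clear_eligibility(SEXP sp) {
  XPtr<Session> S(sp);
  session_clear_tags(*S);
}

// [[Rcpp::export]]
void sess_set_tagging(SEXP sp, bool on, double windhebb, double lenhebb) {
  XPtr<Session> S(sp);
  S->tagging_on = on;
  S->windhebb = windhebb;
  S->lenhebb = lenhebb;
}

// [[Rcpp::export]]
NumericVector sess_get_weights(SEXP sp) {
  XPtr<Session> S(sp);
  int np = S->plastic_idx.size();
  NumericVector out(np);
  for (int g = 0; g < np; ++g) out[g] = S->w[S->plastic_idx[g]];
  return out;
}

// [[Rcpp::export]]
void sess_set_weights(SEXP sp, NumericVector g) {
  XPtr<Session> S(sp);
  int np = S->plastic_idx.size();
  if (g.size() != np) stop("genome length mismatch");
  std::fill(S->cur_trans.begin(), S->cur_trans.end(), 0.0);
  for (int k = 0; k < np; ++k) {
    int si = S->plastic_idx[k];
    if (g[k] < 0) stop("negative weight");
    S->w[si] = g[k];
  }
  for (int k = 0; k < np; ++k) {
    int si = S->plastic_idx[k];
    S->cur_trans[S->pre[si]] += S->w[si];
  }
}

// [[Rcpp::export]]
IntegerVector sess_run_window(SEXP sp, IntegerVector stim, double stim_weight,
                              double window, NumericVector stim_offsets = NumericVector::create(0.0)) {
  XPtr<Session> S(sp);
  std::vector<int> st(stim.size());
  for (int i = 0; i < stim.size(); ++i) st[i] = stim[i] - 1;
  std::vector<double> off(stim_offsets.begin(), stim_offsets.end());
  run_window(*S, st, stim_weight, window, off);
  return IntegerVector(S->win_count.begin(), S->win_count.end());
}

// [[Rcpp::export]]
double sess_time(SEXP sp) {
  XPtr<Session> S(sp);
  return S->tnow;
}

// [[Rcpp::export]]
List sess_state(SEXP sp) {
  XPtr<Session> S(sp);
  NumericMatrix vsyn(S->n, N_CHAN);
  NumericVector vahp(S->n), vthr(S->n), vm(S->n), last_spike(S->n);
  for (int i = 0; i < S->n; ++i) {
    Neuron nr = S->st[i];
    const CellP& c = S->cellp[S->ctype[i]];
    decay_neuron(nr, c, S->chanp, S->tnow);
    for (int k = 0; k < N_CHAN; ++k) vsyn(i, k) = nr.vsyn[k];
    vahp[i] = nr.vahp; vthr[i] = nr.vthr;
    vm[i] = membrane(nr, c, S->chanp);
    last_spike[i] = nr.last_spike;
  }
  return List::create(_["vsyn"] = vsyn, _["vahp"] = vahp, _["vthresh"] = vthr,
                      _["vm"] = vm, _["last_spike"] = last_spike);
}

// [[Rcpp::export]]
NumericVector sess_tag_expiry(SEXP sp) {
  XPtr<Session> S(sp);
  return NumericVector(S->tag_expiry.begin(), S->tag_expiry.end());
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Critic-gated weight update over live eligibility tags. `s` is the
// per-genome-position delivery scaling computed in R (targeted variants).
// Output-balance factors are computed from the transmission totals as they
// stood when the critic arrived (snapshot), then all changes are applied.
// [[Rcpp::export]]
int sess_apply_critic(SEXP sp, NumericVector s, double critic, double hebbwt,
                      double now, bool use_balance, double bal_min, double bal_max) {
  XPtr<Session> S(sp);
  int np = S->plastic_idx.size();
  if (s.size() != np) stop("scaling vector length mismatch");
  if (critic < -1.0 || critic > 1.0) stop("critic outside [-1, 1]");
  int touched = 0;
  std::vector<double> trans_delta(S->n, 0.0);
  for (int g = 0; g < np; ++g) {
    if (S->tag_expiry[g] < now) continue;
    double sg = s[g];
    double delta = hebbwt * critic * sg;
    if (delta == 0.0) continue;
    int si = S->plastic_idx[g];
    int p = S->pre[si];
    if (use_balance) {
      double cur = S->cur_trans[p], init = S->init_trans[p], b;
      if (delta > 0)       // reward-like change for this synapse
        b = (cur <= 0) ? bal_max : clampd(init / cur, bal_min, bal_max);
      else                 // punishment-like change
        b = (cur <= 0) ? bal_min : clampd(cur / init, bal_min, bal_max);
      delta *= b;
    }
    double old = S->w[si], nw = old + delta;
    if (nw < 0) nw = 0;
    S->w[si] = nw;
    trans_delta[p] += nw - old;
    ++touched;
  }
  for (int i = 0; i < S->n; ++i) S->cur_trans[i] += trans_delta[i];
  return touched;
}

// Rescale every neuron's incoming plastic weights to its reception target.
// [[Rcpp::export]]
void sess_balance_inputs(SEXP sp) {
  XPtr<Session> S(sp);
  for (int i = 0; i < S->n; ++i) {
    const std::vector<int>& inc = S->in_plastic[i];
    if (inc.empty()) continue;
    double cur = 0.0;
    for (size_t j = 0; j < inc.size(); ++j) cur += S->w[inc[j]];
    if (cur <= 0.0) continue;
    double f = S->recept_target[i] / cur;
    for (size_t j = 0; j < inc.size(); ++j) {
      int si = inc[j];
      double old = S->w[si];
      S->w[si] = old * f;
      S->cur_trans[S->pre[si]] += S->w[si] - old;
    }
  }
}

// [[Rcpp::export]]
void sess_scale_reception_targets(SEXP sp, NumericVector factor) {
  XPtr<Session> S(sp);
  if (factor.size() != S->n) stop("factor length mismatch");
  for (int i = 0; i < S->n; ++i) S->recept_target[i] *= factor[i];
}

// [[Rcpp::export]]
NumericVector sess_reception_targets(SEXP sp) {
  XPtr<Session> S(sp);
  return NumericVector(S->recept_target.begin(), S->recept_target.end());
}

// [[Rcpp::export]]
List sess_transmission_totals(SEXP sp) {
  XPtr<Session> S(sp);
  return List::create(
    _["initial"] = NumericVector(S->init_trans.begin(), S->init_trans.end()),
    _["current"] = NumericVector(S->cur_trans.begin(), S->cur_trans.end()));
}

// ---------------------------------------------------------------------------
// Cart-pole dynamics and the frozen-policy episode runner
// ---------------------------------------------------------------------------

struct EnvP {
  double gravity, masscart, masspole, length, force_mag, dt, theta_bound, x_bound;
};

static EnvP env_from_list(List env) {
  EnvP e;
  e.gravity = env["gravity"]; e.masscart = env["mass_cart"];
  e.masspole = env["mass_pole"]; e.length = env["half_length"];
  e.force_mag = env["force_mag"]; e.dt = env["dt"];
  e.theta_bound = env["angle_limit"]; e.x_bound = env["position_limit"];
  return e;
}

static void cp_step(double st[4], int action, const EnvP& e) {
  double force = action == 1 ? e.force_mag : -e.force_mag;  // 1 = RIGHT
  double total_mass = e.masscart + e.masspole;
  double pml = e.masspole * e.length;
  double ct = std::cos(st[2]), sn = std::sin(st[2]);
  double temp = (force + pml * st[3] * st[3] * sn) / total_mass;
  double thetaacc = (e.gravity * sn - ct * temp) /
                    (e.length * (4.0 / 3.0 - e.masspole * ct * ct / total_mass));
  double xacc = temp - pml * thetaacc * ct / total_mass;
  st[0] += e.dt * st[1];
  st[1] += e.dt * xacc;
  st[2] += e.dt * st[3];
  st[3] += e.dt * thetaacc;
}

static inline bool cp_terminated(const double st[4], const EnvP& e) {
  return std::fabs(st[0]) > e.x_bound || std::fabs(st[2]) > e.theta_bound;
}

// findInterval-compatible bin lookup: number of boundaries <= v, in 0..19.
static inline int rf_bin(double v, const double* b) {
  int c = 0;
  while (c < 19 && b[c] <= v) ++c;
  return c;
}

// Run one frozen-weights episode from a given start state. Resets neural
// state and time first; tags are untouched (caller controls tagging flag).
// Returns steps survived plus per-step actions and motor counts.
// [[Rcpp::export]]
List sess_run_episode(SEXP sp, NumericVector state0, NumericMatrix boundaries,
                      List env, int max_steps, double window, double stim_weight,
                      int tie_seed, bool record,
                      NumericVector stim_offsets = NumericVector::create(0.0)) {
  XPtr<Session> S(sp);
  EnvP e = env_from_list(env);
  session_reset_state(*S);
  XRng rng((uint64_t)tie_seed);
  std::vector<double> off(stim_offsets.begin(), stim_offsets.end());
  double st[4] = { state0[0], state0[1], state0[2], state0[3] };
  std::vector<int> stim(4);
  std::vector<int> actions, nl_log, nr_log;
  std::vector<double> states;
  int steps = 0;
  for (int it = 0; it < max_steps; ++it) {
    for (int v = 0; v < 4; ++v)
      stim[v] = v * 20 + rf_bin(st[v], &boundaries(0, v));
    run_window(*S, stim, stim_weight, window, off);
    int nl = 0, nr = 0;
    for (int i = 140; i < 160; ++i) nl += S->win_count[i];
    for (int i = 160; i < 180; ++i) nr += S->win_count[i];
    int action;  // 0 = LEFT, 1 = RIGHT
    if (nl > nr) action = 0;
    else if (nr > nl) action = 1;
    else action = rng.unif() < 0.5 ? 0 : 1;
    if (record) {
      actions.push_back(action); nl_log.push_back(nl); nr_log.push_back(nr);
      for (int v = 0; v < 4; ++v) states.push_back(st[v]);
    }
    cp_step(st, action, e);
    ++steps;
    if (cp_terminated(st, e)) break;
  }
  List out = List::create(_["steps"] = steps);
  if (record) {
    out["actions"] = IntegerVector(actions.begin(), actions.end());
    out["n_left"] = IntegerVector(nl_log.begin(), nl_log.end());
    out["n_right"] = IntegerVector(nr_log.begin(), nr_log.end());
    NumericMatrix sm(4, steps);
    for (int i = 0; i < steps; ++i)
      for (int v = 0; v < 4; ++v) sm(v, i) = states[4 * i + v];
    out["states"] = sm;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cartpole_step_cpp(NumericVector state, int action, List env) {
  EnvP e = env_from_list(env);
  double st[4] = { state[0], state[1], state[2], state[3] };
  cp_step(st, action, e);
  return NumericVector::create(st[0], st[1], st[2], st[3]);
}

// ---------------------------------------------------------------------------
// All-inputs sweep: stimulate sensory combinations interleaved with blanks
// ---------------------------------------------------------------------------

// combos: m x 4 matrix of 0-based bin indices. Returns per-record activity
// flags, motor counts, decoded action (0 L, 1 R), tie flags, and the number
// of residual spikes that leaked into each blank period.
// [[Rcpp::export]]
List sess_sweep(SEXP sp, IntegerMatrix combos, double window, double blank,
                double stim_weight, int tie_seed,
                NumericVector stim_offsets = NumericVector::create(0.0)) {
  XPtr<Session> S(sp);
  int m = combos.nrow();
  session_reset_state(*S);
  XRng rng((uint64_t)tie_seed);
  std::vector<double> off(stim_offsets.begin(), stim_offsets.end());
  std::vector<double> off0(1, 0.0);
  LogicalMatrix active(m, S->n);
  IntegerVector nleft(m), nright(m), action(m), residual(m);
  LogicalVector tie(m);
  std::vector<int> stim(4);
  std::vector<int> none;
  for (int r = 0; r < m; ++r) {
    for (int v = 0; v < 4; ++v) stim[v] = v * 20 + combos(r, v);
    run_window(*S, stim, stim_weight, window, off);
    int nl = 0, nr = 0;
    for (int i = 0; i < S->n; ++i) active(r, i) = S->win_count[i] > 0;
    for (int i = 140; i < 160; ++i) nl += S->win_count[i];
    for (int i = 160; i < 180; ++i) nr += S->win_count[i];
    nleft[r] = nl; nright[r] = nr;
    if (nl > nr) { action[r] = 0; tie[r] = false; }
    else if (nr > nl) { action[r] = 1; tie[r] = false; }
    else { action[r] = rng.unif() < 0.5 ? 0 : 1; tie[r] = true; }
    run_window(*S, none, 0.0, blank, off0);
    int res = 0;
    for (int i = 0; i < S->n; ++i) res += S->win_count[i];
    residual[r] = res;
  }
  return List::create(_["active"] = active, _["n_left"] = nleft,
                      _["n_right"] = nright, _["action"] = action,
                      _["tie"] = tie, _["residual"] = residual);
}

// ---------------------------------------------------------------------------
// Single-neuron trajectories (event-driven path and dense clock oracle)
// ---------------------------------------------------------------------------

static CellP cell_from_vec(NumericVector p) {
  CellP c;
  c.v_rest = p[0]; c.v_thresh = p[1]; c.v_block = p[2]; c.tau_ar = p[3];
  c.w_rr = p[4]; c.tau_rr = p[5]; c.dv_ahp = p[6]; c.tau_ahp = p[7];
  return c;
}

static void chan_from_mat(NumericMatrix m, ChanP* chanp) {
  for (int k = 0; k < N_CHAN; ++k) {
    chanp[k].e_syn = m(k, 0); chanp[k].tau = m(k, 1); chanp[k].sign = m(k, 2);
  }
}

// [[Rcpp::export]]
List neuron_trajectory_event(NumericVector cell, NumericMatrix chan,
                             NumericVector ev_t, IntegerVector ev_chan,
                             NumericVector ev_w) {
  CellP c = cell_from_vec(cell);
  ChanP chanp[N_CHAN];
  chan_from_mat(chan, chanp);
  Neuron nr;
  reset_neuron(nr, c);
  int m = ev_t.size();
  NumericVector vm(m);
  LogicalVector fired(m);
  std::vector<double> spikes;
  for (int i = 0; i < m; ++i) {
    bool f = deliver(nr, c, chanp, ev_chan[i] - 1, ev_w[i], ev_t[i]);
    fired[i] = f;
    if (f) spikes.push_back(ev_t[i]);
    vm[i] = membrane(nr, c, chanp);
  }
  return List::create(_["vm"] = vm, _["fired"] = fired,
                      _["spike_times"] = NumericVector(spikes.begin(), spikes.end()));
}

// Dense clock-driven oracle: exponential relaxation applied tick by tick,
// events delivered at their (tick-aligned) times, fire check at event ticks
// only. Independent code path from the lazy event-driven updates above.
// [[Rcpp::export]]
List neuron_trajectory_clock(NumericVector cell, NumericMatrix chan,
                             NumericVector ev_t, IntegerVector ev_chan,
                             NumericVector ev_w, double dt) {
  CellP c = cell_from_vec(cell);
  ChanP chanp[N_CHAN];
  chan_from_mat(chan, chanp);
  double fsyn[N_CHAN];
  for (int k = 0; k < N_CHAN; ++k) fsyn[k] = std::exp(-dt / chanp[k].tau);
  double fahp = std::exp(-dt / c.tau_ahp);
  double frr = std::exp(-dt / c.tau_rr);
  double vsyn[N_CHAN] = {0, 0, 0, 0};
  double vahp = 0, vthr = c.v_thresh, refr_until = -1e300;
  int m = ev_t.size();
  NumericVector vm_out(m);
  LogicalVector fired(m);
  std::vector<double> spikes;
  long tick = 0;
  for (int i = 0; i < m; ++i) {
    long target = (long)std::floor(ev_t[i] / dt + 0.5);
    for (; tick < target; ++tick) {
      for (int k = 0; k < N_CHAN; ++k) vsyn[k] *= fsyn[k];
      vahp *= fahp;
      vthr = c.v_thresh + (vthr - c.v_thresh) * frr;
    }
    double t = tick * dt;
    double vm = c.v_rest - vahp;
    for (int k = 0; k < N_CHAN; ++k) vm += chanp[k].sign * vsyn[k];
    int ch = ev_chan[i] - 1;
    double dv = ev_w[i] * (1.0 - (vm - c.v_rest) / (chanp[ch].e_syn - c.v_rest));
    vsyn[ch] += dv;
    if (vsyn[ch] < 0) vsyn[ch] = 0;
    vm = c.v_rest - vahp;
    for (int k = 0; k < N_CHAN; ++k) vm += chanp[k].sign * vsyn[k];
    bool f = (vm >= vthr && vm <= c.v_block && t >= refr_until);
    if (f) {
      spikes.push_back(t);
      vahp += c.dv_ahp;
      vthr += c.w_rr * (c.v_block - vthr);
      refr_until = t + c.tau_ar;
      for (int k = 0; k < N_CHAN; ++k) vsyn[k] = 0;
      vm = c.v_rest - vahp;
    }
    fired[i] = f;
    vm_out[i] = vm;
  }
  return List::create(_["vm"] = vm_out, _["fired"] = fired,
                      _["spike_times"] = NumericVector(spikes.begin(), spikes.end()));
}
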