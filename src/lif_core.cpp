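// Clock-driven core for the LIF network with homeostatic structural
// plasticity. All randomness goes through R's RNG so that set.seed()
// makes every run bit-reproducible. Neurons are indexed 0..N_E-1
// (excitatory) and N_E..N-1 (inhibitory). The E->E connectivity matrix A
// is dense integer, A(i, j) = number of synapses from presynaptic j to
// postsynaptic i (columns are axons, rows are dendrites). Static wiring
// (everything involving inhibitory neurons) is a flattened source-major
// adjacency list and never changes.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Fast internal PRNG (xoshiro256++), seeded once per engine call from R's
// RNG so that set.seed() still makes every run bit-reproducible. The inner
// loop draws ~1e10 uniforms for a long run; R's generator is too slow for
// that through its API.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  void seed_from_r() {  // consumes two R uniforms
    uint64_t x = (uint64_t)(unif_rand() * 4294967296.0) << 32;
    x ^= (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // uniform on [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline int below(int n) {  // uniform on 0..n-1
    int k = (int)(unif() * n);
    return (k >= n) ? n - 1 : k;
  }
};

// O(1) Poisson sampler for a fixed mean: alias method (Vose) over the
// probability table truncated where the cumulative mass reaches 1 - 1e-14.
struct PoisSampler {
  double mean = 0.0;
  std::vector<double> prob;   // threshold per bucket
  std::vector<int> alias;
  void init(double m) {
    mean = m;
    prob.clear();
    alias.clear();
    if (m <= 0.0) return;
    std::vector<double> p;
    double pk = std::exp(-m), c = pk;
    p.push_back(pk);
    int kmax = (int)(m + 12.0 * std::sqrt(m) + 30.0);
    for (int k = 1; k <= kmax && c < 1.0 - 1e-14; ++k) {
      pk *= m / k;
      c += pk;
      p.push_back(pk);
    }
    const int n = (int)p.size();
    prob.assign(n, 1.0);
    alias.assign(n, 0);
    std::vector<double> scaled(n);
    std::vector<int> small, large;
    for (int k = 0; k < n; ++k) {
      scaled[k] = p[k] / c * n;
      (scaled[k] < 1.0 ? small : large).push_back(k);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = (scaled[l] + scaled[s]) - 1.0;
      (scaled[l] < 1.0 ? small : large).push_back(l);
    }
  }
  inline int draw(Xoshiro& rng) const {
    if (mean <= 0.0) return 0;
    const int n = (int)prob.size();
    double u = rng.unif() * n;
    int k = (int)u;
    if (k >= n) k = n - 1;
    return (u - k) < prob[k] ? k : alias[k];
  }
};

// One structural-plasticity bookkeeping unit. Presynaptic elements
// (boutons) of neuron j are bound in column j of A; postsynaptic elements
// (spines) of neuron i are bound in row i.
struct Plasticity {
  int NE;
  double nu, eps, tau_ca, beta_ca;  // growth rate [1/s], set point, decay [s], increment
  std::vector<double> C, z_pre, z_post;
  std::vector<int> free_pre, free_post, bound_pre, bound_post;
  bool clamped = false;  // a deficit exhausted both free and bound elements

  void init_from(IntegerMatrix A, NumericVector C0, NumericVector zpre,
                 NumericVector zpost, IntegerVector fpre, IntegerVector fpost) {
    NE = A.nrow();
    C.assign(C0.begin(), C0.end());
    z_pre.assign(zpre.begin(), zpre.end());
    z_post.assign(zpost.begin(), zpost.end());
    free_pre.assign(fpre.begin(), fpre.end());
    free_post.assign(fpost.begin(), fpost.end());
    bound_pre.assign(NE, 0);
    bound_post.assign(NE, 0);
    for (int j = 0; j < NE; ++j)
      for (int i = 0; i < NE; ++i) {
        int c = A(i, j);
        if (c > 0) {
          bound_pre[j] += c;
          bound_post[i] += c;
        }
      }
  }
};

struct BlockSums {
  int G;  // number of excitatory groups (>= 1)
  std::vector<double> sums;        // G x G, [tgt * G + src]
  std::vector<int> gsize;          // per group
  std::vector<int> memb;           // 0-based group per E neuron
  void init(IntegerVector membership, int NE, int G_, IntegerMatrix A) {
    G = G_;
    memb.assign(membership.begin(), membership.begin() + NE);
    gsize.assign(G, 0);
    for (int i = 0; i < NE; ++i) gsize[memb[i]]++;
    sums.assign(G * G, 0.0);
    for (int j = 0; j < NE; ++j)
      for (int i = 0; i < NE; ++i)
        if (A(i, j) > 0) sums[memb[i] * G + memb[j]] += A(i, j);
  }
  inline void add(int post, int pre, int k) { sums[memb[post] * G + memb[pre]] += k; }
};

void delete_bound_pre(IntegerMatrix A, Plasticity& P, BlockSums& B, int j,
                      Xoshiro& rng) {
  // break one synapse of presynaptic neuron j, chosen uniformly among its
  // bound boutons; the partner's spine returns to the free pool
  int r = rng.below(P.bound_pre[j]);
  int acc = 0;
  for (int i = 0; i < P.NE; ++i) {
    int c = A(i, j);
    if (c == 0) continue;
    acc += c;
    if (r < acc) {
      A(i, j) = c - 1;
      P.bound_pre[j]--;
      P.bound_post[i]--;
      P.free_post[i]++;
      B.add(i, j, -1);
      return;
    }
  }
}

void delete_bound_post(IntegerMatrix A, Plasticity& P, BlockSums& B, int i,
                       Xoshiro& rng) {
  int r = rng.below(P.bound_post[i]);
  int acc = 0;
  for (int j = 0; j < P.NE; ++j) {
    int c = A(i, j);
    if (c == 0) continue;
    acc += c;
    if (r < acc) {
      A(i, j) = c - 1;
      P.bound_post[i]--;
      P.bound_pre[j]--;
      P.free_pre[j]++;
      B.add(i, j, -1);
      return;
    }
  }
}

// Reconcile integer element counts with the continuous counter z for one
// element kind: surplus integers become free elements, deficits consume
// free elements first and then break bound synapses.
void settle_elements(IntegerMatrix A, Plasticity& P, BlockSums& B,
                     bool pre_kind, Xoshiro& rng) {
  std::vector<double>& z = pre_kind ? P.z_pre : P.z_post;
  std::vector<int>& fre = pre_kind ? P.free_pre : P.free_post;
  std::vector<int>& bnd = pre_kind ? P.bound_pre : P.bound_post;
  for (int n = 0; n < P.NE; ++n) {
    if (z[n] < 0.0) z[n] = 0.0;
    int avail = (int)std::floor(z[n]);
    int held = fre[n] + bnd[n];
    if (avail > held) {
      fre[n] += avail - held;
    } else if (avail < held) {
      int need = held - avail;
      int take = need < fre[n] ? need : fre[n];
      fre[n] -= take;
      need -= take;
      while (need > 0 && bnd[n] > 0) {
        if (pre_kind)
          delete_bound_pre(A, P, B, n, rng);
        else
          delete_bound_post(A, P, B, n, rng);
        need--;
      }
      if (need > 0) {  // runaway: nothing left to remove
        P.clamped = true;
        z[n] = 0.0;
      }
    }
  }
}

// Randomly combine free boutons with free spines of other neurons into new
// synapses: one shuffled pass, min(total free_pre, total free_post)
// attempted pairings, self-pairings re-drawn a bounded number of times.
void pair_free(IntegerMatrix A, Plasticity& P, BlockSums& B, Xoshiro& rng) {
  std::vector<int> pre_own, post_own;
  for (int n = 0; n < P.NE; ++n) {
    for (int k = 0; k < P.free_pre[n]; ++k) pre_own.push_back(n);
    for (int k = 0; k < P.free_post[n]; ++k) post_own.push_back(n);
  }
  int attempts = (int)std::min(pre_own.size(), post_own.size());
  int stuck = 0;
  for (int t = 0; t < attempts && stuck < 20; ++t) {
    int a = rng.below((int)pre_own.size());
    int b = rng.below((int)post_own.size());
    int tries = 0;
    while (pre_own[a] == post_own[b] && tries < 10) {
      b = rng.below((int)post_own.size());
      a = rng.below((int)pre_own.size());
      tries++;
    }
    if (pre_own[a] == post_own[b]) {  // only self-pairs reachable
      stuck++;
      continue;
    }
    stuck = 0;
    int j = pre_own[a], i = post_own[b];
    A(i, j)++;
    P.bound_pre[j]++;
    P.bound_post[i]++;
    P.free_pre[j]--;
    P.free_post[i]--;
    B.add(i, j, +1);
    pre_own[a] = pre_own.back();
    pre_own.pop_back();
    post_own[b] = post_own.back();
    post_own.pop_back();
  }
}

}  // namespace

//' @useDynLib tdcsnet, .registration = TRUE
//' @importFrom Rcpp evalCpp
// [[Rcpp::export]]
List cpp_run_phase(List state, List cfg, List sched, List rec) {
  // --- configuration ---------------------------------------------------
  const int NE = as<int>(cfg["n_e"]), NI = as<int>(cfg["n_i"]);
  const int N = NE + NI;
  const double dt = as<double>(cfg["dt_ms"]);          // ms
  const double tau_m = as<double>(cfg["tau_m"]);       // ms
  const int tref_steps = as<int>(cfg["t_ref_steps"]);
  const double V_th = as<double>(cfg["v_th"]), V_reset = as<double>(cfg["v_reset"]);
  const double J_E = as<double>(cfg["j_e"]), J_I = as<double>(cfg["j_i"]);
  const double J_ext = as<double>(cfg["j_ext"]);
  const double r_ext = as<double>(cfg["r_ext"]);       // Hz per neuron
  const int d_steps = as<int>(cfg["delay_steps"]);
  const bool threshold_on = as<bool>(cfg["threshold_on"]);
  const bool plastic = as<bool>(cfg["plastic"]);
  const double nu = as<double>(cfg["nu"]);             // elements / s
  const double eps = as<double>(cfg["eps"]);
  const double tau_ca = as<double>(cfg["tau_ca"]);     // s
  const double beta_ca = as<double>(cfg["beta_ca"]);
  const int struct_steps = as<int>(cfg["struct_steps"]);
  const double ceiling_hz = as<double>(cfg["rate_ceiling"]);
  const int ceiling_sustain = as<int>(cfg["ceiling_sustain"]);  // seconds

  IntegerVector static_ptr = cfg["static_ptr"];  // length N + 1, 0-based
  IntegerVector static_tgt = cfg["static_tgt"];

  const double duration_s = as<double>(cfg["duration_s"]);
  const long n_steps = (long)std::llround(duration_s * 1000.0 / dt);
  const double alpha = std::exp(-dt / tau_m);
  const double ca_decay = std::exp(-(struct_steps * dt / 1000.0) / tau_ca);
  const double dz = nu * (struct_steps * dt / 1000.0);

  // --- schedule ---------------------------------------------------------
  NumericVector bp_time = sched["times"];        // s, ascending, bp_time[0] == 0
  NumericMatrix bp_vals = sched["values"];       // intervals x groups, mV
  IntegerVector membership = sched["membership"]; // per neuron, 0-based group, -1 none
  const int G = bp_vals.ncol() > 0 ? bp_vals.ncol() : 1;

  // --- mutable state ----------------------------------------------------
  NumericVector V = clone(as<NumericVector>(state["v"]));
  IntegerVector refr = clone(as<IntegerVector>(state["refr"]));
  NumericMatrix buf = clone(as<NumericMatrix>(state["buffer"]));  // N x d_steps
  int slot = as<int>(state["slot"]);
  IntegerMatrix A = clone(as<IntegerMatrix>(state["a"]));

  Plasticity P;
  P.nu = nu; P.eps = eps; P.tau_ca = tau_ca; P.beta_ca = beta_ca;
  P.init_from(A, state["calcium"], state["z_pre"], state["z_post"],
              state["free_pre"], state["free_post"]);

  BlockSums B;
  B.init(membership, NE, G, A);

  // --- recording --------------------------------------------------------
  const double window_s = as<double>(rec["window_s"]);
  const double trace_every_s = as<double>(rec["trace_every_s"]);
  const bool record_spikes = as<bool>(rec["record_spikes"]);
  const bool record_v = as<bool>(rec["record_v"]);
  const long window_steps = (long)std::llround(window_s * 1000.0 / dt);
  const long trace_steps = (long)std::llround(trace_every_s * 1000.0 / dt);
  const int n_windows = (int)(n_steps / window_steps);
  IntegerMatrix win_counts(N, n_windows > 0 ? n_windows : 1);
  std::vector<double> tr_time;
  std::vector<std::vector<double>> tr_blocks(G * G);
  std::vector<double> tr_total, tr_ca, tr_z;
  std::vector<int> spike_id;
  std::vector<double> spike_t;
  double v_sum = 0.0;
  long v_n = 0;

  // runaway guard bookkeeping (per simulated second)
  const long sec_steps = (long)std::llround(1000.0 / dt);
  long sec_count = 0;
  int hot_seconds = 0;
  bool aborted = false;

  std::vector<int> spike_acc(NE, 0);  // spikes since last structural update
  int steps_mod_struct = as<int>(state["steps_mod_struct"]);

  PoisSampler pois;
  pois.init(r_ext * dt / 1000.0);
  Xoshiro rng;

  // per-neuron polarization bias, rebuilt at schedule breakpoints
  std::vector<double> bias(N, 0.0);
  int interval = -1;

  std::vector<int> spiked;
  spiked.reserve(256);

  GetRNGstate();
  rng.seed_from_r();
  PutRNGstate();
  for (long step = 0; step < n_steps; ++step) {
    const double t_s = step * dt / 1000.0;
    // advance schedule
    int iv = interval < 0 ? 0 : interval;
    while (iv + 1 < bp_time.size() && bp_time[iv + 1] <= t_s + 1e-12) ++iv;
    if (iv != interval) {
      interval = iv;
      for (int i = 0; i < N; ++i) {
        int g = membership[i];
        bias[i] = (g >= 0) ? bp_vals(interval, g) : 0.0;
      }
    }

    // deliver this slot's delayed input, then clear it for reuse
    // (buffer stored N x d_steps: column `slot` is contiguous)
    double* in = &buf(0, slot);
    spiked.clear();
    for (int i = 0; i < N; ++i) {
      double syn = in[i];
      in[i] = 0.0;
      if (refr[i] > 0) {  // refractory: clamp, discard input
        refr[i]--;
        V[i] = V_reset;
        continue;
      }
      double v = bias[i] + (V[i] - bias[i]) * alpha;  // exact decay to bias
      v += syn + J_ext * pois.draw(rng);
      if (threshold_on && v >= V_th) {
        spiked.push_back(i);
        v = V_reset;
        refr[i] = tref_steps;
      }
      V[i] = v;
    }

    if (record_v) {
      for (int i = 0; i < N; ++i) v_sum += V[i];
      v_n += N;
    }

    // propagate spikes into the buffer slot d_steps ahead (== same slot,
    // which is read again exactly d_steps from now)
    if (!spiked.empty()) {
      const int wslot = (slot + d_steps) % d_steps;  // = slot
      double* out = &buf(0, wslot);
      const int wi = step / window_steps < n_windows ? (int)(step / window_steps) : -1;
      for (int s : spiked) {
        if (wi >= 0) win_counts(s, wi)++;
        if (record_spikes) {
          spike_id.push_back(s + 1);  // 1-based for R
          spike_t.push_back((step + 1) * dt);
        }
        if (s < NE) {
          spike_acc[s]++;
          sec_count++;
          // E -> E through the plastic matrix (column walk)
          const int* col = &A(0, s);
          for (int i = 0; i < NE; ++i) {
            int c = col[i];
            if (c) out[i] += J_E * c;
          }
          // static E -> I
          for (int k = static_ptr[s]; k < static_ptr[s + 1]; ++k)
            out[static_tgt[k]] += J_E;
        } else {
          for (int k = static_ptr[s]; k < static_ptr[s + 1]; ++k)
            out[static_tgt[k]] += J_I;
        }
      }
    }
    slot = (slot + 1) % d_steps;

    // structural plasticity at its own cadence
    if (plastic && ++steps_mod_struct >= struct_steps) {
      steps_mod_struct = 0;
      for (int n = 0; n < NE; ++n) {
        P.C[n] = P.C[n] * ca_decay + beta_ca * spike_acc[n];
        spike_acc[n] = 0;
        double g = dz * (1.0 - P.C[n] / eps);
        P.z_pre[n] += g;
        P.z_post[n] += g;
      }
      settle_elements(A, P, B, true, rng);
      settle_elements(A, P, B, false, rng);
      pair_free(A, P, B, rng);
    } else if (!plastic && steps_mod_struct >= 0) {
      // keep calcium traces current even when rewiring is frozen
      if (++steps_mod_struct >= struct_steps) {
        steps_mod_struct = 0;
        for (int n = 0; n < NE; ++n) {
          P.C[n] = P.C[n] * ca_decay + beta_ca * spike_acc[n];
          spike_acc[n] = 0;
        }
      }
    }

    // connectivity trace
    if (trace_steps > 0 && (step + 1) % trace_steps == 0) {
      tr_time.push_back((step + 1) * dt / 1000.0);
      double tot = 0.0, mc = 0.0, mz = 0.0;
      for (int g = 0; g < G * G; ++g) tot += B.sums[g];
      for (int th = 0; th < G; ++th)
        for (int sg = 0; sg < G; ++sg)
          tr_blocks[th * G + sg].push_back(
              B.sums[th * G + sg] / ((double)B.gsize[th] * B.gsize[sg]));
      tr_total.push_back(tot / ((double)NE * NE));
      for (int n = 0; n < NE; ++n) { mc += P.C[n]; mz += P.z_pre[n]; }
      tr_ca.push_back(mc / NE);
      tr_z.push_back(mz / NE);
    }

    // runaway guard: sustained population rate above ceiling
    if ((step + 1) % sec_steps == 0) {
      double rate = (double)sec_count / NE;  // Hz over the past second
      sec_count = 0;
      hot_seconds = (ceiling_hz > 0 && rate > ceiling_hz) ? hot_seconds + 1 : 0;
      if (ceiling_hz > 0 && hot_seconds >= ceiling_sustain) {
        aborted = true;
        break;
      }
    }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  // --- pack results -----------------------------------------------------
  List out_state = List::create(
      _["v"] = V, _["refr"] = refr, _["buffer"] = buf, _["slot"] = slot,
      _["a"] = A,
      _["calcium"] = NumericVector(P.C.begin(), P.C.end()),
      _["z_pre"] = NumericVector(P.z_pre.begin(), P.z_pre.end()),
      _["z_post"] = NumericVector(P.z_post.begin(), P.z_post.end()),
      _["free_pre"] = IntegerVector(P.free_pre.begin(), P.free_pre.end()),
      _["free_post"] = IntegerVector(P.free_post.begin(), P.free_post.end()),
      _["steps_mod_struct"] = steps_mod_struct);

  int n_tr = (int)tr_time.size();
  NumericMatrix blocks(n_tr, G * G);
  for (int g = 0; g < G * G; ++g)
    for (int r = 0; r < n_tr; ++r) blocks(r, g) = tr_blocks[g][r];

  return List::create(
      _["state"] = out_state,
      _["window_counts"] = win_counts,
      _["trace_time"] = NumericVector(tr_time.begin(), tr_time.end()),
      _["trace_blocks"] = blocks,
      _["trace_total"] = NumericVector(tr_total.begin(), tr_total.end()),
      _["trace_calcium"] = NumericVector(tr_ca.begin(), tr_ca.end()),
      _["trace_z"] = NumericVector(tr_z.begin(), tr_z.end()),
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["spike_t_ms"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["mean_v"] = v_n > 0 ? v_sum / v_n : NA_REAL,
      _["bound_pre"] = IntegerVector(P.bound_pre.begin(), P.bound_pre.end()),
      _["bound_post"] = IntegerVector(P.bound_post.begin(), P.bound_post.end()),
      _["clamped"] = P.clamped,
      _["aborted"] = aborted);
}

// Single LIF neuron under Poisson background with a constant membrane
// polarization bias; used for the tDCS dose-response experiments.
// [[Rcpp::export]]
List cpp_single_neuron(double duration_s, double rate_hz, double j_ext,
                       double bias_mv, double tau_m, double t_ref_ms,
                       double v_th, double v_reset, double dt_ms,
                       bool threshold_on, bool record_spikes) {
  const long n_steps = (long)std::llround(duration_s * 1000.0 / dt_ms);
  const double alpha = std::exp(-dt_ms / tau_m);
  const int tref_steps = (int)std::llround(t_ref_ms / dt_ms);
  PoisSampler pois;
  pois.init(rate_hz * dt_ms / 1000.0);
  double V = 0.0, v_sum = 0.0;
  int refr = 0;
  long n_spikes = 0;
  std::vector<double> st;
  Xoshiro rng;
  GetRNGstate();
  rng.seed_from_r();
  PutRNGstate();
  for (long step = 0; step < n_steps; ++step) {
    if (refr > 0) {
      refr--;
      V = v_reset;
    } else {
      V = bias_mv + (V - bias_mv) * alpha + j_ext * pois.draw(rng);
      if (threshold_on && V >= v_th) {
        n_spikes++;
        if (record_spikes) st.push_back((step + 1) * dt_ms);
        V = v_reset;
        refr = tref_steps;
      }
    }
    v_sum += V;
  }
  return List::create(_["n_spikes"] = (double)n_spikes,
                      _["rate"] = n_spikes / duration_s,
                      _["mean_v"] = v_sum / n_steps,
                      _["spike_t_ms"] = NumericVector(st.begin(), st.end()));
}
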