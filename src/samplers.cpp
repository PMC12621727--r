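// Discrete MCMC cores for Potts sequence models: systematic-scan Gibbs and
// Discrete Langevin Monte Carlo (factorized locally-informed categorical
// proposals with optional Metropolis-Hastings correction), both with an
// optional local-composition-perplexity (LCP) restraint. Sequences are
// 0-based here; R wrappers convert. All randomness comes from R's RNG so
// chains are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Incidence {
  int edge;
  int other;
  bool first; // site is the smaller-index endpoint of the edge
};

struct PottsC {
  int L, A;
  NumericMatrix h;
  IntegerMatrix edges; // m x 2, 0-based, i < j
  std::vector<NumericMatrix> J;
  std::vector<std::vector<Incidence>> inc;

  PottsC(NumericMatrix h_, IntegerMatrix edges_, List J_)
      : L(h_.nrow()), A(h_.ncol()), h(h_), edges(edges_) {
    int m = edges.nrow();
    J.reserve(m);
    for (int k = 0; k < m; ++k) J.push_back(as<NumericMatrix>(J_[k]));
    inc.resize(L);
    for (int k = 0; k < m; ++k) {
      int i = edges(k, 0), j = edges(k, 1);
      inc[i].push_back({k, j, true});
      inc[j].push_back({k, i, false});
    }
  }

  // h[site, a] + coupling contributions of residue a at `site` vs state s
  void local_energies(const std::vector<int>& s, int site,
                      std::vector<double>& out) const {
    for (int a = 0; a < A; ++a) out[a] = h(site, a);
    for (const Incidence& e : inc[site]) {
      const NumericMatrix& blk = J[e.edge];
      int o = s[e.other];
      if (e.first) {
        for (int a = 0; a < A; ++a) out[a] += blk(a, o);
      } else {
        for (int a = 0; a < A; ++a) out[a] += blk(o, a);
      }
    }
  }

  double total_energy(const std::vector<int>& s) const {
    double e = 0.0;
    for (int i = 0; i < L; ++i) e += h(i, s[i]);
    for (int k = 0; k < edges.nrow(); ++k) {
      e += J[k](s[edges(k, 0)], s[edges(k, 1)]);
    }
    return e;
  }
};

// Local composition perplexity restraint over sliding windows.
struct LcpC {
  bool enabled;
  int w;
  double pmin, lambda, pc;
  int L, A, nw;
  std::vector<std::vector<int>> counts; // nw x A
  std::vector<double> pen;              // per-window penalty

  LcpC(bool enabled_, int w_, double pmin_, double lambda_, double pc_,
       int L_, int A_)
      : enabled(enabled_), w(w_), pmin(pmin_), lambda(lambda_), pc(pc_),
        L(L_), A(A_), nw(enabled_ ? L_ - w_ + 1 : 0) {}

  double window_penalty(const std::vector<int>& cnt) const {
    double tot = w + A * pc;
    double H = 0.0;
    for (int a = 0; a < A; ++a) {
      double p = (cnt[a] + pc) / tot;
      if (p > 0) H -= p * std::log(p);
    }
    double gap = pmin - std::exp(H);
    return gap > 0 ? gap * gap : 0.0;
  }

  void init(const std::vector<int>& s) {
    if (!enabled) return;
    counts.assign(nw, std::vector<int>(A, 0));
    pen.assign(nw, 0.0);
    for (int win = 0; win < nw; ++win) {
      for (int p = win; p < win + w; ++p) counts[win][s[p]]++;
      pen[win] = window_penalty(counts[win]);
    }
  }

  double total() const {
    double t = 0.0;
    for (int win = 0; win < nw; ++win) t += pen[win];
    return t;
  }

  // penalty change (unweighted) from substituting residue a at `site`
  double delta(int site, int cur, int a) {
    if (!enabled || a == cur) return 0.0;
    int lo = std::max(0, site - w + 1), hi = std::min(site, nw - 1);
    double d = 0.0;
    for (int win = lo; win <= hi; ++win) {
      counts[win][cur]--; counts[win][a]++;
      d += window_penalty(counts[win]) - pen[win];
      counts[win][cur]++; counts[win][a]--;
    }
    return d;
  }

  void commit(int site, int cur, int a) {
    if (!enabled || a == cur) return;
    int lo = std::max(0, site - w + 1), hi = std::min(site, nw - 1);
    for (int win = lo; win <= hi; ++win) {
      counts[win][cur]--; counts[win][a]++;
      pen[win] = window_penalty(counts[win]);
    }
  }
};

int sample_categorical(const std::vector<double>& logp) {
  // Gumbel-free inverse-CDF sampling on normalized probabilities
  int n = logp.size();
  double mx = logp[0];
  for (int i = 1; i < n; ++i) mx = std::max(mx, logp[i]);
  double z = 0.0;
  std::vector<double> p(n);
  for (int i = 0; i < n; ++i) { p[i] = std::exp(logp[i] - mx); z += p[i]; }
  double u = unif_rand() * z, acc = 0.0;
  for (int i = 0; i < n; ++i) {
    acc += p[i];
    if (u <= acc) return i;
  }
  return n - 1;
}

double log_softmax_norm(const std::vector<double>& l) {
  double mx = l[0];
  for (size_t i = 1; i < l.size(); ++i) mx = std::max(mx, l[i]);
  double z = 0.0;
  for (size_t i = 0; i < l.size(); ++i) z += std::exp(l[i] - mx);
  return mx + std::log(z);
}

} // namespace

// [[Rcpp::export]]
List cpp_gibbs_chain(NumericMatrix h, IntegerMatrix edges, List J,
                     IntegerVector init, int n_record, int burn_in,
                     int thinning, NumericVector temps, bool lcp_enabled,
                     int lcp_w, double lcp_pmin, double lcp_lambda,
                     double lcp_pc) {
  PottsC model(h, edges, J);
  int L = model.L, A = model.A;
  std::vector<int> s(init.begin(), init.end());
  LcpC lcp(lcp_enabled, lcp_w, lcp_pmin, lcp_lambda, lcp_pc, L, A);
  lcp.init(s);

  int total_sweeps = burn_in + n_record * thinning;
  IntegerMatrix samples(n_record, L);
  NumericVector energy(n_record);
  std::vector<double> loc(A), logp(A);
  std::vector<int> perm(L);
  int rec = 0;

  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    double T = temps[sweep];
    // seeded random scan order per sweep (Fisher-Yates on R's RNG)
    for (int i = 0; i < L; ++i) perm[i] = i;
    for (int i = L - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int t = 0; t < L; ++t) {
      int site = perm[t];
      model.local_energies(s, site, loc);
      for (int a = 0; a < A; ++a) {
        double comp = loc[a];
        if (lcp.enabled) comp += lcp.lambda * lcp.delta(site, s[site], a);
        logp[a] = -comp / T;
      }
      int a_new = sample_categorical(logp);
      if (a_new != s[site]) {
        lcp.commit(site, s[site], a_new);
        s[site] = a_new;
      }
    }
    if (sweep >= burn_in && (sweep - burn_in + 1) % thinning == 0) {
      for (int i = 0; i < L; ++i) samples(rec, i) = s[i];
      energy[rec] = model.total_energy(s) + lcp.lambda * lcp.total();
      ++rec;
    }
  }
  return List::create(_["samples"] = samples, _["energy"] = energy,
                      _["acceptance_rate"] = 1.0);
}

// [[Rcpp::export]]
List cpp_dlmc_chain(NumericMatrix h, IntegerMatrix edges, List J,
                    IntegerVector init, int n_record, int burn_in,
                    int thinning, NumericVector temps, double step_size,
                    bool mh_correction, bool lcp_enabled, int lcp_w,
                    double lcp_pmin, double lcp_lambda, double lcp_pc) {
  PottsC model(h, edges, J);
  int L = model.L, A = model.A;
  std::vector<int> s(init.begin(), init.end());
  LcpC lcp(lcp_enabled, lcp_w, lcp_pmin, lcp_lambda, lcp_pc, L, A);
  lcp.init(s);

  int total_steps = burn_in + n_record * thinning;
  IntegerMatrix samples(n_record, L);
  NumericVector energy(n_record);
  std::vector<double> loc(A);
  std::vector<std::vector<double>> logits(L, std::vector<double>(A));
  std::vector<int> prop(L);
  int rec = 0;
  long accepted = 0;
  double lazy = 1.0 / (2.0 * step_size);

  // proposal logits at state s: -(Delta_i(a))/(2T) - 1[a != s_i]/(2*step)
  auto fill_logits = [&](const std::vector<int>& state, double T) {
    for (int i = 0; i < L; ++i) {
      model.local_energies(state, i, loc);
      double cur = loc[state[i]];
      for (int a = 0; a < A; ++a) {
        double d = loc[a] - cur;
        if (lcp.enabled) d += lcp.lambda * lcp.delta(i, state[i], a);
        logits[i][a] = -d / (2.0 * T) - (a == state[i] ? 0.0 : lazy);
      }
    }
  };

  for (int step = 0; step < total_steps; ++step) {
    double T = temps[step];
    fill_logits(s, T);
    double log_q_fwd = 0.0;
    for (int i = 0; i < L; ++i) {
      prop[i] = sample_categorical(logits[i]);
      log_q_fwd += logits[i][prop[i]] - log_softmax_norm(logits[i]);
    }
    bool accept = true;
    if (mh_correction) {
      double e_cur = model.total_energy(s) + lcp.lambda * lcp.total();
      // move LCP state to the proposal to evaluate the reverse kernel
      std::vector<int> s_old = s;
      for (int i = 0; i < L; ++i) {
        if (prop[i] != s[i]) { lcp.commit(i, s[i], prop[i]); s[i] = prop[i]; }
      }
      double e_prop = model.total_energy(s) + lcp.lambda * lcp.total();
      fill_logits(s, T);
      double log_q_rev = 0.0;
      for (int i = 0; i < L; ++i) {
        log_q_rev += logits[i][s_old[i]] - log_softmax_norm(logits[i]);
      }
      double log_alpha = -(e_prop - e_cur) / T + log_q_rev - log_q_fwd;
      if (std::log(unif_rand()) < log_alpha) {
        accept = true; // s already holds the proposal
      } else {
        accept = false;
        for (int i = 0; i < L; ++i) {
          if (s[i] != s_old[i]) { lcp.commit(i, s[i], s_old[i]); s[i] = s_old[i]; }
        }
      }
    } else {
      for (int i = 0; i < L; ++i) {
        if (prop[i] != s[i]) { lcp.commit(i, s[i], prop[i]); s[i] = prop[i]; }
      }
    }
    if (accept) ++accepted;
    if (step >= burn_in && (step - burn_in + 1) % thinning == 0) {
      for (int i = 0; i < L; ++i) samples(rec, i) = s[i];
      energy[rec] = model.total_energy(s) + lcp.lambda * lcp.total();
      ++rec;
    }
  }
  return List::create(_["samples"] = samples, _["energy"] = energy,
                      _["acceptance_rate"] = (double)accepted / total_steps);
}
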