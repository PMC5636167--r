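// Hot loops of the simulator: the 600-step epoch dynamics of the full
// spiking network, a single-neuron trajectory used to cross-check the R
// reference implementation, and the exhaustive 5-move-lookahead search of
// the heuristic baseline agent. All randomness is drawn from a locally
// seeded Mersenne Twister so runs are reproducible independent of platform.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline double unif01(std::mt19937 &rng) {
  // uniform in (0, 1), identical across platforms
  return (static_cast<double>(rng()) + 0.5) * (1.0 / 4294967296.0);
}

// One update of the fast map. Branch 2 (the spike peak) requires the
// previous membrane value to be non-positive so each spike yields exactly
// one peak before the reset branch takes over.
static inline double fast_map(double v, double vprev, double drive,
                              double alpha, bool &spiked) {
  if (v <= 0.0) {
    spiked = false;
    return alpha / (1.0 - v) - 1.0 + drive;
  }
  if (v < alpha + drive && vprev <= 0.0) {
    spiked = true;
    return alpha + drive;
  }
  spiked = false;
  return -1.0;
}

// [[Rcpp::export]]
List epoch_dynamics_cpp(NumericVector v0, NumericVector vprev0,
                        NumericVector islow0, NumericVector gexc0,
                        NumericVector ginh0, IntegerVector stim,
                        int n_in, int n_hid, int n_out,
                        IntegerVector in_ptr, IntegerVector in_tgt,
                        NumericVector in_w, NumericVector in_wbar,
                        NumericMatrix w_out, NumericMatrix wbar_out,
                        double alpha, double mu, double sigma, double beta_e,
                        double sigma_e, double gamma, double noise_R,
                        double vrp_e, double vrp_i,
                        bool inh_in, bool inh_out, int inh_delay,
                        int steps, int half_steps,
                        double pulse, int pulse_steps, int seed) {
  const int n = n_in + n_hid + n_out;
  NumericVector v = clone(v0), vprev = clone(vprev0), islow = clone(islow0);
  NumericVector gexc = clone(gexc0), ginh = clone(ginh0);
  std::vector<char> stimflag(n_in, 0);
  for (int k = 0; k < stim.size(); ++k) stimflag[stim[k] - 1] = 1;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  // ring buffer of pending (delayed, disynaptic) inhibitory increments
  const int D = inh_delay + 1;
  std::vector<double> inh_pending(static_cast<size_t>(D) * n, 0.0);

  std::vector<int> spike_cell, spike_step, spikers;
  spike_cell.reserve(256);
  spike_step.reserve(256);
  IntegerVector counts(n);
  IntegerVector half_out(n_out);

  double *pv = REAL(v), *pvp = REAL(vprev), *pis = REAL(islow);
  double *pge = REAL(gexc), *pgi = REAL(ginh);
  int *pcounts = INTEGER(counts);

  for (int t = 0; t < steps; ++t) {
    spikers.clear();
    for (int j = 0; j < n; ++j) {
      double iext = 0.0;
      if (j < n_in) {
        if (t < pulse_steps && stimflag[j]) iext += pulse;
      } else {
        double ge = pge[j], gi = pgi[j];
        if (ge != 0.0) iext -= ge * (pv[j] - vrp_e);
        if (gi != 0.0) iext -= gi * (pv[j] - vrp_i);
      }
      double drive = pis[j] + beta_e * iext;
      bool spk;
      double vnew = fast_map(pv[j], pvp[j], drive, alpha, spk);
      pis[j] += -mu * (vnew + 1.0) + mu * sigma + mu * sigma_e * iext;
      pvp[j] = pv[j];
      pv[j] = vnew;
      if (spk) {
        spikers.push_back(j);
        spike_cell.push_back(j + 1);
        spike_step.push_back(t);
        pcounts[j]++;
        if (j >= n_in + n_hid && t < half_steps) half_out[j - n_in - n_hid]++;
      }
    }
    // conductance relaxation, then delivery of this step's spikes (a spike
    // at step t first drives its targets at step t + 1; inhibition is
    // disynaptic and arrives inh_delay steps after the excitation)
    double *pend = &inh_pending[static_cast<size_t>(t % D) * n];
    for (int j = n_in; j < n; ++j) {
      pge[j] *= gamma;
      pgi[j] = pgi[j] * gamma + pend[j];
      pend[j] = 0.0;
      // flush decayed conductances to zero before they reach the denormal
      // range (denormal arithmetic is pathologically slow on x86)
      if (pge[j] < 1e-30) pge[j] = 0.0;
      if (pgi[j] < 1e-30) pgi[j] = 0.0;
    }
    double *late = &inh_pending[static_cast<size_t>((t + inh_delay) % D) * n];
    for (size_t s = 0; s < spikers.size(); ++s) {
      int j = spikers[s];
      if (j < n_in) {
        for (int e = in_ptr[j]; e < in_ptr[j + 1]; ++e) {
          int h = n_in + in_tgt[e] - 1;
          double x = 2.0 * unif01(rng) - 1.0;
          pge[h] += (1.0 + x * noise_R) * in_w[e];
          if (inh_in) {
            double x2 = 2.0 * unif01(rng) - 1.0;
            double inc = (1.0 + x2 * noise_R) * in_wbar[e];
            if (inh_delay == 0) pgi[h] += inc; else late[h] += inc;
          }
        }
      } else if (j < n_in + n_hid) {
        int hi = j - n_in;
        for (int o = 0; o < n_out; ++o) {
          int oj = n_in + n_hid + o;
          double x = 2.0 * unif01(rng) - 1.0;
          pge[oj] += (1.0 + x * noise_R) * w_out(hi, o);
          if (inh_out) {
            double x2 = 2.0 * unif01(rng) - 1.0;
            double inc = (1.0 + x2 * noise_R) * wbar_out(hi, o);
            if (inh_delay == 0) pgi[oj] += inc; else late[oj] += inc;
          }
        }
      }
    }
  }
  return List::create(
      _["spike_cell"] = wrap(spike_cell), _["spike_step"] = wrap(spike_step),
      _["counts"] = counts, _["half_out"] = half_out, _["v"] = v,
      _["v_prev"] = vprev, _["i_slow"] = islow, _["g_exc"] = gexc,
      _["g_inh"] = ginh);
}

// Single-neuron trajectory under a prescribed external current, for
// cross-checking the compiled map against the plain-R reference.
// [[Rcpp::export]]
List rulkov_path_cpp(double v0, double vprev0, double islow0,
                     NumericVector i_ext, double alpha, double mu,
                     double sigma, double beta_e, double sigma_e) {
  int nsteps = i_ext.size();
  NumericVector v(nsteps);
  std::vector<int> spikes;
  double vv = v0, vp = vprev0, is = islow0;
  for (int t = 0; t < nsteps; ++t) {
    double drive = is + beta_e * i_ext[t];
    bool spk;
    double vnew = fast_map(vv, vp, drive, alpha, spk);
    is += -mu * (vnew + 1.0) + mu * sigma + mu * sigma_e * i_ext[t];
    vp = vv;
    vv = vnew;
    v[t] = vnew;
    if (spk) spikes.push_back(t + 1);
  }
  return List::create(_["v"] = v, _["spike_steps"] = wrap(spikes),
                      _["v_final"] = vv, _["v_prev_final"] = vp,
                      _["i_slow_final"] = is);
}

// ---- exhaustive 5-move lookahead -----------------------------------------
// Depth-first search over all move sequences of length 5 restricted to the
// 7x7 visual field. Score ordering: more food first; equal food broken by
// lexicographically earlier acquisition times; remaining ties are left to
// the caller to break at random among the optimal first moves.

struct Score {
  int count;
  int times[5];
};

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

static inline bool better(const Score &a, const Score &b) {
  if (a.count != b.count) return a.count > b.count;
  for (int k = 0; k < 5; ++k) {
    if (a.times[k] != b.times[k]) return a.times[k] < b.times[k];
  }
  return false;
}

struct LookaheadCtx {
  const int *field; // 49 entries, row-major, center = agent
  Score best;
  Score cur;
};

static void lookahead_dfs(LookaheadCtx &ctx, int r, int c, int depth,
                          uint64_t consumed) {
  if (depth == 5) {
    if (better(ctx.cur, ctx.best)) ctx.best = ctx.cur;
    return;
  }
  for (int d = 0; d < 8; ++d) {
    int nr = r + DR[d], nc = c + DC[d];
    if (nr < -3 || nr > 3 || nc < -3 || nc > 3) continue;
    int bit = (nr + 3) * 7 + (nc + 3);
    uint64_t mask = (uint64_t)1 << bit;
    bool got = ctx.field[bit] && !(consumed & mask);
    if (got) {
      ctx.cur.times[ctx.cur.count++] = depth;
      lookahead_dfs(ctx, nr, nc, depth + 1, consumed | mask);
      ctx.cur.count--;
      ctx.cur.times[ctx.cur.count] = 1000;
    } else {
      lookahead_dfs(ctx, nr, nc, depth + 1, consumed);
    }
  }
}

// Returns the direction codes (1..8) whose best 5-move completion attains
// the overall optimum of the lookahead.
// [[Rcpp::export]]
IntegerVector exhaustive5_cpp(IntegerVector field) {
  LookaheadCtx ctx;
  ctx.field = INTEGER(field);
  Score per_move[8];
  Score overall;
  overall.count = -1;
  for (int k = 0; k < 5; ++k) overall.times[k] = 1000;
  for (int d = 0; d < 8; ++d) {
    ctx.best.count = -1;
    for (int k = 0; k < 5; ++k) ctx.best.times[k] = 1000;
    ctx.cur.count = 0;
    for (int k = 0; k < 5; ++k) ctx.cur.times[k] = 1000;
    int nr = DR[d], nc = DC[d];
    int bit = (nr + 3) * 7 + (nc + 3);
    uint64_t consumed = 0;
    if (ctx.field[bit]) {
      ctx.cur.times[ctx.cur.count++] = 0;
      consumed = (uint64_t)1 << bit;
    }
    lookahead_dfs(ctx, nr, nc, 1, consumed);
    per_move[d] = ctx.best;
    if (better(ctx.best, overall)) overall = ctx.best;
  }
  std::vector<int> out;
  for (int d = 0; d < 8; ++d) {
    if (!better(overall, per_move[d])) out.push_back(d + 1);
  }
  return wrap(out);
}

// Grouped accumulation: out[g] += x[k] for g = idx[k] (1-based), length n.
// Replaces rowsum() in per-epoch hot paths.
// [[Rcpp::export]]
NumericVector accumulate_by_index_cpp(IntegerVector idx, NumericVector x,
                                      int n) {
  NumericVector out(n);
  for (int k = 0; k < idx.size(); ++k) out[idx[k] - 1] += x[k];
  return out;
}
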