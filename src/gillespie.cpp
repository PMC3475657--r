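#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

// splitmix64: decorrelates per-channel seeds derived from one root seed,
// so channel streams are independent and order-independent.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double unif01(std::mt19937_64 &rng) {
  // 53-bit uniform in (0, 1)
  return ((rng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

struct Exit {
  double rate;
  int target;
  int trans;     // transition index
  bool forward;  // binding/opening direction
};

// Exact stochastic simulation of an ensemble of independent channels
// across the segments of a concentration-jump protocol. Occupancies are
// sampled at the bin edges of each segment; directed transition events
// are counted per bin.
// [[Rcpp::export(name = ".gillespie_ensemble_cpp")]]
List gillespie_ensemble_cpp(int n_states,
                            IntegerVector trans_from,
                            IntegerVector trans_to,
                            NumericMatrix kf_eff,
                            NumericMatrix kb,
                            NumericVector p0,
                            List bin_edges_list,
                            int n_channels,
                            double root_seed) {
  const int n_trans = trans_from.size();
  const int n_seg = bin_edges_list.size();

  // per segment, per state: outgoing exits and total rate
  std::vector<std::vector<std::vector<Exit>>> exits(n_seg);
  std::vector<std::vector<double>> total_rate(n_seg);
  for (int s = 0; s < n_seg; ++s) {
    exits[s].assign(n_states, {});
    total_rate[s].assign(n_states, 0.0);
    for (int j = 0; j < n_trans; ++j) {
      double kf = kf_eff(j, s), kbw = kb(j, s);
      if (kf > 0) {
        exits[s][trans_from[j]].push_back({kf, trans_to[j], j, true});
        total_rate[s][trans_from[j]] += kf;
      }
      if (kbw > 0) {
        exits[s][trans_to[j]].push_back({kbw, trans_from[j], j, false});
        total_rate[s][trans_to[j]] += kbw;
      }
    }
  }

  std::vector<NumericVector> edges(n_seg);
  std::vector<IntegerMatrix> occ(n_seg), cnt_fwd(n_seg), cnt_bwd(n_seg);
  for (int s = 0; s < n_seg; ++s) {
    edges[s] = as<NumericVector>(bin_edges_list[s]);
    int ne = edges[s].size();
    occ[s] = IntegerMatrix(n_states, ne);
    cnt_fwd[s] = IntegerMatrix(n_trans, ne - 1);
    cnt_bwd[s] = IntegerMatrix(n_trans, ne - 1);
  }

  // initial-state CDF
  std::vector<double> cdf(n_states);
  double acc = 0.0;
  for (int i = 0; i < n_states; ++i) { acc += p0[i]; cdf[i] = acc; }

  const uint64_t root = (uint64_t)root_seed;
  for (int ch = 0; ch < n_channels; ++ch) {
    std::mt19937_64 rng(splitmix64(root ^ splitmix64((uint64_t)ch + 1)));
    double u = unif01(rng) * acc;
    int st = 0;
    while (st < n_states - 1 && u > cdf[st]) ++st;

    for (int s = 0; s < n_seg; ++s) {
      const NumericVector &be = edges[s];
      const int ne = be.size();
      const double T = be[ne - 1];
      double t = 0.0;
      int e_idx = 0;
      for (;;) {
        double R = total_rate[s][st];
        double t_next = (R > 0) ? t - std::log(unif01(rng)) / R
                                : std::numeric_limits<double>::infinity();
        while (e_idx < ne && be[e_idx] <= t_next) {
          occ[s](st, e_idx) += 1;
          ++e_idx;
        }
        if (t_next >= T) break;
        // choose the exit
        double v = unif01(rng) * R;
        const std::vector<Exit> &ex = exits[s][st];
        size_t k = 0;
        double c = 0.0;
        for (; k < ex.size(); ++k) {
          c += ex[k].rate;
          if (v <= c) break;
        }
        if (k == ex.size()) k = ex.size() - 1;  // numerical guard
        int bin = e_idx - 1;
        if (bin >= ne - 1) bin = ne - 2;
        if (ex[k].forward) cnt_fwd[s](ex[k].trans, bin) += 1;
        else cnt_bwd[s](ex[k].trans, bin) += 1;
        st = ex[k].target;
        t = t_next;
      }
      // t carries over to 0 of the next segment; exponential waiting is
      // memoryless so restarting the clock is exact.
    }
  }

  List out(n_seg);
  for (int s = 0; s < n_seg; ++s) {
    out[s] = List::create(_["bin_edges"] = edges[s], _["occupancy"] = occ[s],
                          _["counts_forward"] = cnt_fwd[s],
                          _["counts_backward"] = cnt_bwd[s]);
  }
  return out;
}
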