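// Asynchronous Monte Carlo core for two-strategy games on a toroidal square
// lattice with payoff memory.  Strategies are coded 1 = C, 0 = D; payoff
// matrix entries are R = 1, P = 0, with T and S free.
//
// RNG contract (per elementary step, in order):
//   1 uniform  -> focal site index  floor(u * L^2)
//   1 uniform  -> neighbor index    floor(u * 4), order (up, down, left, right)
//   (delayed variant only) 1 acceptance uniform for the focal player, then
//                          1 acceptance uniform for the neighbor
//   1 uniform  -> adoption Bernoulli (consumed even when both strategies agree)
// Uniforms come from R's global stream (unif_rand) unless a scripted vector
// is supplied, in which case they are consumed from it left to right.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct UniformSource {
  const double* script;
  R_xlen_t n, pos;
  bool scripted;
  double next() {
    if (scripted) {
      if (pos >= n) stop("scripted uniform stream exhausted");
      return script[pos++];
    }
    return unif_rand();
  }
};

// Overflow-guarded Fermi function W = 1 / (1 + exp((pi - pj) / K)).
inline double fermi(double pi, double pj, double K) {
  double x = (pi - pj) / K;
  if (x > 0.0) {
    double e = std::exp(-x);
    return e / (1.0 + e);
  }
  return 1.0 / (1.0 + std::exp(x));
}

// Subgroup codes: 0 = C_C, 1 = C_D, 2 = D_D, 3 = D_C
inline int subgroup(int cur, int ref) {
  if (cur == 1) return (ref == 1) ? 0 : 1;
  return (ref == 0) ? 2 : 3;
}

// Directed invasion channels, invaded <- invader:
// 0 DD<-CC, 1 DC<-CC, 2 DD<-CD, 3 DC<-CD (cooperator gain)
// 4 CC<-DD, 5 CD<-DD, 6 CC<-DC, 7 CD<-DC (cooperator loss)
inline int channel_index(int sub_invader, int sub_invaded) {
  if (sub_invader <= 1) {  // invader cooperates
    return 2 * sub_invader + (sub_invaded == 2 ? 0 : 1);
  }
  return 4 + 2 * (sub_invader - 2) + (sub_invaded == 0 ? 0 : 1);
}

}  // namespace

// [[Rcpp::export]]
List cpp_run(IntegerMatrix strat_in,
             double Tpay, double Spay, double K,
             int variant,        // 0 none, 1 averaged, 2 delayed
             double alpha, int tau, int M, double nu, int lag,
             int relax, int measure,
             bool stop_at_absorption, bool prefill,
             bool record_ledger, bool record_trace,
             Nullable<NumericVector> uniforms = R_NilValue) {
  const int L = strat_in.nrow();
  if (strat_in.ncol() != L) stop("strategy grid must be square");
  const int N = L * L;
  const int total = relax + measure;

  UniformSource rng{nullptr, 0, 0, false};
  NumericVector uvec;
  if (uniforms.isNotNull()) {
    uvec = uniforms.get();
    rng.script = REAL(uvec);
    rng.n = uvec.size();
    rng.scripted = true;
  }

  std::vector<int> strat(N);
  int ncoop = 0;
  for (int r = 0; r < L; ++r)
    for (int c = 0; c < L; ++c) {
      int s = strat_in(r, c);
      strat[r * L + c] = s;
      ncoop += s;
    }

  // precomputed von Neumann neighbors, order up, down, left, right
  std::vector<int> nbr(4 * N);
  for (int r = 0; r < L; ++r)
    for (int c = 0; c < L; ++c) {
      int i = r * L + c;
      nbr[4 * i + 0] = ((r - 1 + L) % L) * L + c;
      nbr[4 * i + 1] = ((r + 1) % L) * L + c;
      nbr[4 * i + 2] = r * L + (c - 1 + L) % L;
      nbr[4 * i + 3] = r * L + (c + 1) % L;
    }

  // Per-MCS payoff records: ring buffers, newest-first access via (w - 1 - m).
  // One record per player per full MCS ("round"); the fresh payoff computed
  // during an elementary step is Eq.-1 entry 0 but is not itself a record.
  const int cap = (variant == 1) ? M : (variant == 2 ? tau : 0);
  std::vector<double> hist(cap > 0 ? (size_t)N * cap : 0, 0.0);
  std::vector<int> hcnt(N, 0), hw(N, 0);

  // geometric weights and partial normalizers for the averaged variant
  std::vector<double> wts, norm;
  if (variant == 1) {
    wts.resize(M + 1);
    norm.resize(M + 2, 0.0);
    for (int m = 0; m <= M; ++m) {
      wts[m] = (m == 0) ? 1.0 : wts[m - 1] * alpha;
      norm[m + 1] = norm[m] + wts[m];
    }
  }

  // per-MCS strategy records for weak/strong classification (newest-first)
  const int scap = lag > 0 ? lag : 0;
  std::vector<signed char> srec(scap > 0 ? (size_t)N * scap : 0);
  int srec_cnt = 0, srec_w = 0;

  auto hist_entry = [&](int i, int m) -> double {
    int idx = hw[i] - 1 - m;
    idx %= cap;
    if (idx < 0) idx += cap;
    return hist[(size_t)i * cap + idx];
  };

  // Running weighted numerators sum_{m=1}^{k} alpha^m P_m for the averaged
  // variant, updated in O(1) per record and rebuilt exactly every REBUILD
  // records to keep floating-point drift negligible.
  const int REBUILD = 1024;
  std::vector<double> wsum;
  std::vector<int> since;
  if (variant == 1 && cap > 0) {
    wsum.assign(N, 0.0);
    since.assign(N, 0);
  }
  auto push_record = [&](int i, double p) {
    if (cap == 0) return;
    if (variant == 1) {
      double s = wsum[i];
      if (hcnt[i] == cap) s -= wts[M] * hist_entry(i, M - 1);  // drop P_M
      s = alpha * (p + s);
      hist[(size_t)i * cap + hw[i]] = p;
      hw[i] = (hw[i] + 1) % cap;
      if (hcnt[i] < cap) ++hcnt[i];
      if (++since[i] >= REBUILD) {
        since[i] = 0;
        s = 0.0;
        for (int m = hcnt[i] - 1; m >= 0; --m)
          s += wts[m + 1] * hist_entry(i, m);
      }
      wsum[i] = s;
    } else {
      hist[(size_t)i * cap + hw[i]] = p;
      hw[i] = (hw[i] + 1) % cap;
      if (hcnt[i] < cap) ++hcnt[i];
    }
  };
  // summed pairwise in neighbor order (up, down, left, right) so traces are
  // bit-reproducible against sequential reference evaluations
  auto accrue = [&](int i) -> double {
    double total = 0.0;
    int si = strat[i];
    for (int k = 0; k < 4; ++k) {
      int sj = strat[nbr[4 * i + k]];
      total += si ? (sj ? 1.0 : Spay) : (sj ? Tpay : 0.0);
    }
    return total;
  };
  // Effective ("final") payoff, evaluated over completed rounds.  The fresh
  // mid-step evaluation stands in only while no records exist (memoryless
  // configurations, or the very first MCS of an unseeded run).
  auto effective = [&](int i, double fresh) -> double {
    if (variant == 1) {
      if (cap == 0 || hcnt[i] == 0) return fresh;
      // Eq.-1 weighted average over the last hcnt completed rounds
      return (wsum[i] / alpha) / norm[hcnt[i]];
    }
    if (variant == 2) {
      double u = rng.next();  // one acceptance draw per player per step
      if (hcnt[i] == 0) return fresh;
      if (u < nu) {
        int m = tau - 1 < hcnt[i] - 1 ? tau - 1 : hcnt[i] - 1;
        return hist_entry(i, m);  // the record tau rounds back, or oldest
      }
      return hist_entry(i, 0);  // past declined: latest completed round
    }
    return fresh;
  };
  auto classify = [&](int i) -> int {
    int ref = strat[i];
    if (lag > 0 && srec_cnt > 0) {
      int back = lag < srec_cnt ? lag : srec_cnt;  // lag MCS ago, or oldest
      int slot = srec_w - back;
      slot %= scap;
      if (slot < 0) slot += scap;
      ref = srec[(size_t)i * scap + slot];
    }
    return subgroup(strat[i], ref);
  };

  // Optionally seed the payoff records as if the initial configuration had
  // always existed: each player's history is filled with its payoff in the
  // starting state, so memory is in force from the first elementary step.
  if (prefill && cap > 0) {
    for (int i = 0; i < N; ++i) {
      double p = accrue(i);
      for (int m = 0; m < cap; ++m) push_record(i, p);
    }
  }

  NumericVector rho(total);
  IntegerMatrix ledger = record_ledger ? IntegerMatrix(total, 8)
                                       : IntegerMatrix(0, 0);

  // optional per-elementary-step trace (small runs only)
  std::vector<int> tr_focal, tr_nbr, tr_si, tr_sj, tr_sub_i, tr_sub_j, tr_adopt;
  std::vector<double> tr_praw_i, tr_praw_j, tr_peff_i, tr_peff_j, tr_W, tr_u;

  bool absorbed = false;
  int absorbed_at = NA_INTEGER;
  int mcs_done = 0;

  for (int t = 0; t < total; ++t) {
    for (int step = 0; step < N; ++step) {
      int i = (int)(rng.next() * N);
      if (i >= N) i = N - 1;
      int k = (int)(rng.next() * 4);
      if (k >= 4) k = 3;
      int j = nbr[4 * i + k];

      double praw_i = accrue(i);
      double praw_j = accrue(j);

      double peff_i = effective(i, praw_i);
      double peff_j = effective(j, praw_j);
      double W = fermi(peff_i, peff_j, K);
      double u_adopt = rng.next();  // consumed even for same-strategy pairs

      int si = strat[i], sj = strat[j];
      int sub_i = -1, sub_j = -1, adopted = 0;
      if (si != sj) {
        sub_i = classify(i);
        sub_j = classify(j);
        if (u_adopt < W) {
          adopted = 1;
          strat[i] = sj;
          ncoop += (sj == 1) ? 1 : -1;
          if (record_ledger) ledger(t, channel_index(sub_j, sub_i)) += 1;
        }
      }
      if (record_trace) {
        tr_focal.push_back(i);
        tr_nbr.push_back(j);
        tr_si.push_back(si);
        tr_sj.push_back(sj);
        tr_praw_i.push_back(praw_i);
        tr_praw_j.push_back(praw_j);
        tr_peff_i.push_back(peff_i);
        tr_peff_j.push_back(peff_j);
        tr_W.push_back(W);
        tr_u.push_back(u_adopt);
        tr_sub_i.push_back(sub_i);
        tr_sub_j.push_back(sub_j);
        tr_adopt.push_back(adopted);
      }
    }
    if (cap > 0) {  // per-MCS payoff records from the end-of-sweep state
      for (int i = 0; i < N; ++i) push_record(i, accrue(i));
    }
    if (scap > 0) {  // per-MCS strategy record
      for (int i = 0; i < N; ++i)
        srec[(size_t)i * scap + srec_w] = (signed char)strat[i];
      srec_w = (srec_w + 1) % scap;
      if (srec_cnt < scap) ++srec_cnt;
    }
    rho[t] = (double)ncoop / N;
    mcs_done = t + 1;
    if (stop_at_absorption && (ncoop == 0 || ncoop == N)) {
      absorbed = true;
      absorbed_at = mcs_done;
      break;
    }
  }

  // stationary cooperator fraction
  double rho_stat;
  if (absorbed) {
    rho_stat = rho[mcs_done - 1];
  } else if (measure > 0) {
    double s = 0.0;
    for (int t = relax; t < total; ++t) s += rho[t];
    rho_stat = s / measure;
  } else {
    rho_stat = mcs_done > 0 ? rho[mcs_done - 1] : (double)ncoop / N;
  }

  IntegerMatrix strat_out(L, L);
  for (int r = 0; r < L; ++r)
    for (int c = 0; c < L; ++c) strat_out(r, c) = strat[r * L + c];

  NumericVector rho_out(mcs_done);
  for (int t = 0; t < mcs_done; ++t) rho_out[t] = rho[t];
  List out = List::create(
      _["strategies"] = strat_out, _["rho"] = rho_out,
      _["rho_stationary"] = rho_stat, _["mcs"] = mcs_done,
      _["absorbed"] = absorbed, _["absorbed_at"] = absorbed_at,
      _["draws_used"] = rng.scripted ? (double)rng.pos : NA_REAL);
  if (record_ledger) {
    IntegerMatrix led(mcs_done, 8);
    for (int t = 0; t < mcs_done; ++t)
      for (int c = 0; c < 8; ++c) led(t, c) = ledger(t, c);
    out["ledger"] = led;
  }
  if (record_trace) {
    out["trace"] = DataFrame::create(
        _["focal"] = tr_focal, _["neighbor"] = tr_nbr, _["s_i"] = tr_si,
        _["s_j"] = tr_sj, _["p_raw_i"] = tr_praw_i, _["p_raw_j"] = tr_praw_j,
        _["p_eff_i"] = tr_peff_i, _["p_eff_j"] = tr_peff_j, _["W"] = tr_W,
        _["u_adopt"] = tr_u, _["sub_i"] = tr_sub_i, _["sub_j"] = tr_sub_j,
        _["adopted"] = tr_adopt);
  }
  return out;
}
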