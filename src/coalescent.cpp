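#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Structured Hudson coalescent over independent non-recombining loci.
// Time is measured in generations; population sizes are diploid Ne, so a pair
// of lineages in a population of size N coalesces at rate 1/(2N) per
// generation. Migration follows the forward convention M[i->j] = probability
// that an individual in j originates from i, which equals the backward jump
// rate of a lineage currently in j toward i.

static const double INF = std::numeric_limits<double>::infinity();

// xoshiro256++ seeded via splitmix64: deterministic across platforms, so the
// byte-identical-output contract does not depend on R's RNG internals.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double unif_pos() { double u; do { u = unif(); } while (u <= 0.0); return u; }
  double exp1() { return -std::log(unif_pos()); }
  int poisson(double lambda) {
    int k = 0;
    while (lambda > 25.0) { k += poisson(25.0); lambda -= 25.0; }
    double L = std::exp(-lambda), p = 1.0;
    int n = 0;
    do { ++n; p *= unif_pos(); } while (p > L);
    return k + n - 1;
  }
};

struct Model {
  int K;
  std::vector<double> N0;      // diploid sizes at sampling time
  std::vector<double> r0;      // forward exponential growth rates per generation
  std::vector<double> mig;     // K*K forward matrix, mig[i*K+j] = M[i->j]
  // events flattened, 6 doubles per event:
  // time, kind (0 join a->b, 1 resize a), a, b, size, growth
  std::vector<double> events;
  int nev;
};

static Model parse_model(const List& model) {
  Model m;
  m.K = as<int>(model["npop"]);
  m.N0 = as<std::vector<double> >(model["sizes"]);
  m.r0 = as<std::vector<double> >(model["growth"]);
  NumericMatrix mm = model["migration"];
  m.mig.assign(m.K * m.K, 0.0);
  for (int i = 0; i < m.K; ++i)
    for (int j = 0; j < m.K; ++j) m.mig[i * m.K + j] = mm(i, j);
  NumericMatrix ev = as<NumericMatrix>(model["events"]);
  m.nev = ev.nrow();
  m.events.resize(6 * m.nev);
  for (int e = 0; e < m.nev; ++e)
    for (int c = 0; c < 6; ++c) m.events[6 * e + c] = ev(e, c);
  return m;
}

struct Lin {
  int pop;
  double birth;
  int d[3];       // descendant sample counts per (sampled) population
  uint64_t mask;  // descendant sample bitmask (site simulation only)
};

struct Branch { uint64_t mask; double len; };

// reusable per-call scratch so the replicate loop does not allocate
struct Workspace {
  std::vector<Lin> lin;
  std::vector<int> mem[3];
  long budget; // total event budget across a replicate batch
};

// One genealogy. mode 0: accumulate branch length into cell accumulator acc
// (column-major over dims (ss[0]+1, ss[1]+1, ss[2]+1)). mode 1: collect
// (mask, length) branch records for mutation placement.
static void run_one(const Model& M, const std::vector<int>& ss, Xoshiro& rng,
                    int mode, double* acc,
                    std::vector<Branch>* branches, double* ttot,
                    Workspace& ws) {
  const int K = M.K;
  const int d1 = ss[0] + 1, d2 = (ss.size() > 1 ? ss[1] : 0) + 1;
  std::vector<Lin>& lin = ws.lin;
  lin.clear();
  std::vector<int>* mem = ws.mem;
  for (int k = 0; k < 3; ++k) mem[k].clear();
  int ntot = 0, bit = 0;
  for (int k = 0; k < K; ++k) ntot += (k < (int)ss.size() ? ss[k] : 0);
  lin.reserve(2 * ntot);
  for (int k = 0; k < K; ++k) {
    int nk = (k < (int)ss.size() ? ss[k] : 0);
    for (int i = 0; i < nk; ++i) {
      Lin l; l.pop = k; l.birth = 0.0;
      l.d[0] = l.d[1] = l.d[2] = 0; l.d[k] = 1;
      l.mask = (mode == 1) ? (1ULL << bit) : 0ULL;
      ++bit;
      mem[k].push_back((int)lin.size());
      lin.push_back(l);
    }
  }
  double curN[3], curR[3], outr[3];
  bool act[3];
  for (int k = 0; k < K; ++k) {
    curN[k] = M.N0[k]; curR[k] = M.r0[k]; act[k] = true; outr[k] = 0.0;
  }
  // outr[k]: per-lineage rate of leaving pop k = sum over active i of M[i->k]
  auto recompute_outr = [&]() {
    for (int k = 0; k < K; ++k) {
      outr[k] = 0.0;
      if (!act[k]) continue;
      for (int i = 0; i < K; ++i)
        if (i != k && act[i]) outr[k] += M.mig[i * K + k];
    }
  };
  recompute_outr();
  double t = 0.0, total_len = 0.0;
  int ev = 0;
  const int nev = M.nev;
  const double* EV = M.events.data();
  int alive = ntot;

  auto die = [&](int li, double now) {
    double len = now - lin[li].birth;
    total_len += len;
    if (mode == 0) {
      int idx = lin[li].d[0] + d1 * (lin[li].d[1] + d2 * lin[li].d[2]);
      acc[idx] += len;
    } else {
      Branch b; b.mask = lin[li].mask; b.len = len;
      branches->push_back(b);
    }
  };

  bool any_growth_model = false;
  for (int k = 0; k < K; ++k) if (M.r0[k] != 0.0) any_growth_model = true;
  for (int e = 0; e < nev; ++e)
    if ((int)EV[6 * e + 1] == 1 && EV[6 * e + 5] != 0.0)
      any_growth_model = true;

  long local_events = 0;
  while (alive > 1) {
    if (--ws.budget < 0 || ++local_events > 5000)
      stop("event budget exhausted (runaway migration/coalescence regime)");
    // candidate waiting times
    double dt_best = INF; int type = -1, pop_best = -1;
    double totm = 0.0;
    for (int k = 0; k < K; ++k) totm += mem[k].size() * outr[k];
    bool growing = false;
    if (any_growth_model)
      for (int k = 0; k < K; ++k)
        if (curR[k] != 0.0 && mem[k].size() > 1) growing = true;
    if (!growing) {
      // constant rates: one exponential for the union of coalescence and
      // migration, then attribute the event by relative rate (one log call)
      double crate[3], total_rate = totm;
      for (int k = 0; k < K; ++k) {
        int nk = (int)mem[k].size();
        crate[k] = (nk >= 2) ? 0.5 * nk * (nk - 1) / (2.0 * curN[k]) : 0.0;
        total_rate += crate[k];
      }
      if (total_rate > 0.0) {
        dt_best = rng.exp1() / total_rate;
        double x = rng.unif() * total_rate, cum = 0.0;
        type = 1;
        for (int k = 0; k < K; ++k) {
          cum += crate[k];
          if (x < cum) { type = 0; pop_best = k; break; }
        }
      }
    } else {
      for (int k = 0; k < K; ++k) {
        int nk = (int)mem[k].size();
        if (nk < 2) continue;
        double rate0 = 0.5 * nk * (nk - 1) / (2.0 * curN[k]);
        double E = rng.exp1(), u;
        if (curR[k] == 0.0) u = E / rate0;
        else {
          double a = 1.0 + curR[k] * E / rate0;
          u = (a > 0.0) ? std::log(a) / curR[k] : INF;
        }
        if (u < dt_best) { dt_best = u; type = 0; pop_best = k; }
      }
      if (totm > 0.0) {
        double u = rng.exp1() / totm;
        if (u < dt_best) { dt_best = u; type = 1; }
      }
    }
    double dt_ev = (ev < nev) ? EV[6 * ev] - t : INF;
    if (dt_ev <= dt_best) { dt_best = dt_ev; type = 2; }
    if (!std::isfinite(dt_best))
      stop("model never coalesces: no coalescence, migration or event possible");
    for (int k = 0; k < K; ++k)
      if (curR[k] != 0.0) curN[k] *= std::exp(-curR[k] * dt_best);
    t += dt_best;
    if (type == 2) {
      // apply all events scheduled at (numerically) this time
      double t_ev = EV[6 * ev];
      while (ev < nev && EV[6 * ev] <= t_ev) {
        int kind = (int)EV[6 * ev + 1];
        int a = (int)EV[6 * ev + 2];
        if (kind == 0) {
          int b = (int)EV[6 * ev + 3];
          for (size_t i = 0; i < mem[a].size(); ++i) {
            lin[mem[a][i]].pop = b;
            mem[b].push_back(mem[a][i]);
          }
          mem[a].clear();
          act[a] = false;
          recompute_outr();
        } else {
          curN[a] = EV[6 * ev + 4];
          curR[a] = EV[6 * ev + 5];
        }
        ++ev;
      }
    } else if (type == 0) {
      // coalescence in pop_best
      std::vector<int>& mk = mem[pop_best];
      int nk = (int)mk.size();
      int ia = (int)(rng.unif() * nk); if (ia >= nk) ia = nk - 1;
      int ib = (int)(rng.unif() * (nk - 1)); if (ib >= nk - 1) ib = nk - 2;
      if (ib >= ia) ++ib;
      int la = mk[ia], lb = mk[ib];
      die(la, t); die(lb, t);
      Lin nl; nl.pop = pop_best; nl.birth = t;
      for (int q = 0; q < 3; ++q) nl.d[q] = lin[la].d[q] + lin[lb].d[q];
      nl.mask = lin[la].mask | lin[lb].mask;
      int ni = (int)lin.size();
      lin.push_back(nl);
      mk[ia] = ni;
      mk[ib] = mk.back(); mk.pop_back();
      --alive;
    } else {
      // migration: pick pop weighted by n_k * outr[k], lineage uniform, then source pop
      double x = rng.unif() * totm, cum = 0.0; int kp = -1;
      for (int k = 0; k < K; ++k) {
        cum += mem[k].size() * outr[k];
        if (x < cum) { kp = k; break; }
      }
      if (kp < 0) kp = K - 1;
      std::vector<int>& mk = mem[kp];
      int ii = (int)(rng.unif() * mk.size()); if (ii >= (int)mk.size()) ii = (int)mk.size() - 1;
      int li = mk[ii];
      // destination i with weight M[i->kp]
      double y = rng.unif() * outr[kp], c2 = 0.0; int dest = -1;
      for (int i = 0; i < K; ++i) {
        if (i == kp || !act[i]) continue;
        c2 += M.mig[i * K + kp];
        if (y < c2) { dest = i; break; }
      }
      if (dest < 0) continue; // numerical edge: no destination, redraw
      mk[ii] = mk.back(); mk.pop_back();
      lin[li].pop = dest;
      mem[dest].push_back(li);
    }
  }
  if (ttot) *ttot = total_len;
}

// Mean branch length per joint-SFS cell over n_reps genealogies.
// [[Rcpp::export]]
NumericVector cpp_expected_sfs_lengths(List model, IntegerVector ss,
                                       int n_reps, double seed) {
  Model M = parse_model(model);
  std::vector<int> s = as<std::vector<int> >(ss);
  while ((int)s.size() < 3) s.push_back(0);
  int nc = (s[0] + 1) * (s[1] + 1) * (s[2] + 1);
  std::vector<double> acc(nc, 0.0);
  Xoshiro rng((uint64_t)seed);
  Workspace ws;
  ws.budget = (long)n_reps * 2000L + 100000L;
  for (int r = 0; r < n_reps; ++r)
    run_one(M, s, rng, 0, acc.data(), NULL, NULL, ws);
  NumericVector out(nc);
  for (int i = 0; i < nc; ++i) out[i] = acc[i] / n_reps;
  out.attr("dim") = IntegerVector::create(s[0] + 1, s[1] + 1, s[2] + 1);
  return out;
}

// n_sites independent loci, one segregating site each: mutation placed on a
// branch chosen with probability proportional to its length. Rows are sites,
// columns haploid genomes (grouped by population), entries 0/1 derived.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_snps(List model, IntegerVector ss, int n_sites,
                           double seed) {
  Model M = parse_model(model);
  std::vector<int> s = as<std::vector<int> >(ss);
  while ((int)s.size() < 3) s.push_back(0);
  int ntot = s[0] + s[1] + s[2];
  if (ntot > 64) stop("site simulation supports at most 64 haploid genomes");
  IntegerMatrix out(n_sites, ntot);
  Xoshiro rng((uint64_t)seed);
  std::vector<Branch> br;
  Workspace ws;
  ws.budget = (long)n_sites * 1000000L + 10000000L;
  // Each emitted site must represent one mutation under the infinite-sites
  // process, so a genealogy's chance of contributing is proportional to its
  // total branch length (longer trees catch more mutations). A pilot batch
  // calibrates a rejection envelope on the total length; conditional on
  // acceptance, the mutated branch is drawn length-weighted within the tree.
  double lmax = 0.0;
  {
    Xoshiro pilot_rng(((uint64_t)seed) ^ 0x5851F42D4C957F2DULL);
    for (int r = 0; r < 512; ++r) {
      br.clear();
      double ttot = 0.0;
      run_one(M, s, pilot_rng, 1, NULL, &br, &ttot, ws);
      if (ttot > lmax) lmax = ttot;
    }
    lmax *= 1.5;
  }
  for (int site = 0; site < n_sites; ++site) {
    double ttot = 0.0;
    do {
      br.clear();
      ttot = 0.0;
      run_one(M, s, rng, 1, NULL, &br, &ttot, ws);
    } while (rng.unif() * lmax > ttot);
    double x = rng.unif() * ttot, cum = 0.0;
    uint64_t mask = br.back().mask;
    for (size_t i = 0; i < br.size(); ++i) {
      cum += br[i].len;
      if (x < cum) { mask = br[i].mask; break; }
    }
    for (int j = 0; j < ntot; ++j)
      out(site, j) = (int)((mask >> j) & 1ULL);
  }
  return out;
}

// n_loci independent loci; per locus, Poisson(mut_rate * total branch length)
// mutations, each on a length-weighted branch. mut_rate is the per-locus
// mutation rate per generation (per-site rate times locus length in bp).
// [[Rcpp::export]]
List cpp_sim_loci(List model, IntegerVector ss, int n_loci,
                  double mut_rate, double seed) {
  Model M = parse_model(model);
  std::vector<int> s = as<std::vector<int> >(ss);
  while ((int)s.size() < 3) s.push_back(0);
  int ntot = s[0] + s[1] + s[2];
  if (ntot > 64) stop("site simulation supports at most 64 haploid genomes");
  Xoshiro rng((uint64_t)seed);
  std::vector<Branch> br;
  std::vector<uint64_t> masks;
  std::vector<int> locus;
  NumericVector ttot_out(n_loci);
  Workspace ws;
  ws.budget = (long)n_loci * 100000L + 1000000L;
  for (int l = 0; l < n_loci; ++l) {
    br.clear();
    double ttot = 0.0;
    run_one(M, s, rng, 1, NULL, &br, &ttot, ws);
    ttot_out[l] = ttot;
    int nmut = rng.poisson(mut_rate * ttot);
    for (int m = 0; m < nmut; ++m) {
      double x = rng.unif() * ttot, cum = 0.0;
      uint64_t mask = br.back().mask;
      for (size_t i = 0; i < br.size(); ++i) {
        cum += br[i].len;
        if (x < cum) { mask = br[i].mask; break; }
      }
      masks.push_back(mask);
      locus.push_back(l + 1);
    }
  }
  IntegerMatrix out((int)masks.size(), ntot);
  for (size_t r = 0; r < masks.size(); ++r)
    for (int j = 0; j < ntot; ++j)
      out((int)r, j) = (int)((masks[r] >> j) & 1ULL);
  return List::create(_["derived"] = out,
                      _["locus"] = wrap(locus),
                      _["total_length"] = ttot_out);
}

// Exact permutation distribution of the Spearman statistic S = sum rx * ry[perm]
// (monotone in r for fixed rank vectors). Returns counts of permutations with
// S >= observed, S <= observed, |S - center| >= |observed - center|, and n!.
// [[Rcpp::export]]
NumericVector cpp_spearman_perm_exact(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  if (n != ry.size()) stop("rank vectors differ in length");
  if (n < 2 || n > 10) stop("exact enumeration supports 2 <= n <= 10");
  std::vector<double> y(ry.begin(), ry.end());
  double s_obs = 0.0, mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { s_obs += rx[i] * ry[i]; mx += rx[i]; my += y[i]; }
  double center = mx * my / n; // S at zero correlation
  double dev_obs = std::fabs(s_obs - center);
  const double tol = 1e-9;
  double n_ge = 0, n_le = 0, n_abs = 0, total = 0;
  // Heap's algorithm, iterative
  std::vector<int> c(n, 0);
  auto tally = [&]() {
    double S = 0.0;
    for (int i = 0; i < n; ++i) S += rx[i] * y[i];
    if (S >= s_obs - tol) n_ge += 1;
    if (S <= s_obs + tol) n_le += 1;
    if (std::fabs(S - center) >= dev_obs - tol) n_abs += 1;
    total += 1;
  };
  tally();
  int i = 0;
  while (i < n) {
    if (c[i] < i) {
      if (i % 2 == 0) std::swap(y[0], y[i]); else std::swap(y[c[i]], y[i]);
      tally();
      c[i] += 1;
      i = 0;
    } else {
      c[i] = 0;
      ++i;
    }
  }
  return NumericVector::create(n_ge, n_le, n_abs, total);
}
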