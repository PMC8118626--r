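#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All randomness goes through R's RNG (unif_rand) so set.seed() in R
// controls every routine here bit-for-bit.

static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

static void fisher_yates(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = rand_int(i + 1);
    std::swap(v[i], v[j]);
  }
}

// ---- occupancy helpers: occ is n_neurons x n_frames, index n * F + f ----

// A placement is admissible only if the block's frames AND the two flanking
// frames are unoccupied: landing adjacent to existing activity would merge
// two blocks and silently change the neuron's block count.
static inline bool range_free(const std::vector<uint8_t>& occ, int n, int F,
                              int start, int len) {
  int lo = (start > 0) ? start - 1 : 0;
  int hi = (start + len < F) ? start + len : F - 1;
  const uint8_t* p = occ.data() + (size_t)n * F;
  for (int t = lo; t <= hi; ++t) if (p[t]) return false;
  return true;
}

static inline void range_set(std::vector<uint8_t>& occ, int n, int F,
                             int start, int len, uint8_t val) {
  uint8_t* p = occ.data() + (size_t)n * F + start;
  for (int t = 0; t < len; ++t) p[t] = val;
}

// Core swap shuffle on a block list. Mutates `neuron` and `occ` in place.
// Every block initiates at least one attempted exchange; a partner that
// would create within-neuron overlap is rejected and resampled up to
// max_retries times, after which the block keeps its neuron (skip count).
static int swap_core(const std::vector<int>& start, const std::vector<int>& len,
                     std::vector<int>& neuron, std::vector<uint8_t>& occ,
                     int F, int max_retries) {
  int nb = (int)neuron.size();
  int skipped = 0;
  if (nb < 2) return 0;
  std::vector<int> order(nb);
  for (int i = 0; i < nb; ++i) order[i] = i;
  fisher_yates(order);
  for (int oi = 0; oi < nb; ++oi) {
    int i = order[oi];
    bool done = false;
    for (int attempt = 0; attempt < max_retries && !done; ++attempt) {
      int j = rand_int(nb);
      if (j == i) continue;
      int a = neuron[i], b = neuron[j];
      if (a == b) continue;
      // temporarily lift both blocks, test the exchanged placement
      range_set(occ, a, F, start[i], len[i], 0);
      range_set(occ, b, F, start[j], len[j], 0);
      bool ok = range_free(occ, b, F, start[i], len[i]) &&
                range_free(occ, a, F, start[j], len[j]);
      if (ok) {
        neuron[i] = b; neuron[j] = a;
        range_set(occ, b, F, start[i], len[i], 1);
        range_set(occ, a, F, start[j], len[j], 1);
        done = true;
      } else {
        range_set(occ, a, F, start[i], len[i], 1);
        range_set(occ, b, F, start[j], len[j], 1);
      }
    }
    if (!done) ++skipped;
  }
  return skipped;
}

static std::vector<uint8_t> build_occ(const std::vector<int>& start,
                                      const std::vector<int>& len,
                                      const std::vector<int>& neuron,
                                      int N, int F) {
  std::vector<uint8_t> occ((size_t)N * F, 0);
  for (size_t i = 0; i < neuron.size(); ++i)
    range_set(occ, neuron[i], F, start[i], len[i], 1);
  return occ;
}

// [[Rcpp::export]]
List cpp_swap_shuffle(IntegerVector start, IntegerVector len,
                      IntegerVector neuron, int n_neurons, int n_frames,
                      int max_retries) {
  int nb = start.size();
  std::vector<int> st(start.begin(), start.end());
  std::vector<int> le(len.begin(), len.end());
  std::vector<int> ne(neuron.begin(), neuron.end());
  std::vector<uint8_t> occ = build_occ(st, le, ne, n_neurons, n_frames);
  int skipped = swap_core(st, le, ne, occ, n_frames, max_retries);
  (void)nb;
  return List::create(_["neuron"] = IntegerVector(ne.begin(), ne.end()),
                      _["skipped"] = skipped);
}

// ---- SHARC -----------------------------------------------------------

// Pairwise Pearson correlation of two binary rows from joint/marginal
// active-frame counts.
static inline double corr_from_counts(double o, double ti, double tj, double F) {
  double d = ti * (F - ti) * tj * (F - tj);
  if (d <= 0) return 0.0;
  return (F * o - ti * tj) / std::sqrt(d);
}

// [[Rcpp::export]]
List cpp_sharc(IntegerVector start, IntegerVector len, IntegerVector neuron,
               int n_neurons, int n_frames, NumericMatrix target,
               int passes, int max_gain, int max_loss, double temperature) {
  const int N = n_neurons, F = n_frames;
  const int nb = start.size();
  std::vector<int> st(start.begin(), start.end());
  std::vector<int> le(len.begin(), len.end());
  std::vector<int> ne(neuron.begin(), neuron.end());
  std::vector<uint8_t> occ = build_occ(st, le, ne, N, F);

  // static frame -> block-id index (block timing never changes)
  std::vector<std::vector<int> > frame_blocks(F);
  for (int i = 0; i < nb; ++i)
    for (int t = 0; t < le[i]; ++t) frame_blocks[st[i] + t].push_back(i);

  // joint active-frame counts O (N x N) and per-neuron totals T
  std::vector<double> O((size_t)N * N, 0.0);
  std::vector<double> T(N, 0.0);
  for (int i = 0; i < nb; ++i) T[ne[i]] += le[i];
  for (int f = 0; f < F; ++f) {
    const std::vector<int>& ids = frame_blocks[f];
    for (size_t u = 0; u < ids.size(); ++u)
      for (size_t v = u + 1; v < ids.size(); ++v) {
        int a = ne[ids[u]], b = ne[ids[v]];
        O[(size_t)a * N + b] += 1.0;
        O[(size_t)b * N + a] += 1.0;
      }
  }

  std::vector<int> net(N, 0);      // blocks received minus donated
  int unassignable = 0, fallback_used = 0;
  std::vector<double> P(N);
  std::vector<bool> forbidden(N);
  std::vector<int> ovl_ids; ovl_ids.reserve(64);
  std::vector<int> ovl_r;   ovl_r.reserve(64);
  std::vector<int> order(nb);
  std::vector<int> argmaxes; argmaxes.reserve(N);

  for (int pass = 0; pass < passes; ++pass) {
    for (int i = 0; i < nb; ++i) order[i] = i;
    fisher_yates(order);
    for (int oi = 0; oi < nb; ++oi) {
      int i = order[oi];
      int a = ne[i];
      if (net[a] - 1 < -max_loss) continue;   // budget: cannot donate further
      // lift block i out of neuron a
      for (int t = 0; t < le[i]; ++t) {
        int f = st[i] + t;
        const std::vector<int>& ids = frame_blocks[f];
        for (size_t u = 0; u < ids.size(); ++u) {
          int j = ids[u];
          if (j == i) continue;
          int m = ne[j];
          O[(size_t)a * N + m] -= 1.0;
          O[(size_t)m * N + a] -= 1.0;
        }
      }
      T[a] -= le[i];
      range_set(occ, a, F, st[i], le[i], 0);

      // overlapping assigned blocks X with overlap lengths r_j
      ovl_ids.clear(); ovl_r.clear();
      for (int t = 0; t < le[i]; ++t) {
        int f = st[i] + t;
        const std::vector<int>& ids = frame_blocks[f];
        for (size_t u = 0; u < ids.size(); ++u) {
          int j = ids[u];
          if (j == i) continue;
          bool seen = false;
          for (size_t q = 0; q < ovl_ids.size(); ++q)
            if (ovl_ids[q] == j) { ovl_r[q]++; seen = true; break; }
          if (!seen) { ovl_ids.push_back(j); ovl_r.push_back(1); }
        }
      }

      std::fill(P.begin(), P.end(), 0.0);
      std::fill(forbidden.begin(), forbidden.end(), false);
      for (size_t q = 0; q < ovl_ids.size(); ++q) {
        int j = ovl_ids[q];
        int nj = ne[j];
        double coef = (double)ovl_r[q] / ((double)le[i] * (double)le[j]);
        double tn = T[nj];
        const double* Orow = O.data() + (size_t)nj * N;
        NumericMatrix::Row trow = target(nj, _);
        for (int m = 0; m < N; ++m) {
          if (m == nj) continue;
          double cur = corr_from_counts(Orow[m], tn, T[m], (double)F);
          P[m] += coef * (trow[m] - cur);
        }
      }
      // neurons whose occupancy conflicts with block i (overlap or
      // adjacency, which would merge blocks) may not take it
      for (int m = 0; m < N; ++m)
        if (!range_free(occ, m, F, st[i], le[i])) forbidden[m] = true;
      // activity budget: receiving is blocked once net gain would exceed +max_gain
      for (int m = 0; m < N; ++m)
        if (m != a && net[m] + 1 > max_gain) forbidden[m] = true;

      int b = -1;
      bool any_eligible = false, any_nonzero = false;
      double best = -std::numeric_limits<double>::infinity();
      for (int m = 0; m < N; ++m) {
        if (forbidden[m]) continue;
        any_eligible = true;
        if (P[m] != 0.0) any_nonzero = true;
        if (P[m] > best) best = P[m];
      }
      if (!any_eligible) {
        b = a;                       // keep current neuron, log
        ++unassignable;
      } else if (any_nonzero) {
        argmaxes.clear();
        for (int m = 0; m < N; ++m)
          if (!forbidden[m] && P[m] == best) argmaxes.push_back(m);
        b = argmaxes[argmaxes.size() == 1 ? 0 : rand_int((int)argmaxes.size())];
      } else {
        // no guesses available: pick a receiver weighted toward net donors
        // so per-neuron activity budgets drift back toward balance
        ++fallback_used;
        double wsum = 0.0;
        for (int m = 0; m < N; ++m)
          if (!forbidden[m]) wsum += std::exp(-net[m] / temperature);
        double u = unif_rand() * wsum, acc = 0.0;
        for (int m = 0; m < N; ++m) {
          if (forbidden[m]) continue;
          acc += std::exp(-net[m] / temperature);
          if (u <= acc) { b = m; break; }
        }
        if (b < 0) { b = a; ++unassignable; }
      }

      // commit block i to neuron b
      for (int t = 0; t < le[i]; ++t) {
        int f = st[i] + t;
        const std::vector<int>& ids = frame_blocks[f];
        for (size_t u = 0; u < ids.size(); ++u) {
          int j = ids[u];
          if (j == i) continue;
          int m = ne[j];
          O[(size_t)b * N + m] += 1.0;
          O[(size_t)m * N + b] += 1.0;
        }
      }
      T[b] += le[i];
      range_set(occ, b, F, st[i], le[i], 1);
      if (b != a) { --net[a]; ++net[b]; }
      ne[i] = b;
    }
  }

  return List::create(_["neuron"] = IntegerVector(ne.begin(), ne.end()),
                      _["net_gain"] = IntegerVector(net.begin(), net.end()),
                      _["unassignable"] = unassignable,
                      _["fallback_used"] = fallback_used);
}

// ---- triplet counting and enrichment ---------------------------------

static inline long long trip_key(int i, int j, int k, long long N) {
  return ((long long)i * N + j) * N + k;  // requires i < j < k
}

typedef std::unordered_map<long long, int> TripMap;

static void count_frame_triplets(const std::vector<int>& active, TripMap& out) {
  int k = (int)active.size();
  if (k < 3) return;
  for (int a = 0; a < k - 2; ++a)
    for (int b = a + 1; b < k - 1; ++b)
      for (int c = b + 1; c < k; ++c)
        out[trip_key(active[a], active[b], active[c], 1000000)]++;
}

// active neurons (sorted) per frame from occupancy
static void frame_active(const std::vector<uint8_t>& occ, int N, int F, int f,
                         std::vector<int>& out) {
  out.clear();
  for (int n = 0; n < N; ++n) if (occ[(size_t)n * F + f]) out.push_back(n);
}

// [[Rcpp::export]]
List cpp_count_triplets(IntegerMatrix raster, IntegerVector frames) {
  int N = raster.nrow();
  TripMap counts;
  std::vector<int> active; active.reserve(N);
  for (int q = 0; q < frames.size(); ++q) {
    int f = frames[q];
    active.clear();
    for (int n = 0; n < N; ++n) if (raster(n, f)) active.push_back(n);
    count_frame_triplets(active, counts);
  }
  int m = (int)counts.size();
  IntegerVector i1(m), i2(m), i3(m), cnt(m);
  int r = 0;
  for (TripMap::const_iterator it = counts.begin(); it != counts.end(); ++it) {
    long long key = it->first;
    i3[r] = (int)(key % 1000000);
    i2[r] = (int)((key / 1000000) % 1000000);
    i1[r] = (int)(key / (1000000LL * 1000000LL));
    cnt[r] = it->second;
    ++r;
  }
  return List::create(_["n1"] = i1, _["n2"] = i2, _["n3"] = i3,
                      _["count"] = cnt);
}

// For each condition: real triplet list (m x 3, 0-based) with real counts.
// Generates n_surrogates whole-session swap shuffles and tallies, per real
// triplet, how many surrogates have a strictly smaller / equal count within
// that condition's frames.
// [[Rcpp::export]]
List cpp_triplet_enrichment(IntegerVector start, IntegerVector len,
                            IntegerVector neuron, int n_neurons, int n_frames,
                            List cond_frames, List real_keys,
                            int n_surrogates, int max_retries) {
  const int N = n_neurons, F = n_frames;
  std::vector<int> st(start.begin(), start.end());
  std::vector<int> le(len.begin(), len.end());
  std::vector<int> ne0(neuron.begin(), neuron.end());
  int ncond = cond_frames.size();

  std::vector<std::vector<int> > cframes(ncond);
  std::vector<std::vector<long long> > keys(ncond);
  std::vector<IntegerVector> n_less(ncond), n_equal(ncond);
  std::vector<std::vector<int> > real_cnt(ncond);
  for (int c = 0; c < ncond; ++c) {
    IntegerVector fv = cond_frames[c];
    cframes[c] = std::vector<int>(fv.begin(), fv.end());
    List rk = real_keys[c];
    IntegerMatrix trip = rk["triplets"];
    IntegerVector rc = rk["count"];
    int m = trip.nrow();
    keys[c].resize(m);
    real_cnt[c] = std::vector<int>(rc.begin(), rc.end());
    for (int r = 0; r < m; ++r)
      keys[c][r] = trip_key(trip(r, 0), trip(r, 1), trip(r, 2), 1000000);
    n_less[c] = IntegerVector(m);
    n_equal[c] = IntegerVector(m);
  }

  std::vector<int> active; active.reserve(N);
  for (int s = 0; s < n_surrogates; ++s) {
    std::vector<int> ne(ne0);
    std::vector<uint8_t> occ = build_occ(st, le, ne, N, F);
    swap_core(st, le, ne, occ, F, max_retries);
    for (int c = 0; c < ncond; ++c) {
      TripMap counts;
      for (size_t q = 0; q < cframes[c].size(); ++q) {
        frame_active(occ, N, F, cframes[c][q], active);
        count_frame_triplets(active, counts);
      }
      int m = (int)keys[c].size();
      for (int r = 0; r < m; ++r) {
        TripMap::const_iterator it = counts.find(keys[c][r]);
        int cs = (it == counts.end()) ? 0 : it->second;
        if (cs < real_cnt[c][r]) n_less[c][r]++;
        else if (cs == real_cnt[c][r]) n_equal[c][r]++;
      }
    }
    if ((s & 63) == 0) Rcpp::checkUserInterrupt();
  }

  List out(ncond);
  for (int c = 0; c < ncond; ++c)
    out[c] = List::create(_["n_less"] = n_less[c], _["n_equal"] = n_equal[c]);
  return out;
}

// ---- delta-rule training ---------------------------------------------

// X: hidden-unit activity per frame (H x Fr), z: labels in {0,1} per frame.
// One output weight per hidden unit; logistic output y = 1/(1+exp(-w.x));
// update dw_i = lr * y (1-y) (z-y) x_i, frames visited in a fresh random
// order each pass. Returns trained w and per-pass training log-loss.
// [[Rcpp::export]]
List cpp_train_delta(NumericMatrix X, NumericVector z, NumericVector w0,
                     double lr, int passes) {
  const int H = X.nrow();
  const int Fr = X.ncol();
  std::vector<double> w(w0.begin(), w0.end());
  NumericVector loss(passes);
  std::vector<int> order(Fr);
  const double* xp = X.begin();
  for (int p = 0; p < passes; ++p) {
    for (int f = 0; f < Fr; ++f) order[f] = f;
    fisher_yates(order);
    double L = 0.0;
    for (int q = 0; q < Fr; ++q) {
      int f = order[q];
      const double* x = xp + (size_t)f * H;
      double s = 0.0;
      for (int i = 0; i < H; ++i) s += w[i] * x[i];
      double y = 1.0 / (1.0 + std::exp(-s));
      double zt = z[f];
      double yc = std::min(std::max(y, 1e-12), 1.0 - 1e-12);
      L += -(zt * std::log(yc) + (1.0 - zt) * std::log(1.0 - yc));
      double g = lr * y * (1.0 - y) * (zt - y);
      if (g != 0.0)
        for (int i = 0; i < H; ++i) w[i] += g * x[i];
    }
    loss[p] = L / Fr;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["loss"] = loss);
}
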