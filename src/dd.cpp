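// Exact integer double description for the flux cone {v >= 0 : S v = 0}.
//
// The cone of the fully irreversible (split) network is intersected with one
// steady-state hyperplane at a time, starting from the non-negative orthant
// (whose extreme rays are the unit flux vectors).  Extreme rays of the final
// cone are exactly the elementary modes of the split network.  All arithmetic
// is in 64-bit integers with 128-bit intermediates and gcd reduction, so
// support minimality tests are exact.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

typedef long long ll;
typedef __int128 lll;

static const ll LLMAX = 4611686018427387903LL; // 2^62 - 1, headroom for sums

static ll gcd_ll(ll a, ll b) {
  if (a < 0) a = -a;
  if (b < 0) b = -b;
  while (b) { ll t = a % b; a = b; b = t; }
  return a;
}

struct Ray {
  std::vector<ll> v;          // flux coordinates, length n
  std::vector<uint64_t> supp; // support bitset over the n columns
};

static inline bool subset(const std::vector<uint64_t>& a,
                          const std::vector<uint64_t>& b) {
  // a subseteq b
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] & ~b[i]) return false;
  return true;
}

static inline int popcount_vec(const std::vector<uint64_t>& a) {
  int c = 0;
  for (uint64_t w : a) c += __builtin_popcountll(w);
  return c;
}

static void make_support(Ray& r, size_t words) {
  r.supp.assign(words, 0);
  for (size_t j = 0; j < r.v.size(); ++j)
    if (r.v[j] != 0) r.supp[j >> 6] |= (uint64_t(1) << (j & 63));
}

static void reduce_ray(Ray& r) {
  ll g = 0;
  for (ll x : r.v) if (x != 0) g = gcd_ll(g, x);
  if (g > 1) for (ll& x : r.v) x /= g;
}

// [[Rcpp::export(name = ".dd_enumerate")]]
NumericMatrix dd_enumerate(IntegerMatrix S, double cap) {
  const int m = S.nrow(), n = S.ncol();
  const size_t words = (n + 63) / 64;

  // process rows by ascending number of nonzeros, ties by row index
  std::vector<int> order(m);
  std::vector<int> nnz(m, 0);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) if (S(i, j) != 0) ++nnz[i];
    order[i] = i;
  }
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return nnz[a] < nnz[b]; });

  std::vector<Ray> rays(n);
  for (int j = 0; j < n; ++j) {
    rays[j].v.assign(n, 0);
    rays[j].v[j] = 1;
    make_support(rays[j], words);
  }

  int processed = 0;
  for (int oi = 0; oi < m; ++oi) {
    int row = order[oi];
    if (nnz[row] == 0) continue;
    ++processed;

    const size_t R = rays.size();
    std::vector<ll> d(R);
    std::vector<int> zero, pos, neg;
    for (size_t k = 0; k < R; ++k) {
      lll acc = 0;
      for (int j = 0; j < n; ++j)
        if (S(row, j) != 0) acc += (lll)S(row, j) * rays[k].v[j];
      if (acc > (lll)LLMAX || acc < -(lll)LLMAX)
        stop("integer overflow in double description step");
      d[k] = (ll)acc;
      if (d[k] == 0) zero.push_back((int)k);
      else if (d[k] > 0) pos.push_back((int)k);
      else neg.push_back((int)k);
    }
    if (pos.empty() && neg.empty()) continue;

    std::vector<Ray> next;
    next.reserve(zero.size() + pos.size() * 2);

    const int supp_bound = processed + 1; // extreme rays after t constraints have |supp| <= t+1
    std::vector<uint64_t> uni(words);
    for (int p : pos) {
      for (int q : neg) {
        for (size_t w = 0; w < words; ++w)
          uni[w] = rays[p].supp[w] | rays[q].supp[w];
        if (popcount_vec(uni) > supp_bound) continue;
        // adjacency: no third ray's support inside the union
        bool adjacent = true;
        for (size_t k = 0; k < R && adjacent; ++k) {
          if ((int)k == p || (int)k == q) continue;
          if (subset(rays[k].supp, uni)) adjacent = false;
        }
        if (!adjacent) continue;
        Ray nr;
        nr.v.assign(n, 0);
        ll a = d[p], b = -d[q]; // both positive; new = b*ray_p + a*ray_q
        ll g = gcd_ll(a, b);
        a /= g; b /= g;
        for (int j = 0; j < n; ++j) {
          lll val = (lll)b * rays[p].v[j] + (lll)a * rays[q].v[j];
          if (val > (lll)LLMAX || val < -(lll)LLMAX)
            stop("integer overflow in double description step");
          nr.v[j] = (ll)val;
        }
        reduce_ray(nr);
        make_support(nr, words);
        next.push_back(std::move(nr));
        if ((double)next.size() > cap)
          stop("mode-count cap exceeded (cap = %.0f, at constraint %d of %d)",
               cap, processed, m);
      }
    }
    for (int k : zero) next.push_back(std::move(rays[k]));
    rays.swap(next);
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(n, (int)rays.size());
  for (size_t k = 0; k < rays.size(); ++k)
    for (int j = 0; j < n; ++j)
      out(j, (int)k) = (double)rays[k].v[j];
  return out;
}
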