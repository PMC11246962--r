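// Gibbs sampler for the STRUCTURE-style admixture model on
// arbitrary-ploidy dosage genotypes.
//
// Model: population allele frequencies P[k][l] ~ Beta(lambda, lambda)
// (independent frequencies across populations and loci); per-accession
// admixture q_i ~ Dirichlet(alpha); each of an accession's ploidy allele
// copies at a locus independently picks a source population from q_i and
// is a B allele with that population's frequency. A dosage call is the
// exact count of B copies; the partition of copies among populations is
// the latent variable sampled here. Missing calls contribute nothing.
//
// RNG: counter-based (splitmix64 sequences keyed by hashed accession and
// marker ids, the sweep index, and a role tag), so draws attached to an
// accession or locus do not depend on row or iteration order; permuting
// the rows of the input permutes the posterior-mean Q rows identically.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t fnv1a(const char *s) {
  uint64_t h = 1469598103934665603ULL;
  while (*s) {
    h ^= (unsigned char)(*s++);
    h *= 1099511628211ULL;
  }
  return h;
}

struct CtrRng {
  uint64_t key, ctr;
  explicit CtrRng(uint64_t k) : key(k), ctr(0) {}
  double unif() {
    uint64_t v = mix64(key + 0x9E3779B97F4A7C15ULL * (++ctr));
    return ((double)(v >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  double gamma(double shape) {
    if (shape < 1.0) {
      double u = unif();
      return gamma(shape + 1.0) * std::pow(u, 1.0 / shape);
    }
    double d = shape - 1.0 / 3.0, c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = normal(), v = 1.0 + c * x;
      if (v <= 0.0) continue;
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v)))
        return d * v;
    }
  }
  double beta(double a, double b) {
    double x = gamma(a), y = gamma(b);
    double s = x + y;
    if (s <= 0.0) return 0.5;
    return x / s;
  }
  int categorical(const double *w, int K) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += w[k];
    if (s <= 0.0) return (int)(unif() * K) % K;
    double u = unif() * s, acc = 0.0;
    for (int k = 0; k < K - 1; ++k) {
      acc += w[k];
      if (u < acc) return k;
    }
    return K - 1;
  }
};

static const uint64_t TAG_Z = 0xA1B2C3D4E5F60718ULL;
static const uint64_t TAG_P = 0x123456789ABCDEF0ULL;
static const uint64_t TAG_Q = 0x0FEDCBA987654321ULL;

// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix dosage, IntegerVector ploidy,
                         CharacterVector acc_ids, CharacterVector marker_ids,
                         int K, double lambda, double alpha,
                         int burn_in, int reps, double seed_in) {
  const int N = dosage.nrow(), M = dosage.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > N) stop("K exceeds the number of accessions");
  if (lambda <= 0.0 || alpha <= 0.0) stop("lambda and alpha must be > 0");
  if (burn_in < 0 || reps < 1) stop("burn_in >= 0 and reps >= 1 required");

  const uint64_t seed = mix64((uint64_t)(int64_t)seed_in ^ 0x5DEECE66DULL);
  std::vector<uint64_t> akey(N), mkey(M);
  for (int i = 0; i < N; ++i)
    akey[i] = mix64(seed ^ fnv1a(CHAR(STRING_ELT(acc_ids, i))));
  for (int l = 0; l < M; ++l)
    mkey[l] = mix64(seed ^ mix64(fnv1a(CHAR(STRING_ELT(marker_ids, l)))));

  // row-major copy of the dosage matrix for cache-friendly locus scans
  std::vector<int> dos((size_t)N * M);
  for (int i = 0; i < N; ++i)
    for (int l = 0; l < M; ++l) dos[(size_t)i * M + l] = dosage(i, l);

  std::vector<double> P((size_t)K * M), Q((size_t)N * K, 1.0 / K);
  // deterministic prior-draw initialisation keyed per (locus, population)
  for (int l = 0; l < M; ++l)
    for (int k = 0; k < K; ++k) {
      CtrRng r(mix64(mkey[l] ^ (TAG_P + 0x9E3779B9ULL * (uint64_t)(k + 1))));
      double p = r.beta(lambda, lambda);
      P[(size_t)l * K + k] = std::min(std::max(p, 1e-9), 1.0 - 1e-9);
    }

  std::vector<double> Qsum((size_t)N * K, 0.0), Qfirst((size_t)N * K, 0.0),
      Qsecond((size_t)N * K, 0.0), Psum((size_t)K * M, 0.0);
  std::vector<int> nB((size_t)K * M), nA((size_t)K * M), ni((size_t)N * K);
  std::vector<double> wB(K), wA(K);
  NumericVector loglik(reps);

  const int total = burn_in + reps;
  const int half = reps / 2;
  for (int s = 1; s <= total; ++s) {
    std::fill(nB.begin(), nB.end(), 0);
    std::fill(nA.begin(), nA.end(), 0);
    std::fill(ni.begin(), ni.end(), 0);
    const uint64_t sweep_tag = mix64(TAG_Z + (uint64_t)s);

    for (int i = 0; i < N; ++i) {
      const int pld = ploidy[i];
      const double *qi = &Q[(size_t)i * K];
      const int *di = &dos[(size_t)i * M];
      for (int l = 0; l < M; ++l) {
        const int g = di[l];
        if (g == NA_INTEGER) continue;
        for (int k = 0; k < K; ++k) {
          const double p = P[(size_t)l * K + k];
          wB[k] = qi[k] * p;
          wA[k] = qi[k] * (1.0 - p);
        }
        CtrRng r(mix64(akey[i] ^ mix64(mkey[l] + sweep_tag)));
        for (int c = 0; c < g; ++c) {
          int k = r.categorical(wB.data(), K);
          ++nB[(size_t)l * K + k];
          ++ni[(size_t)i * K + k];
        }
        for (int c = 0; c < pld - g; ++c) {
          int k = r.categorical(wA.data(), K);
          ++nA[(size_t)l * K + k];
          ++ni[(size_t)i * K + k];
        }
      }
    }

    for (int l = 0; l < M; ++l)
      for (int k = 0; k < K; ++k) {
        CtrRng r(mix64(mkey[l] ^
                       mix64(TAG_P + 0x9E3779B9ULL * (uint64_t)(k + 1) +
                             (uint64_t)s)));
        double p = r.beta(lambda + nB[(size_t)l * K + k],
                          lambda + nA[(size_t)l * K + k]);
        P[(size_t)l * K + k] = std::min(std::max(p, 1e-9), 1.0 - 1e-9);
      }

    for (int i = 0; i < N; ++i) {
      double *qi = &Q[(size_t)i * K];
      if (K == 1) {
        qi[0] = 1.0;
      } else {
        CtrRng r(mix64(akey[i] ^ mix64(TAG_Q + (uint64_t)s)));
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          qi[k] = r.gamma(alpha + ni[(size_t)i * K + k]);
          tot += qi[k];
        }
        if (tot <= 0.0) {
          for (int k = 0; k < K; ++k) qi[k] = 1.0 / K;
        } else {
          for (int k = 0; k < K; ++k) {
            qi[k] /= tot;
            if (qi[k] < 1e-12) qi[k] = 1e-12;
          }
          double renorm = 0.0;
          for (int k = 0; k < K; ++k) renorm += qi[k];
          for (int k = 0; k < K; ++k) qi[k] /= renorm;
        }
      }
    }

    if (s > burn_in) {
      const int rec = s - burn_in;
      double ll = 0.0;
      for (int i = 0; i < N; ++i) {
        const int pld = ploidy[i];
        const double *qi = &Q[(size_t)i * K];
        const int *di = &dos[(size_t)i * M];
        for (int l = 0; l < M; ++l) {
          const int g = di[l];
          if (g == NA_INTEGER) continue;
          double mfreq = 0.0;
          for (int k = 0; k < K; ++k) mfreq += qi[k] * P[(size_t)l * K + k];
          if (mfreq < 1e-12) mfreq = 1e-12;
          if (mfreq > 1.0 - 1e-12) mfreq = 1.0 - 1e-12;
          ll += Rf_lchoose((double)pld, (double)g) + g * std::log(mfreq) +
                (pld - g) * std::log1p(-mfreq);
        }
      }
      loglik[rec - 1] = ll;
      for (size_t t = 0; t < Q.size(); ++t) {
        Qsum[t] += Q[t];
        if (rec <= half) Qfirst[t] += Q[t]; else Qsecond[t] += Q[t];
      }
      for (size_t t = 0; t < P.size(); ++t) Psum[t] += P[t];
    }
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix Qmean(N, K), Qa(N, K), Qb(N, K);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) {
      Qmean(i, k) = Qsum[(size_t)i * K + k] / reps;
      Qa(i, k) = half > 0 ? Qfirst[(size_t)i * K + k] / half : NA_REAL;
      Qb(i, k) = (reps - half) > 0
                     ? Qsecond[(size_t)i * K + k] / (reps - half)
                     : NA_REAL;
    }
  NumericMatrix Pmean(K, M);
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < M; ++l)
      Pmean(k, l) = Psum[(size_t)l * K + k] / reps;

  return List::create(_["Q"] = Qmean, _["P"] = Pmean,
                      _["loglik"] = loglik, _["Q_first_half"] = Qa,
                      _["Q_second_half"] = Qb);
}
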