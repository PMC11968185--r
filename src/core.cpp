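#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Shared two-sex life cycle: adults produce gametes in proportion to their
// sex-specific fecundity, gametes fuse at random, juveniles are regulated to
// a fixed number per sex. The continuum-of-alleles and polygenic engines
// below both follow this cycle; they differ only in how genotypes are stored
// and transmitted.
//
// RNG contract (replayable from R with the same seed): draws are consumed in
// a fixed documented order so that a pure-R mirror of one generation
// reproduces the C++ output exactly. Per offspring:
//   father pick (1 uniform), paternal gamete draws, mother pick (1 uniform),
//   maternal gamete draws. Gamete draws are: start-homolog (1), SDR-interval
//   switch (1, PAR mode only), L-1 adjacent-interval switches, then L
//   mutation tests (each followed by one N(0,1) deviate in the
//   continuum-of-alleles case when the test fires).

struct Landscape {
  int family; // 0 = power, 1 = gaussian
  double theta, Km, Kf, cm, cf, bm, bf, sm, sf;

  double wm(double z) const {
    if (family == 0) {
      double u = (theta - z) / (2.0 * theta);
      return Km * (1.0 - cm * (1.0 - std::pow(u, bm)));
    }
    double d = z + theta; // male optimum at -theta
    return Km * std::exp(-d * d / (2.0 * sm * sm));
  }
  double wf(double z) const {
    if (family == 0) {
      double v = (theta + z) / (2.0 * theta);
      return Kf * (1.0 - cf * (1.0 - std::pow(v, bf)));
    }
    double d = z - theta; // female optimum at +theta
    return Kf * std::exp(-d * d / (2.0 * sf * sf));
  }
};

static Landscape parse_landscape(const List& lp) {
  Landscape L;
  std::string fam = as<std::string>(lp["family"]);
  L.family = (fam == "power") ? 0 : 1;
  L.theta = as<double>(lp["theta"]);
  L.Km = as<double>(lp["K_m"]);
  L.Kf = as<double>(lp["K_f"]);
  if (L.family == 0) {
    L.cm = as<double>(lp["c_m"]);
    L.cf = as<double>(lp["c_f"]);
    L.bm = as<double>(lp["b_m"]);
    L.bf = as<double>(lp["b_f"]);
    L.sm = L.sf = 0.0;
  } else {
    L.sm = as<double>(lp["sigma_m"]);
    L.sf = as<double>(lp["sigma_f"]);
    L.cm = L.cf = L.bm = L.bf = 0.0;
  }
  return L;
}

// first index with cum[i] >= target; cum has length n, strictly reaches total
static int pick_parent(const std::vector<double>& cum, double total) {
  double target = unif_rand() * total;
  std::vector<double>::const_iterator it =
    std::lower_bound(cum.begin(), cum.end(), target);
  if (it == cum.end()) return (int)cum.size() - 1;
  return (int)(it - cum.begin());
}

// ---------------------------------------------------------------------------
// Continuum-of-alleles engine: one additive autosomal locus, allelic values
// clamped to [-theta/2, theta/2].
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".coa_chunk")]]
List coa_chunk(NumericVector x1, NumericVector x2, int n_male,
               int n_gens, double mu, double kernel_sd, List lp_in) {
  const int N = x1.size();
  if (n_male <= 0 || n_male >= N)
    stop("need at least one adult of each sex");
  Landscape lp = parse_landscape(lp_in);
  const double half = lp.theta / 2.0;

  std::vector<double> a1(x1.begin(), x1.end()), a2(x2.begin(), x2.end());
  std::vector<double> b1(N), b2(N);
  std::vector<double> cumm(n_male), cumf(N - n_male);
  NumericVector mean_wm(n_gens), mean_wf(n_gens);

  for (int g = 0; g < n_gens; ++g) {
    // fecundities of current adults (males are 0..n_male-1 by convention)
    double tm = 0.0, tf = 0.0;
    for (int i = 0; i < n_male; ++i) {
      double w = lp.wm(a1[i] + a2[i]);
      if (w < 0) w = 0;
      tm += w;
      cumm[i] = tm;
    }
    for (int i = n_male; i < N; ++i) {
      double w = lp.wf(a1[i] + a2[i]);
      if (w < 0) w = 0;
      tf += w;
      cumf[i - n_male] = tf;
    }
    if (!(tm > 0.0) || !(tf > 0.0))
      stop("extinction: all fecundities are zero in one sex (generation %d)",
           g + 1);
    mean_wm[g] = tm / n_male;
    mean_wf[g] = tf / (N - n_male);

    for (int i = 0; i < N; ++i) {
      int dad = pick_parent(cumm, tm);
      double al = (unif_rand() < 0.5) ? a1[dad] : a2[dad];
      if (unif_rand() < mu) al += norm_rand() * kernel_sd;
      if (al > half) al = half;
      if (al < -half) al = -half;
      b1[i] = al;

      int mom = n_male + pick_parent(cumf, tf);
      al = (unif_rand() < 0.5) ? a1[mom] : a2[mom];
      if (unif_rand() < mu) al += norm_rand() * kernel_sd;
      if (al > half) al = half;
      if (al < -half) al = -half;
      b2[i] = al;
    }
    std::swap(a1, b1);
    std::swap(a2, b2);
  }

  return List::create(_["x1"] = NumericVector(a1.begin(), a1.end()),
                      _["x2"] = NumericVector(a2.begin(), a2.end()),
                      _["mean_wm"] = mean_wm, _["mean_wf"] = mean_wf);
}

// ---------------------------------------------------------------------------
// Polygenic diallelic engine. Haplotypes are 0/1 rows (1 = trait-increasing
// allele A); h1 is the paternally and h2 the maternally inherited homolog.
// Modes: 0 autosome, 1 X-hemizygous, 2 PAR. In X mode a male's single X is
// mirrored into both homolog slots so the phenotype map (each allele counted
// twice) is uniform; in PAR mode sdr1/sdr2 carry the sex-determining allele
// (0 = X, 1 = Y) linked to the locus block at recombination rate r_sdr.
// ---------------------------------------------------------------------------

struct Arch {
  int L;
  std::vector<double> delta;
  double mu, r_adj, r_sdr;
  int mode; // 0 autosome, 1 x_hemizygous, 2 par
};

static Arch parse_arch(const List& arch_in) {
  Arch a;
  a.L = as<int>(arch_in["L"]);
  NumericVector d = arch_in["delta"];
  a.delta.assign(d.begin(), d.end());
  a.mu = as<double>(arch_in["mu"]);
  a.r_adj = as<double>(arch_in["r_adjacent"]);
  a.r_sdr = as<double>(arch_in["r_sdr"]);
  std::string m = as<std::string>(arch_in["mode"]);
  a.mode = (m == "autosome") ? 0 : (m == "x_hemizygous") ? 1 : 2;
  return a;
}

static double phen(const std::vector<int>& g1, const std::vector<int>& g2,
                   int row, const Arch& a) {
  double z = 0.0;
  int off = row * a.L;
  for (int k = 0; k < a.L; ++k)
    z += 2.0 * (g1[off + k] + g2[off + k] - 1) * a.delta[k];
  return z;
}

// recombinant gamete with SDR tracking; consumes the documented draw order
static void gamete(const std::vector<int>& g1, const std::vector<int>& g2,
                   int row, int sdr1, int sdr2, const Arch& a, bool par,
                   std::vector<int>& out, int out_row, int* out_sdr) {
  int off = row * a.L, ooff = out_row * a.L;
  int cur = (unif_rand() < 0.5) ? 0 : 1; // start homolog
  if (par) {
    *out_sdr = cur == 0 ? sdr1 : sdr2;
    if (unif_rand() < a.r_sdr) cur = 1 - cur;
  }
  for (int k = 0; k < a.L; ++k) {
    if (k > 0 && unif_rand() < a.r_adj) cur = 1 - cur;
    out[ooff + k] = cur == 0 ? g1[off + k] : g2[off + k];
  }
  for (int k = 0; k < a.L; ++k)
    if (unif_rand() < a.mu) out[ooff + k] = 1 - out[ooff + k];
}

// hemizygous transmission: father's single X, mutation only
static void gamete_x(const std::vector<int>& g, int row, const Arch& a,
                     std::vector<int>& out, int out_row) {
  int off = row * a.L, ooff = out_row * a.L;
  for (int k = 0; k < a.L; ++k) {
    int al = g[off + k];
    if (unif_rand() < a.mu) al = 1 - al;
    out[ooff + k] = al;
  }
}

// [[Rcpp::export(name = ".wf_chunk")]]
List wf_chunk(IntegerMatrix h1_in, IntegerMatrix h2_in,
              IntegerVector sdr1_in, IntegerVector sdr2_in, int n_male,
              int n_gens, List arch_in, List lp_in, bool record_parentage) {
  Arch a = parse_arch(arch_in);
  Landscape lp = parse_landscape(lp_in);
  const int N = h1_in.nrow(), L = a.L;
  if (h1_in.ncol() != L || h2_in.ncol() != L) stop("haplotype matrix shape");
  if (n_male <= 0 || n_male >= N)
    stop("need at least one adult of each sex");

  // row-major copies for locality
  std::vector<int> g1((size_t)N * L), g2((size_t)N * L);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < L; ++k) {
      g1[(size_t)i * L + k] = h1_in(i, k);
      g2[(size_t)i * L + k] = h2_in(i, k);
    }
  std::vector<int> s1(sdr1_in.begin(), sdr1_in.end()),
      s2(sdr2_in.begin(), sdr2_in.end());
  std::vector<int> n1(g1.size()), n2(g2.size()), t1(N), t2(N);
  std::vector<double> cumm(n_male), cumf(N - n_male), w(N);
  NumericVector mean_wm(n_gens), mean_wf(n_gens);
  IntegerVector entry_count(record_parentage ? N : 0);
  NumericVector entry_w(record_parentage ? N : 0);

  for (int g = 0; g < n_gens; ++g) {
    double tm = 0.0, tf = 0.0;
    for (int i = 0; i < N; ++i) {
      double z = phen(g1, g2, i, a);
      double wi = (i < n_male) ? lp.wm(z) : lp.wf(z);
      if (wi < 0) wi = 0;
      w[i] = wi;
      if (i < n_male) {
        tm += wi;
        cumm[i] = tm;
      } else {
        tf += wi;
        cumf[i - n_male] = tf;
      }
    }
    if (!(tm > 0.0) || !(tf > 0.0))
      stop("extinction: all fecundities are zero in one sex (generation %d)",
           g + 1);
    mean_wm[g] = tm / n_male;
    mean_wf[g] = tf / (N - n_male);
    bool rec = record_parentage && g == 0;
    if (rec)
      for (int i = 0; i < N; ++i) entry_w[i] = w[i];

    if (a.mode == 2) {
      // PAR: paternal gamete's SDR allele determines zygote sex; zygotes are
      // drawn until each sex's quota is filled (rejection once one is full)
      int got_m = 0, got_f = 0;
      long guard = 0, guard_max = 10000L * (long)N;
      while (got_m < n_male || got_f < N - n_male) {
        if (++guard > guard_max)
          stop("PAR zygote sampling failed to fill sex quotas");
        int dad = pick_parent(cumm, tm);
        int mom = n_male + pick_parent(cumf, tf);
        int psdr = 0, msdr = 0;
        gamete(g1, g2, dad, s1[dad], s2[dad], a, true, n1, N - 1, &psdr);
        gamete(g1, g2, mom, s1[mom], s2[mom], a, true, n2, N - 1, &msdr);
        int slot;
        if (psdr == 1) { // Y-bearing sperm -> son
          if (got_m >= n_male) continue;
          slot = got_m++;
        } else {
          if (got_f >= N - n_male) continue;
          slot = n_male + got_f++;
        }
        // move the scratch rows (written at N-1) into the accepted slot
        if (slot != N - 1) {
          std::copy(n1.begin() + (size_t)(N - 1) * L,
                    n1.begin() + (size_t)N * L, n1.begin() + (size_t)slot * L);
          std::copy(n2.begin() + (size_t)(N - 1) * L,
                    n2.begin() + (size_t)N * L, n2.begin() + (size_t)slot * L);
        }
        t1[slot] = psdr;
        t2[slot] = msdr;
        if (rec) {
          entry_count[dad]++;
          entry_count[mom]++;
        }
      }
    } else {
      for (int i = 0; i < N; ++i) {
        bool male_off = i < n_male;
        int dad = pick_parent(cumm, tm);
        int sdr_dummy;
        if (a.mode == 0) {
          gamete(g1, g2, dad, 0, 0, a, false, n1, i, &sdr_dummy);
        } else {
          // X mode: daughters get the paternal X (no crossover in the
          // hemizygous father); sons inherit no paternal copy here
          if (!male_off) gamete_x(g1, dad, a, n1, i);
        }
        int mom = n_male + pick_parent(cumf, tf);
        gamete(g1, g2, mom, 0, 0, a, false, n2, i, &sdr_dummy);
        if (a.mode == 1 && male_off) {
          // mirror the single maternal X into both slots (dosage doubling)
          std::copy(n2.begin() + (size_t)i * L, n2.begin() + (size_t)(i + 1) * L,
                    n1.begin() + (size_t)i * L);
        }
        t1[i] = 0;
        t2[i] = 0;
        if (rec) {
          entry_count[dad]++;
          entry_count[mom]++;
        }
      }
    }
    std::swap(g1, n1);
    std::swap(g2, n2);
    std::swap(s1, t1);
    std::swap(s2, t2);
  }

  IntegerMatrix o1(N, L), o2(N, L);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < L; ++k) {
      o1(i, k) = g1[(size_t)i * L + k];
      o2(i, k) = g2[(size_t)i * L + k];
    }
  return List::create(
      _["h1"] = o1, _["h2"] = o2,
      _["sdr1"] = IntegerVector(s1.begin(), s1.end()),
      _["sdr2"] = IntegerVector(s2.begin(), s2.end()),
      _["mean_wm"] = mean_wm, _["mean_wf"] = mean_wf,
      _["entry_count"] = entry_count, _["entry_w"] = entry_w);
}
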