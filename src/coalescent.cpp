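// Structured-coalescent simulator for a fixed three-deme topology
// ((chilensis, pallatangae), albiceps) with epoch-limited migration.
//
// Deme indices: 0 = chilensis (C), 1 = pallatangae (P), 2 = albiceps (A).
// Backward in time: at tCP all lineages in P move to C (the C+P ancestor
// keeps C's size); at tA all lineages move to A (the root keeps A's size).
// Migration is active only on [migStart, tCP) and only between terminal
// demes; rates are backward per-lineage per-generation probabilities.
//
// All randomness goes through R's RNG (unif_rand / exp_rand / Rf_rpois) so
// results are reproducible from set.seed().

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <map>
using namespace Rcpp;

namespace {

struct SimTree {
  int n;                     // number of sampled gene copies (leaves 0..n-1)
  std::vector<int> parent;   // size 2n-1; -1 at the root
  std::vector<double> ntime; // node times in generations (leaves at 0)
};

SimTree simulate_tree(const std::vector<int>& leaf_deme,
                      const double sizes[3],
                      double t_cp, double t_a,
                      const double mig[3][3],
                      double mig_start)
{
  const int n = (int)leaf_deme.size();
  SimTree tr;
  tr.n = n;
  tr.parent.assign(2 * n - 1, -1);
  tr.ntime.assign(2 * n - 1, 0.0);

  std::vector<int> act;   // active node ids
  std::vector<int> deme;  // deme of each active lineage
  act.reserve(n); deme.reserve(n);
  for (int i = 0; i < n; ++i) { act.push_back(i); deme.push_back(leaf_deme[i]); }

  double rowrate[3];
  bool mig_any = false;
  for (int i = 0; i < 3; ++i) {
    rowrate[i] = 0.0;
    for (int j = 0; j < 3; ++j) rowrate[i] += mig[i][j];
    if (rowrate[i] > 0.0) mig_any = true;
  }

  int next_node = n;
  double t = 0.0;

  while ((int)act.size() > 1) {
    double t_end;
    if (t < mig_start && mig_start < t_cp) t_end = mig_start;
    else if (t < t_cp) t_end = t_cp;
    else if (t < t_a) t_end = t_a;
    else t_end = R_PosInf;

    int k[3] = {0, 0, 0};
    for (size_t i = 0; i < act.size(); ++i) k[deme[i]]++;

    const bool mig_on = mig_any && t >= mig_start && t < t_cp;

    double crate[3], ctot = 0.0;
    for (int d = 0; d < 3; ++d) {
      crate[d] = (k[d] > 1) ? 0.5 * k[d] * (k[d] - 1.0) / sizes[d] : 0.0;
      ctot += crate[d];
    }
    double mtot = 0.0;
    if (mig_on) for (int d = 0; d < 3; ++d) mtot += k[d] * rowrate[d];

    const double rate = ctot + mtot;
    const double dt = (rate > 0.0) ? exp_rand() / rate : R_PosInf;

    if (t + dt >= t_end) {
      t = t_end;
      if (t == t_cp) {
        for (size_t i = 0; i < deme.size(); ++i) if (deme[i] == 1) deme[i] = 0;
      } else if (t == t_a) {
        for (size_t i = 0; i < deme.size(); ++i) deme[i] = 2;
      }
      continue; // hitting migStart merely switches migration on
    }
    t += dt;

    double u = unif_rand() * rate;
    if (u < ctot) {
      // coalescence: choose deme, then an unordered pair within it
      int d = 0; double acc = crate[0];
      while (u >= acc && d < 2) { ++d; acc += crate[d]; }
      int i1 = (int)(unif_rand() * k[d]); if (i1 >= k[d]) i1 = k[d] - 1;
      int i2 = (int)(unif_rand() * (k[d] - 1)); if (i2 >= k[d] - 1) i2 = k[d] - 2;
      if (i2 >= i1) ++i2;
      int p1 = -1, p2 = -1, seen = 0;
      for (size_t i = 0; i < act.size(); ++i) if (deme[i] == d) {
        if (seen == i1) p1 = (int)i;
        if (seen == i2) p2 = (int)i;
        ++seen;
      }
      const int a = act[p1], b = act[p2];
      const int node = next_node++;
      tr.parent[a] = node; tr.parent[b] = node; tr.ntime[node] = t;
      act[p1] = node;
      act.erase(act.begin() + p2);
      deme.erase(deme.begin() + p2);
    } else {
      // migration: lineage weighted by its deme's row rate, then destination
      u -= ctot;
      int pos = (int)act.size() - 1; double acc = 0.0;
      for (size_t i = 0; i < act.size(); ++i) {
        acc += rowrate[deme[i]];
        if (u < acc) { pos = (int)i; break; }
      }
      const int from = deme[pos];
      double v = unif_rand() * rowrate[from];
      int to = 0; double a2 = mig[from][0];
      while (v >= a2 && to < 2) { ++to; a2 += mig[from][to]; }
      deme[pos] = to;
    }
  }
  return tr;
}

void unpack_mig(const NumericVector& m9, double mig[3][3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      mig[i][j] = m9[3 * i + j];
}

// per-pop leaf counts under each node; child ids always precede parents
void subtree_pop_counts(const SimTree& tr, const std::vector<int>& leaf_pop,
                        std::vector<int>& cnt /* (2n-1) x 3 flat */)
{
  const int nn = 2 * tr.n - 1;
  cnt.assign(nn * 3, 0);
  for (int i = 0; i < tr.n; ++i) cnt[3 * i + leaf_pop[i]] = 1;
  for (int v = 0; v < nn - 1; ++v) {
    const int p = tr.parent[v];
    for (int q = 0; q < 3; ++q) cnt[3 * p + q] += cnt[3 * v + q];
  }
}

struct LocusAcc {
  // raw per-locus accumulators over mutations
  double Sp[3] = {0, 0, 0};
  double pi_sum[3] = {0, 0, 0};  // sum over sites of d*(n-d)
  double Stot = 0;
  double d_sum[3] = {0, 0, 0};   // pairs (C,P), (C,A), (P,A)
};

const int PAIR_I[3] = {0, 0, 1};
const int PAIR_J[3] = {1, 2, 2};

void add_site(LocusAcc& acc, const int d[3], const int np[3]) {
  int dtot = d[0] + d[1] + d[2];
  int ntot = np[0] + np[1] + np[2];
  if (dtot > 0 && dtot < ntot) acc.Stot += 1;
  for (int p = 0; p < 3; ++p) {
    if (np[p] >= 2) {
      if (d[p] > 0 && d[p] < np[p]) acc.Sp[p] += 1;
      acc.pi_sum[p] += (double)d[p] * (np[p] - d[p]);
    }
  }
  for (int q = 0; q < 3; ++q) {
    const int a = PAIR_I[q], b = PAIR_J[q];
    if (np[a] >= 1 && np[b] >= 1)
      acc.d_sum[q] += (double)d[a] * (np[b] - d[b]) + (double)(np[a] - d[a]) * d[b];
  }
}

// simulate one locus and accumulate mutation-site statistics;
// returns per-locus values: S_p (3), pi_p (3), S_tot, d_pq (3); NaN = undefined
void sim_locus_stats(const std::vector<int>& leaf_deme, const double sizes[3],
                     double t_cp, double t_a, const double mig[3][3],
                     double mig_start, double theta_locus, int L,
                     double out[10], long& fallback_count)
{
  const int n = (int)leaf_deme.size();
  SimTree tr = simulate_tree(leaf_deme, sizes, t_cp, t_a, mig, mig_start);

  int np[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i) np[leaf_deme[i]]++;

  std::vector<double> cum(2 * n - 2);
  double tot = 0.0;
  for (int v = 0; v < 2 * n - 2; ++v) {
    tot += tr.ntime[tr.parent[v]] - tr.ntime[v];
    cum[v] = tot;
  }
  const int nmut = (int)R::rpois(tot * theta_locus);

  LocusAcc acc;
  if (nmut > 0) {
    std::vector<int> cnt;
    subtree_pop_counts(tr, leaf_deme, cnt);
    if (nmut <= L) {
      // infinite-sites: every mutation is its own biallelic column
      for (int m = 0; m < nmut; ++m) {
        const double u = unif_rand() * tot;
        const int v = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
        const int d[3] = {cnt[3 * v], cnt[3 * v + 1], cnt[3 * v + 2]};
        add_site(acc, d, np);
      }
    } else {
      // finite-sites fallback: repeated hits at one site toggle the allele
      ++fallback_count;
      std::map<int, std::vector<int> > by_site;
      for (int m = 0; m < nmut; ++m) {
        const double u = unif_rand() * tot;
        const int v = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
        int s = (int)(unif_rand() * L); if (s >= L) s = L - 1;
        by_site[s].push_back(v);
      }
      std::vector<std::vector<int> > children(2 * n - 1);
      for (int v = 0; v < 2 * n - 2; ++v) children[tr.parent[v]].push_back(v);
      std::vector<char> state(n);
      std::vector<int> stack;
      for (std::map<int, std::vector<int> >::const_iterator it = by_site.begin();
           it != by_site.end(); ++it) {
        std::fill(state.begin(), state.end(), 0);
        for (size_t b = 0; b < it->second.size(); ++b) {
          stack.clear(); stack.push_back(it->second[b]);
          while (!stack.empty()) {
            const int v = stack.back(); stack.pop_back();
            if (v < n) state[v] ^= 1;
            else for (size_t c = 0; c < children[v].size(); ++c)
              stack.push_back(children[v][c]);
          }
        }
        int d[3] = {0, 0, 0};
        for (int i = 0; i < n; ++i) if (state[i]) d[leaf_deme[i]]++;
        add_site(acc, d, np);
      }
    }
  }

  for (int p = 0; p < 3; ++p) {
    if (np[p] >= 2) {
      out[p] = acc.Sp[p];
      out[3 + p] = acc.pi_sum[p] / (0.5 * np[p] * (np[p] - 1.0));
    } else {
      out[p] = R_NaN; out[3 + p] = R_NaN;
    }
  }
  out[6] = (n >= 2) ? acc.Stot : R_NaN;
  for (int q = 0; q < 3; ++q) {
    const int a = PAIR_I[q], b = PAIR_J[q];
    out[7 + q] = (np[a] >= 1 && np[b] >= 1)
      ? acc.d_sum[q] / ((double)np[a] * np[b]) : R_NaN;
  }
}

// aggregate per-locus raw stats into the 13-component StatVector:
// means across loci where defined; FST as 1 - mean(piw)/mean(pib), 0 when
// mean between-diversity is 0, clamped to [-1, 1]
void aggregate_stats(const std::vector<std::array<double, 10> >& per_locus,
                     double out[13])
{
  double sum[10] = {0}; int cnt[10] = {0};
  double piw_sum[3] = {0, 0, 0}, pib_sum[3] = {0, 0, 0};
  int fst_cnt[3] = {0, 0, 0};
  for (size_t l = 0; l < per_locus.size(); ++l) {
    const std::array<double, 10>& x = per_locus[l];
    for (int j = 0; j < 10; ++j)
      if (!ISNAN(x[j])) { sum[j] += x[j]; cnt[j]++; }
    for (int q = 0; q < 3; ++q) {
      const int a = PAIR_I[q], b = PAIR_J[q];
      if (!ISNAN(x[3 + a]) && !ISNAN(x[3 + b]) && !ISNAN(x[7 + q])) {
        piw_sum[q] += 0.5 * (x[3 + a] + x[3 + b]);
        pib_sum[q] += x[7 + q];
        fst_cnt[q]++;
      }
    }
  }
  for (int j = 0; j < 10; ++j)
    out[j] = (cnt[j] > 0) ? sum[j] / cnt[j] : R_NaN;
  for (int q = 0; q < 3; ++q) {
    if (fst_cnt[q] == 0) { out[10 + q] = R_NaN; continue; }
    const double pib = pib_sum[q] / fst_cnt[q];
    if (pib <= 0.0) { out[10 + q] = 0.0; continue; }
    double f = 1.0 - (piw_sum[q] / fst_cnt[q]) / pib;
    if (f > 1.0) f = 1.0;
    if (f < -1.0) f = -1.0;
    out[10 + q] = f;
  }
}

std::vector<int> expand_leaf_deme(const IntegerMatrix& counts, int locus) {
  std::vector<int> leaf;
  for (int d = 0; d < 3; ++d)
    for (int i = 0; i < counts(locus, d); ++i) leaf.push_back(d);
  return leaf;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(IntegerVector leafDeme, NumericVector sizes,
                       double tCP, double tA, NumericVector mig9,
                       double migStart)
{
  std::vector<int> leaf(leafDeme.begin(), leafDeme.end());
  double mig[3][3]; unpack_mig(mig9, mig);
  double sz[3] = {sizes[0], sizes[1], sizes[2]};
  SimTree tr = simulate_tree(leaf, sz, tCP, tA, mig, migStart);
  const int nn = 2 * tr.n - 1;
  IntegerVector parent(nn);
  NumericVector ntime(nn);
  for (int v = 0; v < nn; ++v) {
    parent[v] = (tr.parent[v] < 0) ? NA_INTEGER : tr.parent[v] + 1;
    ntime[v] = tr.ntime[v];
  }
  return List::create(_["parent"] = parent, _["nodeTime"] = ntime,
                      _["nLeaves"] = tr.n);
}

//' @noRd
// [[Rcpp::export(name = ".build_reference_cpp")]]
NumericMatrix build_reference_cpp(NumericMatrix demo, NumericMatrix migs,
                                  NumericVector migStart, IntegerMatrix counts,
                                  NumericVector lociLen, NumericVector muSite,
                                  NumericVector ploidy)
{
  const int nsim = demo.nrow();
  const int nloci = counts.nrow();
  NumericMatrix out(nsim, 13);

  std::vector<std::vector<int> > leaves(nloci);
  for (int l = 0; l < nloci; ++l) leaves[l] = expand_leaf_deme(counts, l);
  long fallback = 0;

  for (int r = 0; r < nsim; ++r) {
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
    double mig[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) mig[i][j] = migs(r, 3 * i + j);
    std::vector<std::array<double, 10> > per_locus(nloci);
    for (int l = 0; l < nloci; ++l) {
      // demo columns: N_C, N_P, N_A (individuals), T_CP, T_A
      double sz[3] = {ploidy[l] * demo(r, 0), ploidy[l] * demo(r, 1),
                      ploidy[l] * demo(r, 2)};
      double st[10];
      sim_locus_stats(leaves[l], sz, demo(r, 3), demo(r, 4), mig,
                      migStart[r], muSite[l] * lociLen[l], (int)lociLen[l], st,
                      fallback);
      for (int j = 0; j < 10; ++j) per_locus[l][j] = st[j];
    }
    double agg[13];
    aggregate_stats(per_locus, agg);
    for (int j = 0; j < 13; ++j) out(r, j) = agg[j];
  }
  if (fallback > 0)
    Rf_warning("finite-sites fallback (mutation count exceeded locus length) "
               "in %ld locus simulations", fallback);
  return out;
}
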