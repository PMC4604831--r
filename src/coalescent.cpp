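// Structured-coalescent core: event-driven simulation of gene genealogies
// embedded in an epoch-wise demography (per-population Ne, backward-in-time
// per-lineage migration rates, population merges at species splits),
// infinite-sites mutation dropping, and branch-ratio accumulation for
// expected joint site-frequency spectra.
//
// Time unit: generations. Ne: diploid individuals, so the pairwise
// coalescence rate within a population of size N is 1/(2N).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Demog {
  int P;                                        // number of population slots
  std::vector<double> epoch_end;                // end time of each epoch (last = Inf)
  std::vector< std::vector<double> > ne;        // [epoch][pop], <=0 means inactive
  std::vector< std::vector<double> > mig;       // [epoch][i*P+j] per-lineage rate i->j
  std::vector< std::vector< std::pair<int,int> > > merges; // applied on entering epoch e
};

Demog unpack_demog(const List& epochs) {
  Demog D;
  NumericVector end = epochs["end"];
  NumericMatrix nem = epochs["ne"];
  List migl = epochs["mig"];
  List mergel = epochs["merges"];
  int E = end.size();
  D.P = nem.ncol();
  D.epoch_end.assign(end.begin(), end.end());
  D.ne.resize(E);
  D.mig.resize(E);
  D.merges.resize(E);
  for (int e = 0; e < E; ++e) {
    D.ne[e].resize(D.P);
    for (int p = 0; p < D.P; ++p) D.ne[e][p] = nem(e, p);
    NumericMatrix m = migl[e];
    D.mig[e].assign(D.P * D.P, 0.0);
    for (int i = 0; i < D.P; ++i)
      for (int j = 0; j < D.P; ++j)
        D.mig[e][i * D.P + j] = m(i, j);
    IntegerMatrix mg = mergel[e];
    for (int r = 0; r < mg.nrow(); ++r)
      D.merges[e].push_back(std::make_pair(mg(r, 0), mg(r, 1)));
  }
  return D;
}

// Simulate one genealogy. lin_pop0: 0-based population of each sampled
// lineage. Fills parent (length 2n-1, root = -1) and node times.
void simulate_tree(const Demog& D, const std::vector<int>& lin_pop0,
                   std::vector<int>& parent, std::vector<double>& tnode) {
  const int n = (int)lin_pop0.size();
  const int P = D.P;
  parent.assign(2 * n - 1, -1);
  tnode.assign(2 * n - 1, 0.0);

  std::vector<int> act(n);        // active node ids
  std::vector<int> pop(n);        // population of each active lineage
  for (int i = 0; i < n; ++i) { act[i] = i; pop[i] = lin_pop0[i]; }
  int k = n;                      // number of active lineages
  int next_id = n;
  double t = 0.0;
  int e = 0;
  const int E = (int)D.epoch_end.size();

  std::vector<int> cnt(P);
  std::vector<double> coalr(P), migrow(P);

  int guard = 0;
  while (k > 1) {
    if (++guard > 100000000) stop("coalescent simulation failed to terminate");
    const std::vector<double>& ne = D.ne[e];
    const std::vector<double>& mg = D.mig[e];
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < k; ++i) cnt[pop[i]]++;
    double ctot = 0.0, mtot = 0.0;
    for (int p = 0; p < P; ++p) {
      double r = 0.0;
      if (cnt[p] > 1) {
        if (ne[p] <= 0.0) stop("lineages present in an inactive population");
        r = cnt[p] * (cnt[p] - 1) / 2.0 / (2.0 * ne[p]);
      }
      coalr[p] = r; ctot += r;
      double mr = 0.0;
      for (int j = 0; j < P; ++j) mr += mg[p * P + j];
      migrow[p] = mr;
      mtot += cnt[p] * mr;
    }
    double tot = ctot + mtot;
    double dt = (tot > 0.0) ? exp_rand() / tot : R_PosInf;
    if (t + dt >= D.epoch_end[e]) {
      if (e >= E - 1) stop("no event possible in final epoch: invalid demography");
      t = D.epoch_end[e];
      ++e;
      for (size_t m = 0; m < D.merges[e].size(); ++m) {
        int from = D.merges[e][m].first, to = D.merges[e][m].second;
        for (int i = 0; i < k; ++i) if (pop[i] == from) pop[i] = to;
      }
      continue;
    }
    t += dt;
    double u = unif_rand() * tot;
    if (u < ctot) {
      int p = 0;
      while (u >= coalr[p]) { u -= coalr[p]; ++p; }
      // pick two distinct lineages in pop p
      int a = (int)std::floor(unif_rand() * cnt[p]);
      int b = (int)std::floor(unif_rand() * (cnt[p] - 1));
      if (b >= a) ++b;
      int ia = -1, ib = -1, seen = 0;
      for (int i = 0; i < k; ++i) if (pop[i] == p) {
        if (seen == a) ia = i;
        if (seen == b) ib = i;
        ++seen;
      }
      int id = next_id++;
      parent[act[ia]] = id;
      parent[act[ib]] = id;
      tnode[id] = t;
      act[ia] = id;                 // replace ia by the new ancestor
      act[ib] = act[k - 1]; pop[ib] = pop[k - 1];
      --k;
    } else {
      u -= ctot;
      // migration: walk lineages
      int il = -1, dest = -1;
      for (int i = 0; i < k && il < 0; ++i) {
        double mr = migrow[pop[i]];
        if (u < mr) {
          for (int j = 0; j < P; ++j) {
            double r = mg[pop[i] * P + j];
            if (u < r) { il = i; dest = j; break; }
            u -= r;
          }
        } else u -= mr;
      }
      if (il < 0) continue;         // numerical slip; redraw
      pop[il] = dest;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List sim_coal_batch_cpp(IntegerVector lin_pop, List epochs, int n_rep) {
  Demog D = unpack_demog(epochs);
  int n = lin_pop.size();
  if (n < 2) stop("need at least two sampled lineages");
  std::vector<int> lp(lin_pop.begin(), lin_pop.end());
  IntegerMatrix parents(n_rep, 2 * n - 1);
  NumericMatrix times(n_rep, 2 * n - 1);
  std::vector<int> par; std::vector<double> tn;
  for (int r = 0; r < n_rep; ++r) {
    simulate_tree(D, lp, par, tn);
    for (int v = 0; v < 2 * n - 1; ++v) {
      parents(r, v) = par[v];
      times(r, v) = tn[v];
    }
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["parent"] = parents, _["time"] = times);
}

// Expected-SFS machinery: average over genealogies of the relative branch
// length subtending exactly (i, j) sampled tips of a species pair, for each
// requested pair, plus the mean total tree length.
// [[Rcpp::export]]
List sfs_expect_cpp(IntegerVector lin_pop, List epochs, IntegerVector species,
                    int n_species, IntegerVector pairA, IntegerVector pairB,
                    int n_rep) {
  Demog D = unpack_demog(epochs);
  int n = lin_pop.size();
  std::vector<int> lp(lin_pop.begin(), lin_pop.end());
  int npair = pairA.size();
  std::vector<int> nsamp(n_species, 0);
  for (int i = 0; i < n; ++i) nsamp[species[i]]++;
  std::vector<NumericMatrix> acc, accl;
  for (int q = 0; q < npair; ++q) {
    acc.push_back(NumericMatrix(nsamp[pairA[q]] + 1, nsamp[pairB[q]] + 1));
    accl.push_back(NumericMatrix(nsamp[pairA[q]] + 1, nsamp[pairB[q]] + 1));
  }
  double tot_len_acc = 0.0;
  std::vector<int> par; std::vector<double> tn;
  int nn = 2 * n - 1;
  std::vector<int> cnt(nn * n_species);
  for (int r = 0; r < n_rep; ++r) {
    simulate_tree(D, lp, par, tn);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) cnt[i * n_species + species[i]] = 1;
    double tot = 0.0;
    for (int v = 0; v < nn - 1; ++v) {
      int p = par[v];
      for (int s = 0; s < n_species; ++s)
        cnt[p * n_species + s] += cnt[v * n_species + s];
      tot += tn[p] - tn[v];
    }
    for (int v = 0; v < nn - 1; ++v) {
      double len = tn[par[v]] - tn[v];
      for (int q = 0; q < npair; ++q) {
        int ia = cnt[v * n_species + pairA[q]], jb = cnt[v * n_species + pairB[q]];
        acc[q](ia, jb) += len / tot;
        accl[q](ia, jb) += len;
      }
    }
    tot_len_acc += tot;
    if ((r & 255) == 0) Rcpp::checkUserInterrupt();
  }
  List out(npair), outl(npair);
  for (int q = 0; q < npair; ++q) {
    NumericMatrix m = acc[q], ml = accl[q];
    for (int i = 0; i < m.nrow(); ++i)
      for (int j = 0; j < m.ncol(); ++j) {
        m(i, j) /= n_rep;
        ml(i, j) /= n_rep;
      }
    out[q] = m;
    outl[q] = ml;
  }
  return List::create(_["ratio"] = out, _["mean_length"] = outl,
                      _["mean_total_length"] = tot_len_acc / n_rep);
}

// Simulate observed joint SFS counts over independent windows: one genealogy
// per window, Poisson(mu * L * total length) mutations placed uniformly on
// branches; each mutation contributes a derived-allele configuration to every
// requested species pair. Cell (0,0) receives all remaining monomorphic sites.
// [[Rcpp::export]]
List obs_sfs_cpp(IntegerVector lin_pop, List epochs, IntegerVector species,
                 int n_species, IntegerVector pairA, IntegerVector pairB,
                 int n_windows, int L, double mu) {
  Demog D = unpack_demog(epochs);
  int n = lin_pop.size();
  std::vector<int> lp(lin_pop.begin(), lin_pop.end());
  int npair = pairA.size();
  std::vector<int> nsamp(n_species, 0);
  for (int i = 0; i < n; ++i) nsamp[species[i]]++;
  std::vector<NumericMatrix> acc;
  for (int q = 0; q < npair; ++q)
    acc.push_back(NumericMatrix(nsamp[pairA[q]] + 1, nsamp[pairB[q]] + 1));
  double n_mut_total = 0.0;
  std::vector<int> par; std::vector<double> tn;
  int nn = 2 * n - 1;
  std::vector<int> cnt(nn * n_species);
  std::vector<double> cum(nn - 1);
  for (int w = 0; w < n_windows; ++w) {
    simulate_tree(D, lp, par, tn);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) cnt[i * n_species + species[i]] = 1;
    double tot = 0.0;
    for (int v = 0; v < nn - 1; ++v) {
      int p = par[v];
      for (int s = 0; s < n_species; ++s)
        cnt[p * n_species + s] += cnt[v * n_species + s];
      tot += tn[p] - tn[v];
      cum[v] = tot;
    }
    int nmut = (int)R::rpois(mu * L * tot);
    if (nmut > L) nmut = L;       // finite-sites saturation guard
    n_mut_total += nmut;
    for (int m = 0; m < nmut; ++m) {
      double u = unif_rand() * tot;
      int lo = 0, hi = nn - 2;
      while (lo < hi) { int mid = (lo + hi) / 2; if (cum[mid] < u) lo = mid + 1; else hi = mid; }
      for (int q = 0; q < npair; ++q)
        acc[q](cnt[lo * n_species + pairA[q]], cnt[lo * n_species + pairB[q]]) += 1.0;
    }
    if ((w & 255) == 0) Rcpp::checkUserInterrupt();
  }
  double total_sites = (double)n_windows * (double)L;
  List out(npair);
  for (int q = 0; q < npair; ++q) {
    acc[q](0, 0) += total_sites - n_mut_total;
    out[q] = acc[q];
  }
  return List::create(_["counts"] = out, _["total_sites"] = total_sites);
}

// Infinite-sites mutation dropping on one genealogy given as parent pointers
// (0-based, root parent = -1) and node times. Returns mutated node (branch
// below it), 1-based positions (uniform with collision redraw), and the
// tip x site 0/1 genotype matrix transpose (sites in rows).
// [[Rcpp::export]]
List drop_mutations_cpp(IntegerVector parent, NumericVector tnode,
                        int n_tip, int L, double mu) {
  int nn = parent.size();
  // branches = all non-root nodes, in input order
  std::vector<int> branch;
  branch.reserve(nn - 1);
  std::vector<double> cum;
  cum.reserve(nn - 1);
  double tot = 0.0;
  for (int v = 0; v < nn; ++v) {
    if (parent[v] < 0) continue;
    tot += tnode[parent[v]] - tnode[v];
    branch.push_back(v);
    cum.push_back(tot);
  }
  int nmut = (int)R::rpois(mu * L * tot);
  if (nmut > L)
    stop("more mutations than sites: locus too short for infinite-sites model");
  // descendant tip lists via children lists (robust to any node numbering)
  std::vector< std::vector<int> > kids(nn), tips(nn);
  int root = -1;
  for (int v = 0; v < nn; ++v) {
    if (parent[v] < 0) root = v; else kids[parent[v]].push_back(v);
  }
  if (root < 0) stop("no root in parent vector");
  std::vector<int> stack, post;
  stack.push_back(root);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    post.push_back(v);
    for (size_t c = 0; c < kids[v].size(); ++c) stack.push_back(kids[v][c]);
  }
  for (int i = (int)post.size() - 1; i >= 0; --i) {
    int v = post[i];
    if (v < n_tip) { tips[v].push_back(v); }
    if (parent[v] >= 0) {
      std::vector<int>& tp = tips[parent[v]];
      tp.insert(tp.end(), tips[v].begin(), tips[v].end());
    }
  }
  IntegerVector node(nmut);
  IntegerVector pos(nmut);
  IntegerMatrix geno(nmut, n_tip);
  std::vector<bool> used(L + 1, false);
  int nb = (int)branch.size();
  for (int m = 0; m < nmut; ++m) {
    double u = unif_rand() * tot;
    int lo = 0, hi = nb - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (cum[mid] < u) lo = mid + 1; else hi = mid; }
    int v = branch[lo];
    node[m] = v;
    int p;
    do { p = 1 + (int)std::floor(unif_rand() * L); } while (used[p]);
    used[p] = true;
    pos[m] = p;
    for (size_t i = 0; i < tips[v].size(); ++i) geno(m, tips[v][i]) = 1;
  }
  return List::create(_["node"] = node, _["pos"] = pos, _["geno"] = geno);
}

// Fused fast path for ABC reference tables: per locus, simulate one
// genealogy, drop Poisson infinite-sites mutations, and accumulate the five
// pairwise statistics (segregating sites, shared / fixed polymorphism,
// dXY, AMOVA PhiST) for every species pair directly from per-species
// derived-allele counts (complete data, so pairwise-difference sums reduce
// to count identities). Returns an n_loci x (npair*5) matrix with pair-major
// columns ordered (S, shared, fixed, dxy, phist).
// [[Rcpp::export]]
NumericMatrix sim_pairstats_cpp(IntegerVector lin_pop, List epochs,
                                IntegerVector species, int n_species,
                                IntegerVector pairA, IntegerVector pairB,
                                int n_loci, int L, double mu) {
  Demog D = unpack_demog(epochs);
  int n = lin_pop.size();
  std::vector<int> lp(lin_pop.begin(), lin_pop.end());
  int npair = pairA.size();
  std::vector<int> nsamp(n_species, 0);
  for (int i = 0; i < n; ++i) nsamp[species[i]]++;
  NumericMatrix out(n_loci, npair * 5);
  std::vector<int> par; std::vector<double> tn;
  int nn = 2 * n - 1;
  std::vector<int> cnt(nn * n_species);
  std::vector<double> cum(nn - 1);
  std::vector<double> Sp(npair), sh(npair), fx(npair), dxys(npair),
      dwA(npair), dwB(npair);
  for (int w = 0; w < n_loci; ++w) {
    simulate_tree(D, lp, par, tn);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) cnt[i * n_species + species[i]] = 1;
    double tot = 0.0;
    for (int v = 0; v < nn - 1; ++v) {
      int p = par[v];
      for (int s = 0; s < n_species; ++s)
        cnt[p * n_species + s] += cnt[v * n_species + s];
      tot += tn[p] - tn[v];
      cum[v] = tot;
    }
    int nmut = (int)R::rpois(mu * L * tot);
    if (nmut > L) nmut = L;
    std::fill(Sp.begin(), Sp.end(), 0.0);
    std::fill(sh.begin(), sh.end(), 0.0);
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(dxys.begin(), dxys.end(), 0.0);
    std::fill(dwA.begin(), dwA.end(), 0.0);
    std::fill(dwB.begin(), dwB.end(), 0.0);
    for (int m = 0; m < nmut; ++m) {
      double u = unif_rand() * tot;
      int lo = 0, hi = nn - 2;
      while (lo < hi) { int mid = (lo + hi) / 2; if (cum[mid] < u) lo = mid + 1; else hi = mid; }
      for (int q = 0; q < npair; ++q) {
        int ka = cnt[lo * n_species + pairA[q]];
        int kb = cnt[lo * n_species + pairB[q]];
        int ma = nsamp[pairA[q]], mb = nsamp[pairB[q]];
        if (ka + kb > 0 && ka + kb < ma + mb) Sp[q] += 1;
        bool pa = ka > 0 && ka < ma, pb = kb > 0 && kb < mb;
        if (pa && pb) sh[q] += 1;
        if ((ka == ma && kb == 0) || (ka == 0 && kb == mb)) fx[q] += 1;
        dxys[q] += (double)ka * (mb - kb) + (double)kb * (ma - ka);
        dwA[q] += (double)ka * (ma - ka);
        dwB[q] += (double)kb * (mb - kb);
      }
    }
    for (int q = 0; q < npair; ++q) {
      int n1 = nsamp[pairA[q]], n2 = nsamp[pairB[q]], N = n1 + n2;
      double S = Sp[q];
      out(w, q * 5 + 0) = S;
      out(w, q * 5 + 1) = S > 0 ? sh[q] / S : NA_REAL;
      out(w, q * 5 + 2) = S > 0 ? fx[q] / S : NA_REAL;
      out(w, q * 5 + 3) = dxys[q] / ((double)n1 * n2 * L);
      double ss_tot = (dwA[q] + dwB[q] + dxys[q]) / N;
      double ss_within = dwA[q] / n1 + dwB[q] / n2;
      double ss_among = ss_tot - ss_within;
      double ms_among = ss_among;                 // df_among = 1
      double ms_within = ss_within / (N - 2);
      double n_c = N - ((double)n1 * n1 + (double)n2 * n2) / N;
      double sig_a = (ms_among - ms_within) / n_c;
      double denom = sig_a + ms_within;
      out(w, q * 5 + 4) = denom != 0.0 ? sig_a / denom : NA_REAL;
    }
    if ((w & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
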