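// Forward-in-time serial-founder range-expansion simulator.
//
// Haplotypes are founder-interval mosaics: each chromosome is a tiling of
// half-open bp intervals labelled by the founder lineage they descend from,
// plus a sorted list of (position, mutation-id) private mutations that
// arose during the run. Runs of homozygosity and linkage disequilibrium
// therefore arise mechanistically from shared founder ancestry, at trivial
// memory cost compared to full sequences.
//
// Standing variation present in the refuge before the expansion (the
// product of long-term ancestral Ne that a desk-scale forward run cannot
// generate) is attached to founder labels: each standing site lists the
// founder haplotypes that carry its derived allele, and genotypes are
// resolved from the founder mosaics only when individuals are sampled, so
// standing sites cost nothing during reproduction.
//
// All randomness is drawn from R's RNG, so results are bit-reproducible
// under set.seed() on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>
#include <utility>
#include <vector>

using namespace Rcpp;

namespace {

struct Hap {
  std::vector<int> bp;   // segment start positions; bp[0] == 0
  std::vector<int> fid;  // founder label per segment
  std::vector<std::pair<int, int> > mut;  // (pos, mutation id), sorted by pos
};

typedef std::vector<Hap> Ind;  // 2 * n_chrom haplotypes; chrom c -> 2c, 2c+1

struct Deme {
  bool colonized;
  int col_gen;
  std::vector<Ind> inds;
  Deme() : colonized(false), col_gen(-1) {}
};

struct Registry {
  std::vector<int> chrom;  // 0-based chromosome index
  std::vector<int> pos;    // 0-based bp position
  std::vector<int> cls;    // 0 = SYN, 1 = NONSYN, 2 = LOF
  std::vector<int> gen;    // generation of origin (-1 for standing variants)
};

inline int runif_int(int n) {  // uniform on 0..n-1
  int k = static_cast<int>(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

void sample_distinct(int n, int k, std::vector<int>& out) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  out.resize(k);
  for (int i = 0; i < k; ++i) {
    int j = i + runif_int(n - i);
    std::swap(idx[i], idx[j]);
    out[i] = idx[i];
  }
}

// Append the [a, b) slice of h (segments and mutations) to gamete g.
void copy_interval(Hap& g, const Hap& h, int a, int b) {
  int n = static_cast<int>(h.bp.size());
  int i = static_cast<int>(std::upper_bound(h.bp.begin(), h.bp.end(), a) -
                           h.bp.begin()) - 1;
  for (; i < n && h.bp[i] < b; ++i) {
    int s = std::max(h.bp[i], a);
    int f = h.fid[i];
    if (g.fid.empty() || g.fid.back() != f) {
      g.bp.push_back(s);
      g.fid.push_back(f);
    }
  }
  std::pair<int, int> key(a, -2147483647);
  for (std::vector<std::pair<int, int> >::const_iterator it =
           std::lower_bound(h.mut.begin(), h.mut.end(), key);
       it != h.mut.end() && it->first < b; ++it) {
    g.mut.push_back(*it);
  }
}

// One meiosis over one chromosome: Poisson crossovers, random start phase.
Hap meiosis(const Hap& h0, const Hap& h1, double morgans, int L) {
  int k = static_cast<int>(R::rpois(morgans));
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  if (k == 0) return cur ? h1 : h0;
  std::vector<int> xo(k);
  for (int i = 0; i < k; ++i) xo[i] = 1 + runif_int(L - 1);
  std::sort(xo.begin(), xo.end());
  Hap g;
  const Hap* src[2] = { &h0, &h1 };
  int prev = 0;
  for (int i = 0; i <= k; ++i) {
    int end = (i < k) ? xo[i] : L;
    if (end > prev) copy_interval(g, *src[cur], prev, end);
    cur ^= 1;
    prev = end;
  }
  return g;
}

int sample_class(const std::vector<double>& cum_probs) {
  double u = unif_rand();
  for (size_t i = 0; i + 1 < cum_probs.size(); ++i)
    if (u < cum_probs[i]) return static_cast<int>(i);
  return static_cast<int>(cum_probs.size()) - 1;
}

// New mutations on a gamete: Poisson(mu * L), positions unique per chromosome.
void add_mutations(Hap& g, int chrom, int L, double mu_L,
                   const std::vector<double>& cum_probs, int gen,
                   Registry& reg, std::unordered_set<int>& used) {
  int nm = static_cast<int>(R::rpois(mu_L));
  for (int i = 0; i < nm; ++i) {
    int pos = runif_int(L);
    int guard = 0;
    while (used.count(pos) && ++guard < 1000) pos = runif_int(L);
    if (used.count(pos)) continue;  // chromosome saturated; skip
    used.insert(pos);
    int id = static_cast<int>(reg.pos.size());
    reg.chrom.push_back(chrom);
    reg.pos.push_back(pos);
    reg.cls.push_back(sample_class(cum_probs));
    reg.gen.push_back(gen);
    std::pair<int, int> rec(pos, id);
    g.mut.insert(std::lower_bound(g.mut.begin(), g.mut.end(), rec), rec);
  }
}

// Sum over segregating mutations of 2p(1-p) within a set of individuals
// (per-site expected heterozygosity, summed; fixed sites contribute 0).
double expected_het(const std::vector<Ind>& inds, const std::vector<int>* subset) {
  std::unordered_map<int, int> cnt;
  int n_ind = subset ? static_cast<int>(subset->size())
                     : static_cast<int>(inds.size());
  for (int s = 0; s < n_ind; ++s) {
    const Ind& ind = inds[subset ? (*subset)[s] : s];
    for (size_t h = 0; h < ind.size(); ++h)
      for (size_t m = 0; m < ind[h].mut.size(); ++m) ++cnt[ind[h].mut[m].second];
  }
  double nh = 2.0 * n_ind, eh = 0.0;
  for (std::unordered_map<int, int>::const_iterator it = cnt.begin();
       it != cnt.end(); ++it) {
    double p = it->second / nh;
    eh += 2.0 * p * (1.0 - p);
  }
  return eh;
}

inline int label_at(const Hap& h, int pos) {
  int i = static_cast<int>(std::upper_bound(h.bp.begin(), h.bp.end(), pos) -
                           h.bp.begin()) - 1;
  return h.fid[i];
}

// Founder-lineage heterozygosity (1 - sum p_label^2) averaged over evenly
// spaced probe positions: the standing-variation component of expected
// heterozygosity, cheap to evaluate at colonization events.
double label_het(const std::vector<Ind>& inds, const std::vector<int>* subset,
                 int C, int L, int n_probes) {
  int n_ind = subset ? static_cast<int>(subset->size())
                     : static_cast<int>(inds.size());
  double nh = 2.0 * n_ind, tot = 0.0;
  int cnt = 0;
  for (int c = 0; c < C; ++c)
    for (int pr = 0; pr < n_probes; ++pr) {
      int pos = static_cast<int>((pr + 0.5) / n_probes * L);
      std::unordered_map<int, int> cnts;
      for (int s = 0; s < n_ind; ++s) {
        const Ind& ind = inds[subset ? (*subset)[s] : s];
        ++cnts[label_at(ind[2 * c], pos)];
        ++cnts[label_at(ind[2 * c + 1], pos)];
      }
      double ss = 0.0;
      for (std::unordered_map<int, int>::const_iterator it = cnts.begin();
           it != cnts.end(); ++it) {
        double p = it->second / nh;
        ss += p * p;
      }
      tot += 1.0 - ss;
      ++cnt;
    }
  return tot / cnt;
}

// Longest interval where both haplotypes carry the same founder label.
int max_autozygous_tract(const Hap& a, const Hap& b, int L) {
  size_t i = 0, j = 0;
  int best = 0, cur_start = -1, pos = 0;
  while (pos < L) {
    int enda = (i + 1 < a.bp.size()) ? a.bp[i + 1] : L;
    int endb = (j + 1 < b.bp.size()) ? b.bp[j + 1] : L;
    int end = std::min(enda, endb);
    if (a.fid[i] == b.fid[j]) {
      if (cur_start < 0) cur_start = pos;
      if (end - cur_start > best) best = end - cur_start;
    } else {
      cur_start = -1;
    }
    pos = end;
    if (end == enda) ++i;
    if (end == endb) ++j;
  }
  return best;
}

int pick_parent(const std::vector<double>& cumw) {
  if (cumw.empty()) return 0;
  double u = unif_rand() * cumw.back();
  return static_cast<int>(std::lower_bound(cumw.begin(), cumw.end(), u) -
                          cumw.begin());
}

}  // namespace

// [[Rcpp::export(name = ".sim_expansion_cpp")]]
List sim_expansion_cpp(List cfg) {
  const int W = as<int>(cfg["grid_width"]);
  const int H = as<int>(cfg["grid_height"]);
  const int orow = as<int>(cfg["origin_row"]);   // 0-based
  const int ocol = as<int>(cfg["origin_col"]);
  const int N = as<int>(cfg["deme_size"]);
  const int K = as<int>(cfg["founders"]);
  const double mig = as<double>(cfg["migration"]);
  const int Tc = as<int>(cfg["colonization_interval"]);
  const int post_exp = as<int>(cfg["post_expansion"]);
  const int burn_in = as<int>(cfg["burn_in"]);
  const int C = as<int>(cfg["n_chromosomes"]);
  const int L = as<int>(cfg["chrom_length_bp"]);
  const double mu = as<double>(cfg["mu"]);
  const double cM_per_Mb = as<double>(cfg["recomb_cM_per_Mb"]);
  NumericVector class_probs = cfg["class_probs"];
  NumericVector sel_coef = cfg["sel_coef"];
  const int spd = as<int>(cfg["sample_per_deme"]);
  const int lgm_epoch = as<int>(cfg["lgm_epoch"]);
  const int n_standing = as<int>(cfg["n_standing"]);
  const double standing_freq = as<double>(cfg["standing_freq"]);
  const bool drop_mono = as<bool>(cfg["drop_monomorphic"]);

  const double morgans = L * cM_per_Mb / 1e6 / 100.0;
  const double mu_L = mu * static_cast<double>(L);
  std::vector<double> cum_probs(3);
  cum_probs[0] = class_probs[0];
  cum_probs[1] = class_probs[0] + class_probs[1];
  cum_probs[2] = 1.0;
  std::vector<double> scls(3);
  scls[0] = sel_coef[0]; scls[1] = sel_coef[1]; scls[2] = sel_coef[2];
  const bool sel_active = scls[0] != 0.0 || scls[1] != 0.0 || scls[2] != 0.0;

  // total generations: burn-in, then one wave step per colonization interval
  // until the farthest cell (Manhattan distance D) is reached, then a
  // post-expansion phase with the range stable (ageing founder tracts the
  // way a completed post-glacial expansion is sampled long after the fact).
  int D = 0;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      D = std::max(D, std::abs(r - orow) + std::abs(c - ocol));
  const int total_gens =
      burn_in + (D > 0 ? (D - 1) * Tc : 0) + std::max(post_exp, 1);
  if (lgm_epoch > total_gens)
    stop("lgm_epoch (%d) is after the final generation (%d)", lgm_epoch,
         total_gens);

  Registry reg;
  std::vector<std::unordered_set<int> > used(C);
  std::vector<Deme> demes(H * W);
  std::vector<int> col_order;  // deme indices in colonization order

  // origin deme: 2N distinct founder labels, no mutations
  {
    Deme& o = demes[orow * W + ocol];
    o.colonized = true;
    o.col_gen = 0;
    o.inds.resize(N);
    // haplotype copy h of individual i carries founder label 2i+h on every
    // chromosome; labels only need to be unique among homologues
    for (int i = 0; i < N; ++i) {
      o.inds[i].resize(2 * C);
      for (int c = 0; c < C; ++c)
        for (int h = 0; h < 2; ++h) {
          Hap& hp = o.inds[i][2 * c + h];
          hp.bp.assign(1, 0);
          hp.fid.assign(1, 2 * i + h);
        }
    }
    col_order.push_back(orow * W + ocol);
  }

  // standing refuge variation attached to founder labels: site id carried
  // by a fixed subset of the 2N founder haplotypes; frequencies follow the
  // neutral 1/c site-frequency spectrum unless a fixed standing_freq >= 0
  // is requested (drift calibration experiments)
  std::vector<std::vector<std::pair<int, int> > > standing(2 * N * C);
  if (n_standing > 0) {
    std::vector<double> sfs_cum(2 * N - 1);
    double acc = 0.0;
    for (int c = 1; c <= 2 * N - 1; ++c) {
      acc += 1.0 / c;
      sfs_cum[c - 1] = acc;
    }
    for (int v = 0; v < n_standing; ++v) {
      int chrom = runif_int(C);
      int pos = runif_int(L);
      int guard = 0;
      while (used[chrom].count(pos) && ++guard < 1000) pos = runif_int(L);
      if (used[chrom].count(pos)) continue;
      used[chrom].insert(pos);
      int id = static_cast<int>(reg.pos.size());
      reg.chrom.push_back(chrom);
      reg.pos.push_back(pos);
      reg.cls.push_back(sample_class(cum_probs));
      reg.gen.push_back(-1);
      int carriers;
      if (standing_freq >= 0) {
        carriers = static_cast<int>(std::floor(standing_freq * 2 * N + 0.5));
        carriers = std::max(1, std::min(2 * N - 1, carriers));
      } else {
        double u = unif_rand() * sfs_cum.back();
        carriers = 1 + static_cast<int>(
            std::lower_bound(sfs_cum.begin(), sfs_cum.end(), u) -
            sfs_cum.begin());
      }
      std::vector<int> hsel;
      sample_distinct(2 * N, carriers, hsel);
      for (size_t s = 0; s < hsel.size(); ++s)
        standing[hsel[s] * C + chrom].push_back(std::make_pair(pos, id));
    }
    for (size_t i = 0; i < standing.size(); ++i)
      std::sort(standing[i].begin(), standing[i].end());
  }

  // per-mutation selection coefficients resolved lazily from class
  // (vector grows with the registry)
  std::vector<double> sel_of;

  // colonization diagnostics
  std::vector<double> diag_src_eh, diag_fnd_eh, diag_src_lhet, diag_fnd_lhet;
  std::vector<int> diag_gen, diag_row, diag_col, diag_src_row, diag_src_col;

  IntegerMatrix presence_lgm(H, W);
  bool lgm_taken = false;
  const int drow[4] = { -1, 0, 1, 0 };  // N, E, S, W
  const int dcol[4] = { 0, 1, 0, -1 };

  for (int g = 0; g < total_gens; ++g) {
    if (g == lgm_epoch) {
      for (int d = 0; d < H * W; ++d)
        presence_lgm(d / W, d % W) = demes[d].colonized ? 1 : 0;
      lgm_taken = true;
    }

    // wave step: colonize empty 4-neighbours of the current colonized set
    if (g >= burn_in && (g - burn_in) % Tc == 0) {
      std::vector<char> was(H * W);
      for (int d = 0; d < H * W; ++d) was[d] = demes[d].colonized ? 1 : 0;
      std::vector<int> new_demes, new_src;
      for (int r = 0; r < H; ++r)
        for (int c = 0; c < W; ++c) {
          int d = r * W + c;
          if (was[d]) continue;
          int src = -1;
          for (int k = 0; k < 4; ++k) {  // fixed N, E, S, W tie-break
            int rr = r + drow[k], cc = c + dcol[k];
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (was[rr * W + cc]) { src = rr * W + cc; break; }
          }
          if (src >= 0) { new_demes.push_back(d); new_src.push_back(src); }
        }
      for (size_t i = 0; i < new_demes.size(); ++i) {
        int d = new_demes[i], src = new_src[i];
        std::vector<int> fsel;
        sample_distinct(static_cast<int>(demes[src].inds.size()), K, fsel);
        diag_src_eh.push_back(expected_het(demes[src].inds, 0));
        diag_fnd_eh.push_back(expected_het(demes[src].inds, &fsel));
        diag_src_lhet.push_back(label_het(demes[src].inds, 0, C, L, 50));
        diag_fnd_lhet.push_back(label_het(demes[src].inds, &fsel, C, L, 50));
        diag_gen.push_back(g);
        diag_row.push_back(d / W);
        diag_col.push_back(d % W);
        diag_src_row.push_back(src / W);
        diag_src_col.push_back(src % W);
        demes[d].colonized = true;
        demes[d].col_gen = g;
        demes[d].inds.resize(K);
        for (int j = 0; j < K; ++j) demes[d].inds[j] = demes[src].inds[fsel[j]];
        col_order.push_back(d);
      }
    }

    // Wright-Fisher reproduction within every colonized deme
    for (size_t ci = 0; ci < col_order.size(); ++ci) {
      Deme& deme = demes[col_order[ci]];
      std::vector<double> cumw;
      if (sel_active) {
        sel_of.resize(reg.pos.size());
        for (size_t mi = 0; mi < reg.pos.size(); ++mi)
          sel_of[mi] = scls[reg.cls[mi]];
        cumw.resize(deme.inds.size());
        double acc = 0.0;
        for (size_t i = 0; i < deme.inds.size(); ++i) {
          // fitness multiplicative over derived alleles, per-class s
          double w = 1.0;
          const Ind& ind = deme.inds[i];
          for (size_t h = 0; h < ind.size(); ++h)
            for (size_t m = 0; m < ind[h].mut.size(); ++m) {
              double f = 1.0 + sel_of[ind[h].mut[m].second];
              w *= (f > 0.0) ? f : 0.0;
            }
          acc += w;
          cumw[i] = acc;
        }
      }
      int np = static_cast<int>(deme.inds.size());
      std::vector<Ind> next(N);
      for (int i = 0; i < N; ++i) {
        int mom = sel_active ? pick_parent(cumw) : runif_int(np);
        int dad = sel_active ? pick_parent(cumw) : runif_int(np);
        next[i].resize(2 * C);
        for (int c = 0; c < C; ++c) {
          Hap g0 = meiosis(deme.inds[mom][2 * c], deme.inds[mom][2 * c + 1],
                           morgans, L);
          add_mutations(g0, c, L, mu_L, cum_probs, g, reg, used[c]);
          Hap g1 = meiosis(deme.inds[dad][2 * c], deme.inds[dad][2 * c + 1],
                           morgans, L);
          add_mutations(g1, c, L, mu_L, cum_probs, g, reg, used[c]);
          next[i][2 * c] = g0;
          next[i][2 * c + 1] = g1;
        }
      }
      deme.inds.swap(next);
    }

    // symmetric migration: floor(m*N) individuals swapped with each
    // colonized 4-neighbour (east and south pairs enumerate each edge once)
    int nm = static_cast<int>(std::floor(mig * N + 1e-9));
    if (nm > 0) {
      for (int r = 0; r < H; ++r)
        for (int c = 0; c < W; ++c) {
          int d = r * W + c;
          if (!demes[d].colonized) continue;
          const int er[2] = { r, r + 1 }, ec[2] = { c + 1, c };
          for (int k = 0; k < 2; ++k) {
            if (er[k] >= H || ec[k] >= W) continue;
            int e = er[k] * W + ec[k];
            if (!demes[e].colonized) continue;
            std::vector<int> ia, ib;
            sample_distinct(N, nm, ia);
            sample_distinct(N, nm, ib);
            for (int x = 0; x < nm; ++x)
              std::swap(demes[d].inds[ia[x]], demes[e].inds[ib[x]]);
          }
        }
    }
  }

  if (!lgm_taken)  // lgm_epoch == total_gens: snapshot of the final state
    for (int d = 0; d < H * W; ++d)
      presence_lgm(d / W, d % W) = demes[d].colonized ? 1 : 0;

  // ---- sample individuals and build the genotype matrix ----
  std::vector<int> samp_deme_row, samp_deme_col;
  std::vector<const Ind*> sampled;
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      Deme& deme = demes[r * W + c];
      if (!deme.colonized) continue;
      std::vector<int> sidx;
      sample_distinct(static_cast<int>(deme.inds.size()),
                      std::min(spd, static_cast<int>(deme.inds.size())), sidx);
      for (size_t s = 0; s < sidx.size(); ++s) {
        sampled.push_back(&deme.inds[sidx[s]]);
        samp_deme_row.push_back(r);
        samp_deme_col.push_back(c);
      }
    }
  int n_samp = static_cast<int>(sampled.size());
  if (n_samp == 0) stop("no individuals sampled");

  // dosage over every registered site (columns ordered by chrom, pos);
  // standing sites are resolved from the founder mosaics
  std::vector<int> ids(reg.pos.size());
  for (size_t i = 0; i < ids.size(); ++i) ids[i] = static_cast<int>(i);
  struct ByChromPos {
    const Registry* reg;
    bool operator()(int a, int b) const {
      if (reg->chrom[a] != reg->chrom[b]) return reg->chrom[a] < reg->chrom[b];
      return reg->pos[a] < reg->pos[b];
    }
  };
  ByChromPos cmp;
  cmp.reg = &reg;
  std::sort(ids.begin(), ids.end(), cmp);

  std::vector<int> col_of(reg.pos.size());
  for (size_t i = 0; i < ids.size(); ++i) col_of[ids[i]] = static_cast<int>(i);

  IntegerMatrix geno(n_samp, static_cast<int>(ids.size()));
  for (int s = 0; s < n_samp; ++s)
    for (int c = 0; c < C; ++c)
      for (int h = 0; h < 2; ++h) {
        const Hap& hp = (*sampled[s])[2 * c + h];
        for (size_t m = 0; m < hp.mut.size(); ++m)
          ++geno(s, col_of[hp.mut[m].second]);
        if (n_standing > 0) {
          size_t nseg = hp.bp.size();
          for (size_t i = 0; i < nseg; ++i) {
            int a = hp.bp[i];
            int b = (i + 1 < nseg) ? hp.bp[i + 1] : L;
            const std::vector<std::pair<int, int> >& sv =
                standing[hp.fid[i] * C + c];
            std::pair<int, int> key(a, -2147483647);
            for (std::vector<std::pair<int, int> >::const_iterator it =
                     std::lower_bound(sv.begin(), sv.end(), key);
                 it != sv.end() && it->first < b; ++it)
              ++geno(s, col_of[it->second]);
          }
        }
      }

  std::vector<int> keep;
  for (int j = 0; j < geno.ncol(); ++j) {
    if (!drop_mono) { keep.push_back(j); continue; }
    int mn = 3, mx = -1;
    for (int s = 0; s < n_samp; ++s) {
      mn = std::min(mn, geno(s, j));
      mx = std::max(mx, geno(s, j));
    }
    bool mono = (mn == mx) && (mn == 0 || mn == 2);
    if (!mono) keep.push_back(j);
  }

  IntegerMatrix geno_out(n_samp, static_cast<int>(keep.size()));
  IntegerVector v_chrom(keep.size()), v_pos(keep.size()), v_cls(keep.size()),
      v_gen(keep.size());
  for (size_t jj = 0; jj < keep.size(); ++jj) {
    int j = keep[jj], id = ids[j];
    for (int s = 0; s < n_samp; ++s) geno_out(s, jj) = geno(s, j);
    v_chrom[jj] = reg.chrom[id];
    v_pos[jj] = reg.pos[id];
    v_cls[jj] = reg.cls[id];
    v_gen[jj] = reg.gen[id];
  }

  IntegerVector max_tract(n_samp);
  for (int s = 0; s < n_samp; ++s) {
    int best = 0;
    for (int c = 0; c < C; ++c)
      best = std::max(best, max_autozygous_tract((*sampled[s])[2 * c],
                                                 (*sampled[s])[2 * c + 1], L));
    max_tract[s] = best;
  }

  IntegerMatrix presence_final(H, W);
  IntegerMatrix colonized_gen(H, W);
  for (int d = 0; d < H * W; ++d) {
    presence_final(d / W, d % W) = demes[d].colonized ? 1 : 0;
    colonized_gen(d / W, d % W) = demes[d].col_gen;
  }

  return List::create(
      _["genotypes"] = geno_out, _["chrom0"] = v_chrom, _["pos0"] = v_pos,
      _["class_code"] = v_cls, _["origin_gen"] = v_gen,
      _["sample_row"] = wrap(samp_deme_row),
      _["sample_col"] = wrap(samp_deme_col), _["max_tract"] = max_tract,
      _["presence_lgm"] = presence_lgm, _["presence_final"] = presence_final,
      _["colonized_gen"] = colonized_gen,
      _["total_generations"] = total_gens,
      _["n_mutations_total"] = static_cast<int>(reg.pos.size()),
      _["colonization"] = List::create(
          _["generation"] = wrap(diag_gen), _["row"] = wrap(diag_row),
          _["col"] = wrap(diag_col), _["source_row"] = wrap(diag_src_row),
          _["source_col"] = wrap(diag_src_col),
          _["source_eh"] = wrap(diag_src_eh),
          _["founder_eh"] = wrap(diag_fnd_eh),
          _["source_label_het"] = wrap(diag_src_lhet),
          _["founder_label_het"] = wrap(diag_fnd_lhet)));
}
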