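#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Orbit census of connected induced bipartite subgraphs (motifs) via the
// ESU enumeration algorithm. Each enumerated subgraph is matched against a
// catalogue of canonical forms; every node is credited in the orbit it
// occupies. Guilds are never interchangeable: rows of a motif's biadjacency
// matrix are plants, columns are pollinators.

namespace {

typedef std::vector<std::vector<int> > PermSet;

// all permutations of 0..(n-1), n <= 5
PermSet perms_of(int n) {
  PermSet out;
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  do { out.push_back(p); } while (std::next_permutation(p.begin(), p.end()));
  if (n == 0) out.push_back(std::vector<int>());
  return out;
}

struct CensusCtx {
  int n;
  const std::vector<std::vector<int> > *adj;
  const IntegerVector *guild;           // 0 = plant, 1 = pollinator
  const NumericMatrix *W;               // symmetric weight matrix
  std::unordered_map<long long, int> keymap;  // canonical key -> motif index
  std::vector<std::vector<int> > orbit; // per motif: global orbit per canonical node
  NumericMatrix *res;
  int mode;                             // 0 binary, 1 mean, 2 sum, 3 geometric mean
  std::vector<PermSet> perms;           // perms[0..5]
  // scratch
  std::vector<int> plants, polls;
};

inline long long motif_key(int p, int a, int bits) {
  return ((long long)(p * 6 + a) << 20) | (long long)bits;
}

void process_subgraph(CensusCtx &ctx, const std::vector<int> &sub) {
  ctx.plants.clear(); ctx.polls.clear();
  for (size_t i = 0; i < sub.size(); ++i) {
    if ((*ctx.guild)[sub[i]] == 0) ctx.plants.push_back(sub[i]);
    else ctx.polls.push_back(sub[i]);
  }
  std::sort(ctx.plants.begin(), ctx.plants.end());
  std::sort(ctx.polls.begin(), ctx.polls.end());
  const int p = (int)ctx.plants.size(), a = (int)ctx.polls.size();
  if (p == 0 || a == 0) return;  // cannot be connected

  // local biadjacency + occurrence weight statistic
  int base[25];
  double wsum = 0.0, wlog = 0.0;
  int ec = 0;
  for (int r = 0; r < p; ++r)
    for (int c = 0; c < a; ++c) {
      double w = (*ctx.W)(ctx.plants[r], ctx.polls[c]);
      base[r * a + c] = (w > 0.0) ? 1 : 0;
      if (w > 0.0) { wsum += w; wlog += std::log(w); ++ec; }
    }

  // canonical form: minimal row-major bit code over guild-preserving perms
  const PermSet &pr = ctx.perms[p], &pc = ctx.perms[a];
  int best = -1;
  const std::vector<int> *bpr = 0, *bpc = 0;
  for (size_t ip = 0; ip < pr.size(); ++ip) {
    for (size_t ic = 0; ic < pc.size(); ++ic) {
      int bits = 0;
      for (int r = 0; r < p; ++r)
        for (int c = 0; c < a; ++c)
          if (base[pr[ip][r] * a + pc[ic][c]]) bits |= (1 << (r * a + c));
      if (best < 0 || bits < best) { best = bits; bpr = &pr[ip]; bpc = &pc[ic]; }
    }
  }

  std::unordered_map<long long, int>::const_iterator it =
    ctx.keymap.find(motif_key(p, a, best));
  if (it == ctx.keymap.end())
    stop("subgraph does not match any catalogue motif (catalogue incomplete?)");
  const std::vector<int> &orb = ctx.orbit[it->second];

  double contrib = 1.0;
  if (ctx.mode == 1) contrib = wsum / ec;
  else if (ctx.mode == 2) contrib = wsum;
  else if (ctx.mode == 3) contrib = std::exp(wlog / ec);

  // canonical position j (plants first) holds original node plants[(*bpr)[j]]
  for (int j = 0; j < p; ++j)
    (*ctx.res)(ctx.plants[(*bpr)[j]], orb[j]) += contrib;
  for (int j = 0; j < a; ++j)
    (*ctx.res)(ctx.polls[(*bpc)[j]], orb[p + j]) += contrib;
}

void extend_subgraph(CensusCtx &ctx, std::vector<int> &sub, std::vector<int> ext,
                     int v, int k, std::vector<int> &nbrcnt,
                     std::vector<char> &insub) {
  if ((int)sub.size() == k) { process_subgraph(ctx, sub); return; }
  while (!ext.empty()) {
    int w = ext.back(); ext.pop_back();
    std::vector<int> ext2 = ext;
    const std::vector<int> &nw = (*ctx.adj)[w];
    for (size_t i = 0; i < nw.size(); ++i) {
      int u = nw[i];
      if (u > v && !insub[u] && nbrcnt[u] == 0) ext2.push_back(u);
    }
    sub.push_back(w); insub[w] = 1;
    for (size_t i = 0; i < nw.size(); ++i) nbrcnt[nw[i]]++;
    extend_subgraph(ctx, sub, ext2, v, k, nbrcnt, insub);
    for (size_t i = 0; i < nw.size(); ++i) nbrcnt[nw[i]]--;
    insub[w] = 0; sub.pop_back();
  }
}

} // namespace

// [[Rcpp::export(name = ".census_cpp")]]
NumericMatrix census_cpp(List adj, IntegerVector guild, NumericMatrix W,
                         int kmin, int kmax, NumericVector keys, List orbits,
                         int npos, int mode) {
  const int n = adj.size();
  std::vector<std::vector<int> > A(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    A[i].assign(nb.begin(), nb.end());
  }
  NumericMatrix res(n, npos);

  CensusCtx ctx;
  ctx.n = n; ctx.adj = &A; ctx.guild = &guild; ctx.W = &W;
  ctx.res = &res; ctx.mode = mode;
  for (int s = 0; s <= 5; ++s) ctx.perms.push_back(perms_of(s));
  for (int m = 0; m < keys.size(); ++m) {
    ctx.keymap[(long long)keys[m]] = m;
    IntegerVector ov = orbits[m];
    ctx.orbit.push_back(std::vector<int>(ov.begin(), ov.end()));
  }

  std::vector<int> nbrcnt(n, 0);
  std::vector<char> insub(n, 0);
  for (int k = kmin; k <= kmax; ++k) {
    for (int v = 0; v < n; ++v) {
      std::vector<int> sub(1, v), ext;
      insub[v] = 1;
      for (size_t i = 0; i < A[v].size(); ++i) {
        nbrcnt[A[v][i]]++;
        if (A[v][i] > v) ext.push_back(A[v][i]);
      }
      extend_subgraph(ctx, sub, ext, v, k, nbrcnt, insub);
      for (size_t i = 0; i < A[v].size(); ++i) nbrcnt[A[v][i]]--;
      insub[v] = 0;
    }
  }
  return res;
}
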