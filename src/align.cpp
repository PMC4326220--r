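// Complete search for the best-matching simple path of a peptide in a patch
// graph. Peptide positions are consumed in order; each is either matched to
// the next path vertex (substitution-matrix score) or skipped at the gap
// penalty (at most maxSkips skips). Depth-first enumeration over
// (skip-set, path) pairs is exact; branch-and-bound cuts discard partial
// solutions whose optimistic completion (suffix sum of the best possible
// per-position gain) cannot beat the incumbent, which never changes the
// optimum, only the number of node expansions. A greedy complete alignment
// seeds the incumbent before the exact search starts.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct SearchState {
  const std::vector<std::vector<int>> *adj;
  const std::vector<int> *vaa;
  const std::vector<int> *pep;
  const NumericMatrix *score;
  double gap;
  int maxSkips;
  int L, nV;
  std::vector<double> suffix;  // suffix[p] = max attainable from position p

  double bestScore;
  bool haveComplete;
  std::vector<int> bestPath;
  int bestSkips;

  int bestPartialMatched;
  double bestPartialScore;
  std::vector<int> bestPartialPath;

  long long expansions;
  std::vector<char> visited;
  std::vector<int> path;
};

inline double matchScore(const SearchState &st, int p, int v) {
  return (*st.score)((*st.pep)[p], (*st.vaa)[v]);
}

void dfs(SearchState &st, int p, int last, int skips, double cur) {
  st.expansions++;
  if (p == st.L) {
    if (!st.path.empty()) {
      if (!st.haveComplete || cur > st.bestScore) {
        st.haveComplete = true;
        st.bestScore = cur;
        st.bestPath = st.path;
        st.bestSkips = skips;
      }
    }
    return;
  }
  if (st.haveComplete && cur + st.suffix[p] <= st.bestScore)
    return;  // bound: optimistic completion cannot beat the incumbent

  bool moved = false;
  // match position p at a new path vertex
  if (last < 0) {
    for (int v = 0; v < st.nV; ++v) {
      st.visited[v] = 1;
      st.path.push_back(v);
      dfs(st, p + 1, v, skips, cur + matchScore(st, p, v));
      st.path.pop_back();
      st.visited[v] = 0;
      moved = true;
    }
  } else {
    for (int u : (*st.adj)[last]) {
      if (st.visited[u]) continue;
      st.visited[u] = 1;
      st.path.push_back(u);
      dfs(st, p + 1, u, skips, cur + matchScore(st, p, u));
      st.path.pop_back();
      st.visited[u] = 0;
      moved = true;
    }
  }
  // skip position p
  if (skips < st.maxSkips) {
    dfs(st, p + 1, last, skips + 1, cur + st.gap);
  } else if (!moved && !st.path.empty()) {
    // dead end: record the best shorter-coverage (partial) alignment,
    // penalising every unmatched remaining position
    int matched = (int)st.path.size();
    double sc = cur + st.gap * (st.L - p);
    if (matched > st.bestPartialMatched ||
        (matched == st.bestPartialMatched && sc > st.bestPartialScore)) {
      st.bestPartialMatched = matched;
      st.bestPartialScore = sc;
      st.bestPartialPath = st.path;
    }
  }
}

// Greedy complete alignment from every start vertex: a cheap valid
// incumbent that makes the exact search's bound bite early.
void greedySeed(SearchState &st) {
  for (int start = 0; start < st.nV; ++start) {
    std::vector<char> vis(st.nV, 0);
    std::vector<int> path;
    double sc = 0.0;
    int skips = 0, p = 0, last = -1;
    bool ok = true;
    while (p < st.L) {
      int bestV = -1;
      double bestM = 0.0;
      if (last < 0) {
        bestV = start;
        bestM = matchScore(st, p, start);
      } else {
        for (int u : (*st.adj)[last]) {
          if (vis[u]) continue;
          double m = matchScore(st, p, u);
          if (bestV < 0 || m > bestM) { bestV = u; bestM = m; }
        }
      }
      if (bestV >= 0 && (skips >= st.maxSkips || bestM >= st.gap)) {
        vis[bestV] = 1;
        path.push_back(bestV);
        sc += bestM;
        last = bestV;
        ++p;
      } else if (skips < st.maxSkips) {
        sc += st.gap;
        ++skips;
        ++p;
      } else {
        ok = false;
        break;
      }
    }
    if (ok && !path.empty() && (!st.haveComplete || sc > st.bestScore)) {
      st.haveComplete = true;
      st.bestScore = sc;
      st.bestPath = path;
      st.bestSkips = skips;
    }
  }
}

void runSearch(SearchState &st) {
  st.bestScore = R_NegInf;
  st.haveComplete = false;
  st.bestSkips = 0;
  st.bestPartialMatched = 0;
  st.bestPartialScore = R_NegInf;
  st.expansions = 0;
  st.visited.assign(st.nV, 0);
  st.path.clear();
  // per-position optimistic gains and their suffix sums
  st.suffix.assign(st.L + 1, 0.0);
  for (int p = st.L - 1; p >= 0; --p) {
    double g = st.gap;
    for (int v = 0; v < st.nV; ++v) {
      double m = matchScore(st, p, v);
      if (m > g) g = m;
    }
    st.suffix[p] = st.suffix[p + 1] + g;
  }
  greedySeed(st);
  dfs(st, 0, -1, 0, 0.0);
}

std::vector<std::vector<int>> makeAdj(const IntegerMatrix &edges, int nV) {
  std::vector<std::vector<int>> adj(nV);
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    adj[u].push_back(v);
    adj[v].push_back(u);
  }
  return adj;
}

// xorshift64* generator: calibration must be reproducible across platforms
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B9ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

}  // namespace

// [[Rcpp::export(name = ".alignPeptideCpp")]]
List alignPeptideCpp(IntegerMatrix edges, IntegerVector vertexAA, int nV,
                     IntegerVector peptideAA, NumericMatrix score,
                     double gap, int maxSkips) {
  std::vector<std::vector<int>> adj = makeAdj(edges, nV);
  std::vector<int> vaa(vertexAA.begin(), vertexAA.end());
  std::vector<int> pep(peptideAA.begin(), peptideAA.end());
  for (auto &x : vaa) x -= 1;
  for (auto &x : pep) x -= 1;
  SearchState st;
  st.adj = &adj; st.vaa = &vaa; st.pep = &pep; st.score = &score;
  st.gap = gap; st.maxSkips = maxSkips;
  st.L = (int)pep.size(); st.nV = nV;
  runSearch(st);
  if (st.haveComplete) {
    IntegerVector path(st.bestPath.begin(), st.bestPath.end());
    return List::create(_["path"] = path + 1, _["score"] = st.bestScore,
                        _["skips"] = st.bestSkips, _["complete"] = true,
                        _["matched"] = (int)st.bestPath.size(),
                        _["expansions"] = (double)st.expansions);
  }
  if (st.bestPartialMatched > 0) {
    IntegerVector path(st.bestPartialPath.begin(), st.bestPartialPath.end());
    return List::create(_["path"] = path + 1,
                        _["score"] = st.bestPartialScore,
                        _["skips"] = st.L - st.bestPartialMatched,
                        _["complete"] = false,
                        _["matched"] = st.bestPartialMatched,
                        _["expansions"] = (double)st.expansions);
  }
  return List::create(_["path"] = IntegerVector(0), _["score"] = NA_REAL,
                      _["skips"] = 0, _["complete"] = false,
                      _["matched"] = 0,
                      _["expansions"] = (double)st.expansions);
}

// Best scores of nSamples random peptides of the given length on one graph:
// the empirical null used to fit the extreme-value calibration.
// [[Rcpp::export(name = ".calibrateScoresCpp")]]
NumericVector calibrateScoresCpp(IntegerMatrix edges, IntegerVector vertexAA,
                                 int nV, int length, NumericMatrix score,
                                 double gap, int maxSkips, int nSamples,
                                 int seed, int nAA) {
  std::vector<std::vector<int>> adj = makeAdj(edges, nV);
  std::vector<int> vaa(vertexAA.begin(), vertexAA.end());
  for (auto &x : vaa) x -= 1;
  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);
  NumericVector out(nSamples);
  std::vector<int> pep(length);
  SearchState st;
  st.adj = &adj; st.vaa = &vaa; st.score = &score;
  st.gap = gap; st.maxSkips = maxSkips;
  st.L = length; st.nV = nV;
  for (int s = 0; s < nSamples; ++s) {
    for (int i = 0; i < length; ++i) pep[i] = rng.unif_int(nAA);
    st.pep = &pep;
    runSearch(st);
    out[s] = st.haveComplete ? st.bestScore
             : (st.bestPartialMatched > 0 ? st.bestPartialScore : NA_REAL);
  }
  return out;
}
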