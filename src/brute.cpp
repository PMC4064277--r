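// Exhaustive alignment oracle: enumerates every path through the edit
// graph (diagonal = match/mismatch, horizontal/vertical = gap columns) by
// depth-first search, scoring each path incrementally with the run-length
// rescore semantics: a run of L matches scores sum_{n=1..L} delta_f(min(n,cap)),
// a mismatch column costs m, a gap's first column costs open_cost and each
// further column in the same direction ext_cost.  Local mode enumerates
// paths between all cell pairs (the empty alignment scores 0).
//
// Deliberately shares no code with the DP engine; it is the validation
// oracle for it.  Guarded to tiny inputs at the R level.

#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

struct BF {
  const char* t;
  const char* q;
  int N, M;
  const double* df;
  int cap;
  double m, open_, e;
  bool local;
  double best;

  void dfs(int i, int j, int run, char last, double score) {
    if (local) {
      if (score > best) best = score;
    } else if (i == N && j == M) {
      if (score > best) best = score;
    }
    if (i < N && j < M) {
      bool match = (t[i] == q[j] && t[i] != 'N');
      if (match) {
        int n = run + 1;
        dfs(i + 1, j + 1, n, 'M', score + df[(n < cap ? n : cap) - 1]);
      } else {
        dfs(i + 1, j + 1, 0, 'X', score - m);
      }
    }
    if (j < M) dfs(i, j + 1, 0, 'I', score - (last == 'I' ? e : open_));
    if (i < N) dfs(i + 1, j, 0, 'D', score - (last == 'D' ? e : open_));
  }
};

}  // namespace

// [[Rcpp::export]]
double cpp_brute_force(std::string target, std::string query, NumericVector delta_f,
                       int depth_cap, double mismatch, double open_cost,
                       double ext_cost, bool local) {
  BF bf;
  bf.t = target.c_str(); bf.q = query.c_str();
  bf.N = (int)target.size(); bf.M = (int)query.size();
  std::vector<double> df(delta_f.begin(), delta_f.end());
  bf.df = df.data(); bf.cap = depth_cap;
  bf.m = mismatch; bf.open_ = open_cost; bf.e = ext_cost; bf.local = local;
  if (local) {
    bf.best = 0.0;  // empty alignment
    for (int si = 0; si <= bf.N; ++si)
      for (int sj = 0; sj <= bf.M; ++sj)
        bf.dfs(si, sj, 0, ' ', 0.0);
  } else {
    bf.best = R_NegInf;
    bf.dfs(0, 0, 0, ' ', 0.0);
  }
  return bf.best;
}
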