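// Dynamic programming core for contiguity-scored pairwise alignment.
//
// The edit graph is three-dimensional: each cell (i,j) holds, besides the
// gap-affine horizontal/vertical states, one node per contiguity depth
// n = 1..d(i,j), where d(i,j) is the length of the matching suffix ending
// at (i,j).  A match arriving at depth n adds the score increment
// delta_f(n) = f(n) - f(n-1); depth nodes are allocated on demand and a
// single node suffices when f is linear (delta_f constant).
//
// The zero-contiguity family Z(i,j) = max(mismatch arrival, gap states,
// local restart) seeds depth node 1, so a match can follow a gap.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const double NEG = -1e18;
static const double REACH = -1e17;  // values below this are unreachable
static const double EPS = 1e-9;

static inline bool eq(double a, double b) {
  return a > REACH && b > REACH && std::fabs(a - b) <= EPS;
}

struct Scheme {
  std::vector<double> df;  // df[n-1] = delta_f(n), length = cap
  int cap;                 // merged depth cap (1 when f is linear)
  double m;                // mismatch penalty
  double open_;            // cost of a gap's first column (rho_o + rho_e; rho_e if linear gaps)
  double e;                // gap extension cost per further column
  bool local;
};

struct Row {
  std::vector<double> best, gH, gV, Z;
  std::vector<int> d;
  std::vector<std::vector<double> > nodes;  // nodes[j][k] = S(i,j,k+1)
  void init(int M1) {
    best.assign(M1, NEG); gH.assign(M1, NEG); gV.assign(M1, NEG);
    Z.assign(M1, NEG); d.assign(M1, 0);
    nodes.assign(M1, std::vector<double>());
  }
};

class Aligner {
public:
  std::string t, q;
  Scheme sc;
  int N, M;
  long band;             // half-width; >= max(N,M) means unbanded
  int maxDepthNodes;     // instrumentation: max depth nodes allocated in any cell
  long long cellsComputed;

  Aligner(const std::string& t_, const std::string& q_, const Scheme& sc_, long band_)
    : t(t_), q(q_), sc(sc_), N((int)t_.size()), M((int)q_.size()),
      band(band_), maxDepthNodes(1), cellsComputed(0) {}

  // band window of permitted columns for row i (inclusive), centred on the
  // resampled main diagonal joining (0,0) and (N,M)
  inline void window(int i, int& jlo, int& jhi) const {
    long c = (long)llround((double)i * M / N);
    long lo = c - band, hi = c + band;
    jlo = (int)std::max(0L, lo);
    jhi = (int)std::min((long)M, hi);
  }

  void initRow0(Row& r) const {
    int jlo, jhi; window(0, jlo, jhi);
    r.init(M + 1);
    if (jlo > 0) return;  // (0,0) out of band cannot happen (centre is 0)
    if (sc.local) {
      for (int j = jlo; j <= jhi; ++j) { r.best[j] = 0; r.Z[j] = 0; }
    } else {
      r.best[0] = 0; r.Z[0] = 0;
      for (int j = std::max(1, jlo); j <= jhi; ++j) {
        double ext = (j - 1 >= jlo && r.gH[j - 1] > REACH) ? r.gH[j - 1] - sc.e : NEG;
        double opn = (j - 1 >= jlo && r.best[j - 1] > REACH) ? r.best[j - 1] - sc.open_ : NEG;
        r.gH[j] = std::max(ext, opn);
        r.best[j] = r.gH[j];
        r.Z[j] = r.gH[j];
      }
    }
  }

  // compute row i (1-based) from row i-1
  void computeRow(int i, const Row& prev, Row& cur) {
    cur.init(M + 1);
    int jlo, jhi; window(i, jlo, jhi);
    int pjlo, pjhi; window(i - 1, pjlo, pjhi);
    char ti = t[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      ++cellsComputed;
      if (j == 0) {
        if (sc.local) { cur.best[0] = 0; cur.Z[0] = 0; }
        else {
          double ext = prev.gV[0] > REACH ? prev.gV[0] - sc.e : NEG;
          double opn = prev.best[0] > REACH ? prev.best[0] - sc.open_ : NEG;
          cur.gV[0] = std::max(ext, opn);
          cur.best[0] = cur.gV[0];
          cur.Z[0] = cur.gV[0];
        }
        continue;
      }
      bool inPrevDiag = (j - 1 >= pjlo && j - 1 <= pjhi);
      bool inPrevUp = (j >= pjlo && j <= pjhi);
      bool match = (ti == q[j - 1] && ti != 'N');

      double mism = NEG;
      if (!match && inPrevDiag && prev.best[j - 1] > REACH)
        mism = prev.best[j - 1] - sc.m;

      double gH = NEG;
      if (j - 1 >= jlo) {
        if (cur.gH[j - 1] > REACH) gH = cur.gH[j - 1] - sc.e;
        if (cur.best[j - 1] > REACH) gH = std::max(gH, cur.best[j - 1] - sc.open_);
      }
      double gV = NEG;
      if (inPrevUp) {
        if (prev.gV[j] > REACH) gV = prev.gV[j] - sc.e;
        if (prev.best[j] > REACH) gV = std::max(gV, prev.best[j] - sc.open_);
      }
      double Z = std::max(std::max(mism, gH), gV);
      if (sc.local) Z = std::max(Z, 0.0);

      double best = Z;
      if (match && inPrevDiag) {
        int dp = prev.d[j - 1];
        int d = dp + 1;
        int nn = std::min(d, sc.cap);
        std::vector<double>& nd = cur.nodes[j];
        nd.resize(nn, NEG);
        if (prev.Z[j - 1] > REACH) nd[0] = prev.Z[j - 1] + sc.df[0];
        const std::vector<double>& pn = prev.nodes[j - 1];
        for (int n = 2; n <= nn; ++n)
          if (pn[n - 2] > REACH) nd[n - 1] = pn[n - 2] + sc.df[n - 1];
        if (d > sc.cap && pn[sc.cap - 1] > REACH)
          nd[sc.cap - 1] = std::max(nd[sc.cap - 1], pn[sc.cap - 1] + sc.df[sc.cap - 1]);
        cur.d[j] = d;
        if (nn > maxDepthNodes) maxDepthNodes = nn;
        for (int n = 0; n < nn; ++n) best = std::max(best, nd[n]);
      }
      cur.gH[j] = gH; cur.gV[j] = gV; cur.Z[j] = Z; cur.best[j] = best;
    }
  }
};

// ------------------------------------------------------------------
// traceback over an abstract row provider

struct RowProvider {
  virtual const Row& getRow(int i) = 0;
  virtual ~RowProvider() {}
};

struct FullMatrix : RowProvider {
  std::vector<Row> rows;
  const Row& getRow(int i) { return rows[i]; }
};

// check-pointed provider: permanent rows at multiples of `interval`,
// blocks between checkpoints recomputed on demand during traceback
struct Checkpointed : RowProvider {
  Aligner* al;
  int interval;
  std::map<int, Row> cp;      // permanent checkpoint rows
  std::map<int, Row> block;   // currently cached recomputed rows
  int peakRows;
  Checkpointed() : al(NULL), interval(1), peakRows(0) {}
  void notePeak() {
    int n = (int)(cp.size() + block.size());
    if (n > peakRows) peakRows = n;
  }
  const Row& getRow(int i) {
    std::map<int, Row>::iterator it = cp.find(i);
    if (it != cp.end()) return it->second;
    it = block.find(i);
    if (it != block.end()) return it->second;
    // drop cached rows above i (traceback proceeds upward only)
    for (std::map<int, Row>::iterator b = block.begin(); b != block.end();)
      if (b->first > i) block.erase(b++); else ++b;
    // recompute from nearest checkpoint at or below i
    std::map<int, Row>::iterator base = cp.upper_bound(i);
    --base;  // largest key <= i (row 0 is always checkpointed)
    int r0 = base->first;
    const Row* prev = &base->second;
    for (int r = r0 + 1; r <= i; ++r) {
      Row nr;
      al->computeRow(r, *prev, nr);
      prev = &(block[r] = nr);
      notePeak();
    }
    return block[i];
  }
};

// ------------------------------------------------------------------
// traceback

struct TraceOut {
  std::string ops;  // per-column ops, reversed during build
  int ti, tj;       // start cell after walk (alignment begins at (ti, tj))
};

static double mismAt(Aligner& A, RowProvider& P, int i, int j) {
  if (i < 1 || j < 1) return NEG;
  bool match = (A.t[i - 1] == A.q[j - 1] && A.t[i - 1] != 'N');
  if (match) return NEG;
  const Row& prev = P.getRow(i - 1);
  int pjlo, pjhi; A.window(i - 1, pjlo, pjhi);
  if (j - 1 < pjlo || j - 1 > pjhi || prev.best[j - 1] <= REACH) return NEG;
  return prev.best[j - 1] - A.sc.m;
}

// walk back from (i,j) starting at the cell-best state
static TraceOut traceback(Aligner& A, RowProvider& P, int i, int j) {
  enum St { S_CELL, S_NODE, S_GH, S_GV, S_Z };
  St st = S_CELL;
  int n = 0;
  TraceOut out;
  for (;;) {
    const Row& cur = P.getRow(i);
    if (st == S_CELL || st == S_Z) {
      double v = (st == S_CELL) ? cur.best[j] : cur.Z[j];
      // priority: deeper match node > mismatch > vertical gap > horizontal gap > restart
      bool resolved = false;
      if (st == S_CELL) {
        const std::vector<double>& nd = cur.nodes[j];
        for (int k = (int)nd.size(); k >= 1 && !resolved; --k)
          if (eq(v, nd[k - 1])) { st = S_NODE; n = k; resolved = true; }
      }
      if (!resolved && eq(v, mismAt(A, P, i, j))) {
        out.ops.push_back('X'); --i; --j; st = S_CELL; continue;
      }
      if (!resolved && eq(v, cur.gV[j])) { st = S_GV; resolved = true; }
      if (!resolved && eq(v, cur.gH[j])) { st = S_GH; resolved = true; }
      if (!resolved) break;  // local restart (v == 0) or boundary origin
      continue;
    }
    if (st == S_NODE) {
      out.ops.push_back('M');
      double v = cur.nodes[j][n - 1];
      const Row& prev = P.getRow(i - 1);
      const std::vector<double>& pn = prev.nodes[j - 1];
      // merged-cap arrival: prefer the deeper (stay-at-cap) predecessor
      if (n == A.sc.cap && (int)pn.size() >= A.sc.cap &&
          eq(v, pn[A.sc.cap - 1] + A.sc.df[A.sc.cap - 1])) {
        --i; --j; st = S_NODE; /* n stays cap */ continue;
      }
      if (n == 1) { --i; --j; st = S_Z; continue; }
      --i; --j; st = S_NODE; n = n - 1; continue;
    }
    if (st == S_GH) {
      out.ops.push_back('I');
      double v = cur.gH[j];
      double ext = (cur.gH[j - 1] > REACH) ? cur.gH[j - 1] - A.sc.e : NEG;
      --j;
      st = eq(v, ext) ? S_GH : S_CELL;
      continue;
    }
    // S_GV
    out.ops.push_back('D');
    double v = cur.gV[j];
    const Row& prev = P.getRow(i - 1);
    double ext = (prev.gV[j] > REACH) ? prev.gV[j] - A.sc.e : NEG;
    --i;
    st = eq(v, ext) ? S_GV : S_CELL;
  }
  out.ti = i; out.tj = j;
  return out;
}

// run-length encode a reversed op string
static void rle(const std::string& rev, std::vector<std::string>& op, std::vector<int>& len) {
  for (int k = (int)rev.size() - 1; k >= 0;) {
    char c = rev[k];
    int l = 0;
    while (k >= 0 && rev[k] == c) { --k; ++l; }
    op.push_back(std::string(1, c));
    len.push_back(l);
  }
}

// [[Rcpp::export]]
List cpp_align(std::string target, std::string query, NumericVector delta_f,
               int depth_cap, double mismatch, double open_cost, double ext_cost,
               bool local, double band_width, int checkpoint_interval) {
  Scheme sc;
  sc.df = std::vector<double>(delta_f.begin(), delta_f.end());
  sc.cap = depth_cap;
  sc.m = mismatch; sc.open_ = open_cost; sc.e = ext_cost; sc.local = local;
  int N = (int)target.size(), M = (int)query.size();
  long band = (band_width < 0 || band_width >= std::max(N, M) ||
               !R_FINITE(band_width))
    ? (long)std::max(N, M) + 1 : (long)band_width;
  Aligner A(target, query, sc, band);

  FullMatrix full;
  Checkpointed cpd;
  RowProvider* prov;
  int peakRows = 0;

  double bestScore; int bi = 0, bj = 0;
  bool found = false;
  bestScore = local ? 0.0 : NEG;

  if (checkpoint_interval <= 0) {
    full.rows.resize(N + 1);
    A.initRow0(full.rows[0]);
    for (int i = 1; i <= N; ++i) A.computeRow(i, full.rows[i - 1], full.rows[i]);
    for (int i = 0; i <= N && local; ++i) {
      int jlo, jhi; A.window(i, jlo, jhi);
      for (int j = jlo; j <= jhi; ++j)
        if (full.rows[i].best[j] > bestScore + EPS) {
          bestScore = full.rows[i].best[j]; bi = i; bj = j; found = true;
        }
    }
    prov = &full;
    peakRows = N + 1;
  } else {
    cpd.al = &A; cpd.interval = checkpoint_interval;
    Row a, b;
    A.initRow0(a);
    cpd.cp[0] = a;
    int nCp = 1;
    Row* prev = &a; Row* cur = &b;
    {
      int jlo, jhi; A.window(0, jlo, jhi);
      for (int j = jlo; j <= jhi; ++j)
        if (prev->best[j] > bestScore + EPS) { bestScore = prev->best[j]; bi = 0; bj = j; found = true; }
    }
    for (int i = 1; i <= N; ++i) {
      A.computeRow(i, *prev, *cur);
      int jlo, jhi; A.window(i, jlo, jhi);
      for (int j = jlo; j <= jhi; ++j)
        if (cur->best[j] > bestScore + EPS) { bestScore = cur->best[j]; bi = i; bj = j; found = true; }
      if (i % checkpoint_interval == 0) { cpd.cp[i] = *cur; ++nCp; }
      std::swap(prev, cur);
      int held = 2 + nCp;
      if (held > peakRows) peakRows = held;
    }
    cpd.peakRows = (int)cpd.cp.size();
    prov = &cpd;
  }

  if (!local) {
    // global end cell fixed at (N, M)
    const Row& last = prov->getRow(N);
    bestScore = last.best[M];
    bi = N; bj = M;
    if (bestScore <= REACH)
      stop("band excludes global path");
    found = true;
  }

  std::vector<std::string> op;
  std::vector<int> len;
  int ti = 0, tj = 0, tend = 0, qend = 0;
  if (local && (!found || bestScore <= EPS)) {
    bestScore = 0.0;  // empty local alignment
  } else {
    TraceOut tr = traceback(A, *prov, bi, bj);
    rle(tr.ops, op, len);
    ti = tr.ti; tj = tr.tj; tend = bi; qend = bj;
  }
  if (checkpoint_interval > 0 && cpd.peakRows > peakRows) peakRows = cpd.peakRows;

  return List::create(
    _["score"] = bestScore,
    _["t_start"] = ti, _["t_end"] = tend,
    _["q_start"] = tj, _["q_end"] = qend,
    _["op"] = op, _["len"] = len,
    _["max_depth_nodes"] = A.maxDepthNodes,
    _["cells_computed"] = (double)A.cellsComputed,
    _["peak_rows"] = peakRows);
}
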