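// Hot loops for the lazy decision-path learner and the population tree.
// Datasets arrive as integer matrices of 1-based domain codes with
// NA_INTEGER marking missing values; the target is a 1-based code vector.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static double entropy_counts(const std::vector<double> &c) {
  double n = 0.0;
  for (double x : c) n += x;
  if (n <= 0.0) return 0.0;
  double h = 0.0;
  for (double x : c)
    if (x > 0.0) {
      double p = x / n;
      h -= p * std::log2(p);
    }
  return h;
}

// Two-sample Dirichlet-multinomial log marginal with alpha_jk = pess/K.
static double bay_two_sample(const std::vector<int> &nin,
                             const std::vector<int> &nout, double pess) {
  int K = (int)nin.size();
  double ajk = pess / K, aj = pess, s = 0.0;
  int Nin = 0, Nout = 0;
  for (int k = 0; k < K; k++) {
    Nin += nin[k];
    Nout += nout[k];
  }
  s += std::lgamma(aj) - std::lgamma(Nin + aj);
  s += std::lgamma(aj) - std::lgamma(Nout + aj);
  for (int k = 0; k < K; k++) {
    s += std::lgamma(nin[k] + ajk) - std::lgamma(ajk);
    s += std::lgamma(nout[k] + ajk) - std::lgamma(ajk);
  }
  return s;
}

// Closed-form pooled leave-one-out AUC for a binary target.  Within each
// subsample every individual of the same class receives the same smoothed
// leave-one-out prediction, so the pooled AUC reduces to pair counting over
// at most four (score, count) groups.  Ties get half credit.
static double auc_loocv(int posIn, int negIn, int posOut, int negOut,
                        double pess) {
  double ap = pess / 2.0;
  std::vector<double> ps, pc, ns, nc;
  int Nin = posIn + negIn, Nout = posOut + negOut;
  if (Nin > 0) {
    double den = pess + Nin - 1;
    if (posIn > 0) {
      ps.push_back((ap + posIn - 1) / den);
      pc.push_back(posIn);
    }
    if (negIn > 0) {
      ns.push_back((ap + posIn) / den);
      nc.push_back(negIn);
    }
  }
  if (Nout > 0) {
    double den = pess + Nout - 1;
    if (posOut > 0) {
      ps.push_back((ap + posOut - 1) / den);
      pc.push_back(posOut);
    }
    if (negOut > 0) {
      ns.push_back((ap + posOut) / den);
      nc.push_back(negOut);
    }
  }
  double P = 0.0, N = 0.0;
  for (double c : pc) P += c;
  for (double c : nc) N += c;
  if (P == 0.0 || N == 0.0) return 0.5;  // undefined AUC convention
  double s = 0.0;
  for (size_t a = 0; a < ps.size(); a++)
    for (size_t b = 0; b < ns.size(); b++) {
      double d = ps[a] - ns[b];
      double w = pc[a] * nc[b];
      if (d > 1e-12)
        s += w;
      else if (d > -1e-12)
        s += 0.5 * w;
    }
  return s / (P * N);
}

// Greedy personalized growth.  criterion: 0 = Bayesian, 1 = info gain,
// 2 = LOOCV AUC.  person holds the test individual's 1-based codes
// (NA_INTEGER = missing, such variables are never candidates).  Candidates
// whose matching subsample would be empty are skipped (they would strand
// the search).  Candidate selection scores the split of the CURRENT
// matching subgroup; the score recorded for pruning is the path-level
// criterion evaluated on the FULL training cohort partitioned into
// path-matching and non-matching individuals, so recorded scores condition
// on the same individuals at every depth and are comparable under the
// argmax pruning rule.  Returns the selected variables (1-based), the
// recorded scores, and the class counts of the matching subgroup after
// each step.
// [[Rcpp::export]]
List cpp_grow_path(IntegerMatrix X, IntegerVector y, int K,
                   IntegerVector person, double pess, int criterion,
                   int positive) {
  int n = X.nrow(), p = X.ncol();
  std::vector<int> idx;
  idx.reserve(n);
  for (int i = 0; i < n; i++) idx.push_back(i);
  std::vector<bool> used(p, false);
  std::vector<int> sel;
  std::vector<double> scores;
  std::vector<std::vector<int>> step_counts;

  std::vector<int> root(K, 0);
  for (int i : idx) root[y[i] - 1]++;
  std::vector<int> cnt = root;

  while (true) {
    int total = (int)idx.size(), nz = 0;
    for (int k = 0; k < K; k++)
      if (cnt[k] > 0) nz++;
    if (total == 0 || nz <= 1) break;  // no individuals left, or pure in T

    int best = -1;
    double best_score = 0.0;
    std::vector<int> best_in;
    int best_Nin = 0;
    for (int v = 0; v < p; v++) {
      if (used[v] || person[v] == NA_INTEGER) continue;
      std::vector<int> nin(K, 0);
      int Nin = 0;
      for (int i : idx) {
        int xv = X(i, v);
        if (xv != NA_INTEGER && xv == person[v]) {
          nin[y[i] - 1]++;
          Nin++;
        }
      }
      int Nout = total - Nin;
      if (Nin == 0) continue;
      double score;
      if (criterion == 0) {
        std::vector<int> nout(K);
        for (int k = 0; k < K; k++) nout[k] = cnt[k] - nin[k];
        score = bay_two_sample(nin, nout, pess);
      } else if (criterion == 1) {
        std::vector<double> cin(K), cout(K), cd(K);
        for (int k = 0; k < K; k++) {
          cin[k] = nin[k];
          cout[k] = cnt[k] - nin[k];
          cd[k] = cnt[k];
        }
        score = entropy_counts(cd) -
                (double)Nin / total * entropy_counts(cin) -
                (double)Nout / total * entropy_counts(cout);
      } else {
        int posIn = nin[positive - 1];
        int posD = cnt[positive - 1];
        score = auc_loocv(posIn, Nin - posIn, posD - posIn,
                          Nout - (posD - posIn), pess);
      }
      if (best < 0 || score > best_score) {  // ties keep the earliest variable
        best = v;
        best_score = score;
        best_in = nin;
        best_Nin = Nin;
      }
    }
    if (best < 0) break;  // every remaining candidate was degenerate

    used[best] = true;
    std::vector<int> nidx;
    nidx.reserve(best_Nin);
    for (int i : idx) {
      int xv = X(i, best);
      if (xv != NA_INTEGER && xv == person[best]) nidx.push_back(i);
    }
    idx.swap(nidx);
    cnt = best_in;

    // path-level score on the full cohort: matches of the extended path
    // (best_in) against everyone else (root - best_in)
    double rec;
    {
      std::vector<int> rest(K);
      int Nmatch = 0, Nroot = 0;
      for (int k = 0; k < K; k++) {
        rest[k] = root[k] - best_in[k];
        Nmatch += best_in[k];
        Nroot += root[k];
      }
      if (criterion == 0) {
        rec = bay_two_sample(best_in, rest, pess);
      } else if (criterion == 1) {
        std::vector<double> cm(best_in.begin(), best_in.end());
        std::vector<double> cr(rest.begin(), rest.end());
        std::vector<double> cd(root.begin(), root.end());
        rec = entropy_counts(cd) -
              (double)Nmatch / Nroot * entropy_counts(cm) -
              (double)(Nroot - Nmatch) / Nroot * entropy_counts(cr);
      } else {
        int posM = best_in[positive - 1];
        int posR = root[positive - 1] - posM;
        rec = auc_loocv(posM, Nmatch - posM, posR,
                        (Nroot - Nmatch) - posR, pess);
      }
    }
    sel.push_back(best + 1);
    scores.push_back(rec);
    step_counts.push_back(best_in);
  }

  int steps = (int)sel.size();
  IntegerMatrix sc(K, steps);
  for (int s = 0; s < steps; s++)
    for (int k = 0; k < K; k++) sc(k, s) = step_counts[s][k];
  return List::create(_["vars"] = wrap(sel), _["scores"] = wrap(scores),
                      _["step_counts"] = sc, _["root_counts"] = wrap(root));
}

// ---------------------------------------------------------------------------
// Population decision tree: top-down multiway recursive splitting maximizing
// information gain, with rows missing the split variable routed to the child
// that received the most training rows.

struct TreeBuild {
  std::vector<int> parent, depth, var, missing_child;
  std::vector<std::vector<int>> counts;    // per node, K class counts
  std::vector<std::vector<int>> children;  // per node, child ids (1-based), empty for leaves
  const IntegerMatrix &X;
  const IntegerVector &y;
  const IntegerVector &nlev;
  int K, min_leaf, max_depth;
  TreeBuild(const IntegerMatrix &X_, const IntegerVector &y_,
            const IntegerVector &nlev_, int K_, int min_leaf_, int max_depth_)
      : X(X_), y(y_), nlev(nlev_), K(K_), min_leaf(min_leaf_),
        max_depth(max_depth_) {}

  int build(const std::vector<int> &rows, int par, int dep,
            std::vector<bool> &used) {
    int id = (int)parent.size();
    parent.push_back(par);
    depth.push_back(dep);
    var.push_back(-1);
    missing_child.push_back(-1);
    std::vector<int> cnt(K, 0);
    for (int i : rows) cnt[y[i] - 1]++;
    counts.push_back(cnt);
    children.push_back(std::vector<int>());

    int nz = 0;
    for (int k = 0; k < K; k++)
      if (cnt[k] > 0) nz++;
    if ((int)rows.size() == 0 || nz <= 1 || dep >= max_depth) return id;

    int p = X.ncol();
    int n = (int)rows.size();
    double node_h = 0.0;
    {
      std::vector<double> cd(cnt.begin(), cnt.end());
      node_h = entropy_counts(cd);
    }
    int best = -1, best_maj = -1;
    double best_gain = 0.0;
    for (int v = 0; v < p; v++) {
      if (used[v]) continue;
      int m = nlev[v];
      std::vector<std::vector<int>> ck(m, std::vector<int>(K, 0));
      std::vector<int> ct(m, 0);
      std::vector<int> miss(K, 0);
      int nmiss = 0;
      for (int i : rows) {
        int xv = X(i, v);
        if (xv == NA_INTEGER) {
          miss[y[i] - 1]++;
          nmiss++;
        } else {
          ck[xv - 1][y[i] - 1]++;
          ct[xv - 1]++;
        }
      }
      int distinct = 0, maj = 0;
      for (int b = 0; b < m; b++) {
        if (ct[b] > 0) distinct++;
        if (ct[b] > ct[maj]) maj = b;
      }
      if (distinct < 2) continue;  // no partition possible
      // merge missing rows into the majority child
      for (int k = 0; k < K; k++) ck[maj][k] += miss[k];
      ct[maj] += nmiss;
      if (min_leaf > 1) {
        bool ok = true;
        for (int b = 0; b < m; b++)
          if (ct[b] > 0 && ct[b] < min_leaf) ok = false;
        if (!ok) continue;
      }
      double gain = node_h;
      for (int b = 0; b < m; b++) {
        if (ct[b] == 0) continue;
        std::vector<double> cb(ck[b].begin(), ck[b].end());
        gain -= (double)ct[b] / n * entropy_counts(cb);
      }
      if (best < 0 || gain > best_gain) {  // ties keep the earliest variable
        best = v;
        best_gain = gain;
        best_maj = maj;
      }
    }
    if (best < 0) return id;  // variables exhausted at this node

    var[id] = best + 1;
    missing_child[id] = best_maj + 1;
    int m = nlev[best];
    std::vector<std::vector<int>> part(m);
    for (int i : rows) {
      int xv = X(i, best);
      int b = (xv == NA_INTEGER) ? best_maj : xv - 1;
      part[b].push_back(i);
    }
    used[best] = true;
    std::vector<int> kids(m);
    for (int b = 0; b < m; b++) kids[b] = build(part[b], id, dep + 1, used) + 1;
    used[best] = false;
    children[id] = kids;
    return id;
  }
};

// [[Rcpp::export]]
List cpp_fit_tree(IntegerMatrix X, IntegerVector y, int K, IntegerVector nlev,
                  int min_leaf, int max_depth) {
  TreeBuild tb(X, y, nlev, K, min_leaf, max_depth);
  std::vector<int> rows;
  rows.reserve(X.nrow());
  for (int i = 0; i < X.nrow(); i++) rows.push_back(i);
  std::vector<bool> used(X.ncol(), false);
  tb.build(rows, -1, 0, used);

  int nn = (int)tb.parent.size();
  IntegerVector parent(nn), depth(nn), var(nn), missing_child(nn);
  IntegerMatrix counts(nn, K);
  List children(nn);
  for (int i = 0; i < nn; i++) {
    parent[i] = tb.parent[i] + 1;  // 0 for root
    depth[i] = tb.depth[i];
    var[i] = tb.var[i] == -1 ? NA_INTEGER : tb.var[i];
    missing_child[i] = tb.missing_child[i] == -1 ? NA_INTEGER
                                                 : tb.missing_child[i];
    for (int k = 0; k < K; k++) counts(i, k) = tb.counts[i][k];
    children[i] = wrap(tb.children[i]);
  }
  return List::create(_["parent"] = parent, _["depth"] = depth, _["var"] = var,
                      _["missing_child"] = missing_child, _["counts"] = counts,
                      _["children"] = children);
}
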