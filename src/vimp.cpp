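#include <Rcpp.h>
using namespace Rcpp;

// Per-tree prediction by traversing the stored ranger tree structure.
// Node arrays are 0-based; a node is terminal iff both child ids are 0
// (node 0 is the root and never a child). For regression trees the terminal
// split.value holds the node mean; for classification trees it holds the
// class value (index into the backend's class.values), and the outcome is
// passed in that same coding so 0-1 loss is a plain inequality.
static inline double tree_pred(const IntegerVector &L, const IntegerVector &R,
                               const IntegerVector &V, const NumericVector &S,
                               const NumericMatrix &X, const int row,
                               const int feat, const double *override_vals,
                               const int override_idx) {
  int node = 0;
  while (true) {
    if (L[node] == 0 && R[node] == 0) return S[node];
    const int v = V[node];
    double x;
    if (override_vals != nullptr && v == feat)
      x = override_vals[override_idx];
    else
      x = X(row, v);
    node = (x <= S[node]) ? L[node] : R[node];
  }
}

static inline double loss(const double pred, const double obs, const int task) {
  if (task == 0) {
    const double d = pred - obs;
    return d * d;
  }
  return pred != obs ? 1.0 : 0.0;
}

// Tree-wise loss on each tree's out-of-bag rows.
// forest: ranger $forest list; X: feature matrix (columns in the order the
// forest was trained on); y: outcome (class-value coding for task == 1);
// oob: list of 1-based row-index vectors per tree; task: 0 regression,
// 1 classification. Returns one loss per tree, NA when a tree has no OOB rows.
// [[Rcpp::export]]
NumericVector cpp_tree_oob_losses(List forest, NumericMatrix X, NumericVector y,
                                  List oob, int task) {
  List childL = forest["child.nodeIDs"];
  List varL = forest["split.varIDs"];
  List valL = forest["split.values"];
  const int ntree = childL.size();
  NumericVector out(ntree);
  for (int t = 0; t < ntree; ++t) {
    List ch = childL[t];
    IntegerVector L = ch[0], R = ch[1];
    IntegerVector V = varL[t];
    NumericVector S = valL[t];
    IntegerVector o = oob[t];
    const int no = o.size();
    if (no == 0) {
      out[t] = NA_REAL;
      continue;
    }
    double acc = 0.0;
    for (int k = 0; k < no; ++k) {
      const int row = o[k] - 1;
      acc += loss(tree_pred(L, R, V, S, X, row, -1, nullptr, 0), y[row], task);
    }
    out[t] = acc / no;
  }
  return out;
}

// Tree-wise OOB loss after replacing one feature's values among the OOB rows.
// permvals: list per tree of a (n_oob x n_perm) matrix of replacement values
// for the feature (column `feat` of X, 1-based). Returns an ntree x n_perm
// matrix of losses (NA rows for trees without OOB rows).
// [[Rcpp::export]]
NumericMatrix cpp_perm_oob_losses(List forest, NumericMatrix X, NumericVector y,
                                  List oob, int feat, List permvals, int task) {
  List childL = forest["child.nodeIDs"];
  List varL = forest["split.varIDs"];
  List valL = forest["split.values"];
  const int ntree = childL.size();
  const int feat0 = feat - 1;
  int nperm = 0;
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix pv = permvals[t];
    if (pv.ncol() > nperm) nperm = pv.ncol();
  }
  NumericMatrix out(ntree, nperm);
  for (int t = 0; t < ntree; ++t) {
    List ch = childL[t];
    IntegerVector L = ch[0], R = ch[1];
    IntegerVector V = varL[t];
    NumericVector S = valL[t];
    IntegerVector o = oob[t];
    NumericMatrix pv = permvals[t];
    const int no = o.size();
    if (no == 0) {
      for (int j = 0; j < nperm; ++j) out(t, j) = NA_REAL;
      continue;
    }
    for (int j = 0; j < nperm; ++j) {
      const double *col = &pv(0, j);
      double acc = 0.0;
      for (int k = 0; k < no; ++k) {
        const int row = o[k] - 1;
        acc += loss(tree_pred(L, R, V, S, X, row, feat0, col, k), y[row], task);
      }
      out(t, j) = acc / no;
    }
  }
  return out;
}
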