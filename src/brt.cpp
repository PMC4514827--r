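// Stagewise gradient boosting for binomial deviance with depth-limited
// exact-greedy regression trees, bagging, shrinkage, and per-leaf Newton
// maximum-likelihood updates. Trees are grown on the gradient residuals
// (y - p) by squared-error split search; leaf values are then refit by full
// one-dimensional Newton iteration of the binomial log-likelihood given the
// current ensemble offsets, so a single unshrunk stump on a binary covariate
// reproduces the per-leaf empirical log-odds exactly.
//
// Split search uses globally presorted feature orders (computed once per
// fit) and a breadth-first single pass per depth level, so each tree costs
// O(depth * p * n) rather than re-sorting per node.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> var, left, right;
  std::vector<double> split, value;
  int addNode() {
    var.push_back(-1); left.push_back(-1); right.push_back(-1);
    split.push_back(0.0); value.push_back(0.0);
    return (int)var.size() - 1;
  }
};

inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

double meanDeviance(const NumericVector& y, const std::vector<double>& F,
                    const std::vector<int>& rows) {
  if (rows.empty()) return NA_REAL;
  double d = 0.0;
  for (int i : rows) {
    double p = sigmoid(F[i]);
    p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
    d += y[i] > 0.5 ? -std::log(p) : -std::log(1.0 - p);
  }
  return 2.0 * d / rows.size();
}

// Per-active-node running state during the single-pass split scan.
struct NodeScan {
  double sumLeft, lastVal;
  int nLeft;
  double bestGain, bestCut;
  int bestVar;
};

} // namespace

// [[Rcpp::export(name = ".brt_fit_cpp")]]
List brt_fit_cpp(NumericMatrix X, NumericVector y, IntegerVector trainRows,
                 IntegerVector valRows, int maxTrees, int maxDepth,
                 double shrinkage, double bagFraction, int minObs,
                 int patience) {
  if (shrinkage <= 0) stop("shrinkage must be > 0");
  const int n = X.nrow(), p = X.ncol();
  std::vector<int> train(trainRows.begin(), trainRows.end());
  std::vector<int> val(valRows.begin(), valRows.end());
  for (int i : train) if (i < 0 || i >= n) stop("train index out of range");

  double ybar = 0.0;
  for (int i : train) ybar += y[i];
  ybar /= train.size();
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  const double f0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, f0);

  // global presort of each feature over all rows (bag rows are filtered
  // per tree while preserving order)
  std::vector<std::vector<int>> order(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    std::vector<int>& o = order[j];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* col = &X(0, j);
    std::stable_sort(o.begin(), o.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  const int nBag = std::max(2, (int)std::floor(bagFraction * train.size()));
  std::vector<int> pool(train);
  std::vector<double> resid(n, 0.0);
  std::vector<char> inBag(n, 0);
  std::vector<int> nodeOf(n, -1);   // active node id per bag row

  std::vector<Tree> trees;
  trees.reserve(256);
  std::vector<double> trainDev, valDev;
  double bestVal = R_PosInf;
  int bestIter = 0;
  const bool useVal = !val.empty();

  for (int m = 0; m < maxTrees; ++m) {
    // bag: partial Fisher-Yates without replacement, R RNG
    std::vector<int> bag;
    if (nBag >= (int)pool.size()) {
      bag = pool;
    } else {
      for (int i = 0; i < nBag; ++i) {
        int j = i + (int)(unif_rand() * (pool.size() - i));
        if (j >= (int)pool.size()) j = (int)pool.size() - 1;
        std::swap(pool[i], pool[j]);
      }
      bag.assign(pool.begin(), pool.begin() + nBag);
    }
    std::fill(inBag.begin(), inBag.end(), 0);
    for (int i : bag) {
      inBag[i] = 1;
      resid[i] = y[i] - sigmoid(F[i]);
      nodeOf[i] = 0;
    }

    Tree t;
    t.addNode();                       // root
    std::vector<int> level{0};        // node ids at the current depth
    std::vector<double> nodeSum(1, 0.0);
    std::vector<int> nodeCnt(1, 0);
    for (int i : bag) { nodeSum[0] += resid[i]; nodeCnt[0]++; }

    for (int depth = 0; depth < maxDepth && !level.empty(); ++depth) {
      const int nAct = (int)level.size();
      std::vector<int> slot(t.var.size(), -1);
      for (int k = 0; k < nAct; ++k) slot[level[k]] = k;
      std::vector<NodeScan> best(nAct);
      for (int k = 0; k < nAct; ++k) {
        best[k].bestGain = 0.0; best[k].bestVar = -1;
      }
      std::vector<NodeScan> run(nAct);
      for (int j = 0; j < p; ++j) {
        for (int k = 0; k < nAct; ++k) {
          run[k].sumLeft = 0.0; run[k].nLeft = 0;
          run[k].lastVal = R_NegInf;
        }
        const double* col = &X(0, j);
        for (int idx = 0; idx < n; ++idx) {
          int r = order[j][idx];
          if (!inBag[r]) continue;
          int nd = nodeOf[r];
          int k = (nd >= 0 && nd < (int)slot.size()) ? slot[nd] : -1;
          if (k < 0) continue;
          NodeScan& s = run[k];
          double v = col[r];
          // nodeSum/nodeCnt are indexed by position within the level
          if (s.nLeft >= minObs && nodeCnt[k] - s.nLeft >= minObs &&
              v > s.lastVal && s.nLeft > 0) {
            double sl = s.sumLeft, tot = nodeSum[k];
            int nl = s.nLeft, nr = nodeCnt[k] - nl;
            double gain = sl * sl / nl + (tot - sl) * (tot - sl) / nr -
                          tot * tot / nodeCnt[k];
            if (gain > best[k].bestGain + 1e-12) {
              best[k].bestGain = gain;
              best[k].bestVar = j;
              best[k].bestCut = 0.5 * (s.lastVal + v);
            }
          }
          s.sumLeft += resid[r];
          s.nLeft++;
          s.lastVal = v;
        }
      }
      // realize the chosen splits; children become the next level
      std::vector<int> nextLevel;
      std::vector<double> nextSum;
      std::vector<int> nextCnt;
      std::vector<char> splitNode(nAct, 0);
      for (int k = 0; k < nAct; ++k) {
        int id = level[k];
        if (best[k].bestVar < 0 || nodeCnt[k] < 2 * minObs) continue;
        t.var[id] = best[k].bestVar;
        t.split[id] = best[k].bestCut;
        int l = t.addNode(), r = t.addNode();
        t.left[id] = l; t.right[id] = r;
        splitNode[k] = 1;
        nextLevel.push_back(l); nextSum.push_back(0.0); nextCnt.push_back(0);
        nextLevel.push_back(r); nextSum.push_back(0.0); nextCnt.push_back(0);
        slot.resize(t.var.size(), -1);
      }
      if (nextLevel.empty()) break;
      std::vector<int> childSlot(t.var.size(), -1);
      for (int k = 0; k < (int)nextLevel.size(); ++k)
        childSlot[nextLevel[k]] = k;
      for (int i : bag) {
        int nd = nodeOf[i];
        if (nd < 0 || t.var[nd] < 0) continue;
        int child = (X(i, t.var[nd]) < t.split[nd]) ? t.left[nd] : t.right[nd];
        nodeOf[i] = child;
        int k = childSlot[child];
        nextSum[k] += resid[i];
        nextCnt[k]++;
      }
      level = nextLevel;
      nodeSum = nextSum;
      nodeCnt = nextCnt;
    }

    // per-leaf Newton MLE of the additive update, on the bag
    const int nn = (int)t.var.size();
    std::vector<std::vector<int>> leafRows(nn);
    for (int i : bag) leafRows[nodeOf[i]].push_back(i);
    for (int id = 0; id < nn; ++id) {
      if (t.var[id] >= 0 || leafRows[id].empty()) continue;
      double gamma = 0.0;
      for (int it = 0; it < 12; ++it) {
        double g = 0.0, h = 0.0;
        for (int i : leafRows[id]) {
          double pr = sigmoid(F[i] + gamma);
          g += y[i] - pr;
          h += pr * (1.0 - pr);
        }
        double step = g / std::max(h, 1e-10);
        gamma += step;
        if (gamma > 10.0) { gamma = 10.0; break; }
        if (gamma < -10.0) { gamma = -10.0; break; }
        if (std::fabs(step) < 1e-10) break;
      }
      t.value[id] = gamma;
    }
    // update all rows (train and validation)
    for (int i = 0; i < n; ++i) {
      int id = 0;
      while (t.var[id] >= 0)
        id = (X(i, t.var[id]) < t.split[id]) ? t.left[id] : t.right[id];
      F[i] += shrinkage * t.value[id];
    }

    trees.push_back(std::move(t));
    trainDev.push_back(meanDeviance(y, F, train));
    if (useVal) {
      double vd = meanDeviance(y, F, val);
      valDev.push_back(vd);
      if (vd < bestVal - 1e-10) { bestVal = vd; bestIter = m + 1; }
      if (m + 1 - bestIter >= patience) break;
    } else {
      bestIter = m + 1;
    }
  }

  int keep = bestIter > 0 ? bestIter : (int)trees.size();
  List treeList(keep);
  for (int m = 0; m < keep; ++m) {
    const Tree& t = trees[m];
    treeList[m] = List::create(
      Named("var") = IntegerVector(t.var.begin(), t.var.end()),
      Named("split") = NumericVector(t.split.begin(), t.split.end()),
      Named("left") = IntegerVector(t.left.begin(), t.left.end()),
      Named("right") = IntegerVector(t.right.begin(), t.right.end()),
      Named("value") = NumericVector(t.value.begin(), t.value.end()));
  }
  return List::create(
    Named("trees") = treeList, Named("f0") = f0,
    Named("shrinkage") = shrinkage, Named("nTrees") = keep,
    Named("trainDeviance") = NumericVector(trainDev.begin(),
                                           trainDev.begin() + keep),
    Named("valDeviance") = useVal
      ? NumericVector(valDev.begin(), valDev.begin() + keep)
      : NumericVector(0));
}

// [[Rcpp::export(name = ".brt_predict_cpp")]]
NumericVector brt_predict_cpp(List trees, double f0, double shrinkage,
                              NumericMatrix X) {
  const int n = X.nrow();
  NumericVector eta(n, f0);
  for (int m = 0; m < trees.size(); ++m) {
    List t = trees[m];
    IntegerVector var = t["var"], left = t["left"], right = t["right"];
    NumericVector split = t["split"], value = t["value"];
    for (int i = 0; i < n; ++i) {
      int id = 0;
      while (var[id] >= 0)
        id = (X(i, var[id]) < split[id]) ? left[id] : right[id];
      eta[i] += shrinkage * value[id];
    }
  }
  return eta;
}
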