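// Path-dependent TreeSHAP for binary-classification random forests.
//
// Each tree contributes its leaf vote (1 = coding, 0 = lncRNA); the forest
// probability is the mean vote, so per-tree attributions averaged over
// trees are additive in probability space: baseline + sum(phi) = f(x).
// Node covers are computed here by routing the in-bag training rows (with
// bootstrap multiplicities) down each tree.
//
// The EXTEND / UNWIND path algebra follows Lundberg et al.'s polynomial-
// time algorithm for exact Shapley values under the tree's own
// path-dependent conditional expectations.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *unique_path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; i--) {
    unique_path[i + 1].pweight += one_fraction * unique_path[i].pweight *
                                  (i + 1) / static_cast<double>(unique_depth + 1);
    unique_path[i].pweight = zero_fraction * unique_path[i].pweight *
                             (unique_depth - i) / static_cast<double>(unique_depth + 1);
  }
}

static void unwind_path(PathElement *unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1) /
                               static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
                               (unique_depth - i) /
                               static_cast<double>(unique_depth + 1);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1)) /
                               static_cast<double>(zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *unique_path, int unique_depth,
                               int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  if (one_fraction != 0) {
    for (int i = unique_depth - 1; i >= 0; --i) {
      const double tmp = next_one_portion /
                         static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight -
                         tmp * zero_fraction * (unique_depth - i);
    }
  } else {
    for (int i = unique_depth - 1; i >= 0; --i) {
      total += unique_path[i].pweight /
               (zero_fraction * static_cast<double>(unique_depth - i));
    }
  }
  return total * (unique_depth + 1);
}

// One tree, one instance. Node arrays are 0-based within the tree;
// children are -1 at leaves.
struct TreeView {
  const int *left, *right, *svar;
  const double *spoint, *leaf_value, *cover;
};

static void tree_shap_recursive(const TreeView &tr, const double *x,
                                double *phi, int node, int unique_depth,
                                PathElement *parent_unique_path,
                                double parent_zero_fraction,
                                double parent_one_fraction,
                                int parent_feature_index) {
  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1,
            unique_path);
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (tr.left[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] +=
          w * (el.one_fraction - el.zero_fraction) * tr.leaf_value[node];
    }
    return;
  }

  const int split_feature = tr.svar[node];
  const int hot = (x[split_feature] <= tr.spoint[node]) ? tr.left[node]
                                                        : tr.right[node];
  const int cold = (hot == tr.left[node]) ? tr.right[node] : tr.left[node];
  const double w = tr.cover[node];
  const double hot_zero_fraction = (w > 0) ? tr.cover[hot] / w : 0.0;
  const double cold_zero_fraction = (w > 0) ? tr.cover[cold] / w : 0.0;
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (unique_path[path_index].feature_index == split_feature) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tr, x, phi, hot, unique_depth + 1, unique_path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(tr, x, phi, cold, unique_depth + 1, unique_path,
                      cold_zero_fraction * incoming_zero_fraction, 0.0,
                      split_feature);
}

static int tree_depth(const int *left, const int *right, int node) {
  if (left[node] < 0) return 1;
  int dl = tree_depth(left, right, left[node]);
  int dr = tree_depth(left, right, right[node]);
  return 1 + (dl > dr ? dl : dr);
}

// [[Rcpp::export]]
List forest_shap_cpp(IntegerVector left, IntegerVector right,
                     IntegerVector svar, NumericVector spoint,
                     NumericVector leaf_value, IntegerVector tree_offset,
                     NumericMatrix xtrain, NumericMatrix inbag,
                     NumericMatrix x) {
  const int n_trees = tree_offset.size() - 1;
  const int n_train = xtrain.nrow();
  const int n = x.nrow();
  const int p = x.ncol();

  // node covers from in-bag routing
  std::vector<double> cover(left.size(), 0.0);
  for (int t = 0; t < n_trees; ++t) {
    const int off = tree_offset[t];
    for (int i = 0; i < n_train; ++i) {
      const double w = inbag(i, t);
      if (w <= 0) continue;
      int node = 0;
      for (;;) {
        cover[off + node] += w;
        if (left[off + node] < 0) break;
        node = (xtrain(i, svar[off + node]) <= spoint[off + node])
                   ? left[off + node] : right[off + node];
      }
    }
  }

  // per-tree baseline: cover-weighted mean leaf value
  double baseline = 0.0;
  int used_trees = 0;
  for (int t = 0; t < n_trees; ++t) {
    const int off = tree_offset[t];
    const int n_nodes = tree_offset[t + 1] - off;
    if (cover[off] <= 0) continue;
    double s = 0;
    for (int j = 0; j < n_nodes; ++j) {
      if (left[off + j] < 0) s += cover[off + j] * leaf_value[off + j];
    }
    baseline += s / cover[off];
    ++used_trees;
  }
  if (used_trees == 0) stop("no tree has in-bag cover");
  baseline /= used_trees;

  NumericMatrix phi(n, p);
  NumericVector fx(n);
  std::vector<double> phi_row(p);
  std::vector<double> xrow(p);

  for (int t = 0; t < n_trees; ++t) {
    const int off = tree_offset[t];
    if (cover[off] <= 0) continue;
    TreeView tr;
    tr.left = &left[off];
    tr.right = &right[off];
    tr.svar = &svar[off];
    tr.spoint = &spoint[off];
    tr.leaf_value = &leaf_value[off];
    tr.cover = &cover[off];
    const int depth = tree_depth(tr.left, tr.right, 0);
    std::vector<PathElement> path((depth + 2) * (depth + 3) / 2 + 2);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = x(i, j);
      std::fill(phi_row.begin(), phi_row.end(), 0.0);
      tree_shap_recursive(tr, xrow.data(), phi_row.data(), 0, 0, path.data(),
                          1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += phi_row[j];
      // tree vote for f(x)
      int node = 0;
      while (tr.left[node] >= 0) {
        node = (xrow[tr.svar[node]] <= tr.spoint[node]) ? tr.left[node]
                                                        : tr.right[node];
      }
      fx[i] += tr.leaf_value[node];
    }
  }
  for (int i = 0; i < n; ++i) {
    fx[i] /= used_trees;
    for (int j = 0; j < p; ++j) phi(i, j) /= used_trees;
  }
  return List::create(_["phi"] = phi, _["baseline"] = baseline,
                      _["fx"] = fx);
}
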