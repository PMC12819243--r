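// Sum-of-trees regression sampler (Chipman-style Bayesian backfitting).
//
// Model: y_i = sum_j g(x_i; T_j, M_j) + e_i, e_i ~ N(0, sigma^2), with the
// standard regularisation priors: leaf values N(0, tau^2), split probability
// alpha * (1 + depth)^-beta at each node, and sigma^2 ~ nu*lambda / chisq_nu.
// Trees are updated one at a time against the residual of the others with
// grow / prune / change Metropolis proposals; leaf values and sigma^2 are
// drawn from their conjugate full conditionals.
//
// All randomness comes from R's RNG so that set.seed() in R fixes the trace.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int var;      // split variable (0-based); -1 for leaf
  double cut;   // split value: x[var] <= cut goes left
  int left;     // child indices; -1 for leaf
  int right;
  int parent;   // -1 for root
  int depth;
  double mu;    // leaf value (only meaningful for leaves)
  bool active;  // false once recycled by a prune
};

typedef std::vector<Node> Tree;

double psplit(int depth, double alpha, double beta) {
  return alpha * std::pow(1.0 + depth, -beta);
}

// log of the integrated leaf likelihood (up to terms common to all states):
// residuals r in a leaf with mu ~ N(0, tau2) marginalised out.
double loglik_leaf(double n, double s, double sigma2, double tau2) {
  if (n <= 0.0) return 0.0;
  double denom = sigma2 + n * tau2;
  return 0.5 * std::log(sigma2 / denom) + tau2 * s * s / (2.0 * sigma2 * denom);
}

int leaf_of(const Tree& tree, const NumericMatrix& X, int i) {
  int node = 0;
  while (tree[node].var >= 0) {
    node = (X(i, tree[node].var) <= tree[node].cut) ? tree[node].left
                                                    : tree[node].right;
  }
  return node;
}

void collect_leaves(const Tree& tree, std::vector<int>& leaves) {
  leaves.clear();
  for (size_t k = 0; k < tree.size(); ++k)
    if (tree[k].active && tree[k].var < 0) leaves.push_back((int)k);
}

// "nog" nodes: internal nodes whose both children are leaves (prunable).
void collect_nog(const Tree& tree, std::vector<int>& nog) {
  nog.clear();
  for (size_t k = 0; k < tree.size(); ++k) {
    const Node& nd = tree[k];
    if (nd.active && nd.var >= 0 &&
        tree[nd.left].var < 0 && tree[nd.right].var < 0)
      nog.push_back((int)k);
  }
}

int count_nog_after_grow(const Tree& tree, int grown_leaf) {
  // after growing at grown_leaf, it becomes a nog node; its parent (if it was
  // nog) stops being one.
  std::vector<int> nog;
  collect_nog(tree, nog);
  int n = (int)nog.size() + 1;
  int par = tree[grown_leaf].parent;
  if (par >= 0) {
    const Node& p = tree[par];
    if (tree[p.left].var < 0 && tree[p.right].var < 0) n -= 1;
  }
  return n;
}

int runif_int(int n) {  // uniform on 0..n-1
  int k = (int)std::floor(R::unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

int alloc_node(Tree& tree, std::vector<int>& freelist) {
  if (!freelist.empty()) {
    int k = freelist.back();
    freelist.pop_back();
    return k;
  }
  tree.push_back(Node());
  return (int)tree.size() - 1;
}

}  // namespace

// [[Rcpp::export(name = ".bart_mcmc")]]
List bart_mcmc(NumericMatrix X, NumericVector y, List cutpoints,
               int ntree, double tau2, double nu, double lambda,
               double alpha, double beta,
               int nburn, int nkeep,
               double prob_grow, double prob_prune,
               int min_leaf, double sigma2_init) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int ndraw = nburn + nkeep;

  std::vector<std::vector<double> > cuts(p);
  for (int v = 0; v < p; ++v) cuts[v] = as<std::vector<double> >(cutpoints[v]);

  // forests: one single-leaf tree each, plus per-tree obs->leaf map and fit.
  std::vector<Tree> forest(ntree);
  std::vector<std::vector<int> > freelist(ntree);
  std::vector<std::vector<int> > leafidx(ntree, std::vector<int>(n, 0));
  std::vector<std::vector<double> > treefit(ntree, std::vector<double>(n, 0.0));
  for (int j = 0; j < ntree; ++j) {
    Node root;
    root.var = -1; root.cut = 0.0; root.left = -1; root.right = -1;
    root.parent = -1; root.depth = 0; root.mu = 0.0; root.active = true;
    forest[j].push_back(root);
  }

  std::vector<double> fit(n, 0.0);   // sum over trees
  double sigma2 = sigma2_init;

  // outputs
  NumericMatrix yhat_draws(nkeep, n);
  NumericVector sigma_draws(nkeep);
  NumericMatrix vip_draws(nkeep, p);
  // serialized kept forests: one row per node
  std::vector<double> ser_var, ser_cut, ser_left, ser_right, ser_mu;
  std::vector<int> tree_offsets;  // start row of each kept (draw, tree)

  std::vector<int> leaves, nog;
  std::vector<double> r(n);

  for (int draw = 0; draw < ndraw; ++draw) {
    for (int j = 0; j < ntree; ++j) {
      Tree& tree = forest[j];
      std::vector<int>& li = leafidx[j];

      // residual against the other trees
      for (int i = 0; i < n; ++i) r[i] = y[i] - (fit[i] - treefit[j][i]);

      collect_leaves(tree, leaves);
      double u = R::unif_rand();
      bool single_leaf = (leaves.size() == 1);

      if (u < prob_grow || (single_leaf && u < prob_grow + prob_prune)) {
        // ---- GROW ----
        int L = leaves[runif_int((int)leaves.size())];
        int v = runif_int(p);
        int nc = (int)cuts[v].size();
        if (nc > 0) {
          double cut = cuts[v][runif_int(nc)];
          double nl = 0, nr = 0, sl = 0, sr = 0, stot = 0;
          for (int i = 0; i < n; ++i) {
            if (li[i] != L) continue;
            stot += r[i];
            if (X(i, v) <= cut) { nl += 1; sl += r[i]; }
            else { nr += 1; sr += r[i]; }
          }
          if (nl >= min_leaf && nr >= min_leaf) {
            int d = tree[L].depth;
            double lp = std::log(psplit(d, alpha, beta)) +
                        2.0 * std::log(1.0 - psplit(d + 1, alpha, beta)) -
                        std::log(1.0 - psplit(d, alpha, beta));
            double ll = loglik_leaf(nl, sl, sigma2, tau2) +
                        loglik_leaf(nr, sr, sigma2, tau2) -
                        loglik_leaf(nl + nr, stot, sigma2, tau2);
            int nnog_new = count_nog_after_grow(tree, L);
            double lq = std::log(prob_prune) - std::log((double)nnog_new) -
                        std::log(prob_grow) + std::log((double)leaves.size());
            if (std::log(R::unif_rand()) < lp + ll + lq) {
              int kl = alloc_node(tree, freelist[j]);
              int kr = alloc_node(tree, freelist[j]);
              Node& ln = tree[kl];
              ln.var = -1; ln.left = ln.right = -1; ln.parent = L;
              ln.depth = tree[L].depth + 1; ln.mu = 0.0; ln.active = true;
              Node& rn = tree[kr];
              rn.var = -1; rn.left = rn.right = -1; rn.parent = L;
              rn.depth = tree[L].depth + 1; rn.mu = 0.0; rn.active = true;
              tree[L].var = v; tree[L].cut = cut;
              tree[L].left = kl; tree[L].right = kr;
              for (int i = 0; i < n; ++i)
                if (li[i] == L) li[i] = (X(i, v) <= cut) ? kl : kr;
            }
          }
        }
      } else if (u < prob_grow + prob_prune) {
        // ---- PRUNE ----
        collect_nog(tree, nog);
        if (!nog.empty()) {
          int N = nog[runif_int((int)nog.size())];
          int kl = tree[N].left, kr = tree[N].right;
          double nl = 0, nr = 0, sl = 0, sr = 0;
          for (int i = 0; i < n; ++i) {
            if (li[i] == kl) { nl += 1; sl += r[i]; }
            else if (li[i] == kr) { nr += 1; sr += r[i]; }
          }
          int d = tree[N].depth;
          double lp = std::log(1.0 - psplit(d, alpha, beta)) -
                      std::log(psplit(d, alpha, beta)) -
                      2.0 * std::log(1.0 - psplit(d + 1, alpha, beta));
          double ll = loglik_leaf(nl + nr, sl + sr, sigma2, tau2) -
                      loglik_leaf(nl, sl, sigma2, tau2) -
                      loglik_leaf(nr, sr, sigma2, tau2);
          int nleaves_after = (int)leaves.size() - 1;
          double lq = std::log(prob_grow) - std::log((double)nleaves_after) -
                      std::log(prob_prune) + std::log((double)nog.size());
          if (std::log(R::unif_rand()) < lp + ll + lq) {
            tree[kl].active = false; tree[kr].active = false;
            freelist[j].push_back(kl); freelist[j].push_back(kr);
            tree[N].var = -1; tree[N].left = -1; tree[N].right = -1;
            tree[N].mu = 0.0;
            for (int i = 0; i < n; ++i)
              if (li[i] == kl || li[i] == kr) li[i] = N;
          }
        }
      } else {
        // ---- CHANGE (new rule at a prunable node) ----
        collect_nog(tree, nog);
        if (!nog.empty()) {
          int N = nog[runif_int((int)nog.size())];
          int kl = tree[N].left, kr = tree[N].right;
          int v = runif_int(p);
          int nc = (int)cuts[v].size();
          if (nc > 0) {
            double cut = cuts[v][runif_int(nc)];
            double nl_o = 0, nr_o = 0, sl_o = 0, sr_o = 0;
            double nl_n = 0, nr_n = 0, sl_n = 0, sr_n = 0;
            for (int i = 0; i < n; ++i) {
              bool inl = (li[i] == kl), inr = (li[i] == kr);
              if (!inl && !inr) continue;
              if (inl) { nl_o += 1; sl_o += r[i]; }
              else { nr_o += 1; sr_o += r[i]; }
              if (X(i, v) <= cut) { nl_n += 1; sl_n += r[i]; }
              else { nr_n += 1; sr_n += r[i]; }
            }
            if (nl_n >= min_leaf && nr_n >= min_leaf) {
              double ll = loglik_leaf(nl_n, sl_n, sigma2, tau2) +
                          loglik_leaf(nr_n, sr_n, sigma2, tau2) -
                          loglik_leaf(nl_o, sl_o, sigma2, tau2) -
                          loglik_leaf(nr_o, sr_o, sigma2, tau2);
              if (std::log(R::unif_rand()) < ll) {
                tree[N].var = v; tree[N].cut = cut;
                for (int i = 0; i < n; ++i)
                  if (li[i] == kl || li[i] == kr)
                    li[i] = (X(i, v) <= cut) ? kl : kr;
              }
            }
          }
        }
      }

      // ---- draw leaf values from the conjugate posterior ----
      collect_leaves(tree, leaves);
      std::vector<double> cnt(leaves.size(), 0.0), sum(leaves.size(), 0.0);
      std::vector<int> which(tree.size(), -1);
      for (size_t k = 0; k < leaves.size(); ++k) which[leaves[k]] = (int)k;
      for (int i = 0; i < n; ++i) {
        int k = which[li[i]];
        cnt[k] += 1; sum[k] += r[i];
      }
      for (size_t k = 0; k < leaves.size(); ++k) {
        double denom = sigma2 + cnt[k] * tau2;
        double mean = tau2 * sum[k] / denom;
        double sd = std::sqrt(sigma2 * tau2 / denom);
        tree[leaves[k]].mu = mean + sd * R::norm_rand();
      }
      for (int i = 0; i < n; ++i) {
        double newfit = tree[li[i]].mu;
        fit[i] += newfit - treefit[j][i];
        treefit[j][i] = newfit;
      }
    }

    // ---- sigma^2 full conditional ----
    double sse = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = y[i] - fit[i];
      sse += e * e;
    }
    sigma2 = (nu * lambda + sse) / R::rchisq(nu + n);

    if (draw >= nburn) {
      int kd = draw - nburn;
      for (int i = 0; i < n; ++i) yhat_draws(kd, i) = fit[i];
      sigma_draws[kd] = std::sqrt(sigma2);
      // split tally and serialization
      std::vector<double> counts(p, 0.0);
      double total = 0.0;
      for (int j = 0; j < ntree; ++j) {
        const Tree& tree = forest[j];
        tree_offsets.push_back((int)ser_var.size());
        // DFS flatten with remapped child indices (relative to tree start)
        std::vector<int> remap(tree.size(), -1);
        std::vector<int> order;
        std::vector<int> stack(1, 0);
        while (!stack.empty()) {
          int k = stack.back(); stack.pop_back();
          remap[k] = (int)order.size();
          order.push_back(k);
          if (tree[k].var >= 0) {
            stack.push_back(tree[k].right);
            stack.push_back(tree[k].left);
          }
        }
        for (size_t q = 0; q < order.size(); ++q) {
          const Node& nd = tree[order[q]];
          ser_var.push_back(nd.var);
          ser_cut.push_back(nd.cut);
          ser_left.push_back(nd.var >= 0 ? remap[nd.left] : -1);
          ser_right.push_back(nd.var >= 0 ? remap[nd.right] : -1);
          ser_mu.push_back(nd.mu);
          if (nd.var >= 0) { counts[nd.var] += 1; total += 1; }
        }
      }
      if (total > 0) {
        for (int v = 0; v < p; ++v) vip_draws(kd, v) = counts[v] / total;
      } else {
        for (int v = 0; v < p; ++v) vip_draws(kd, v) = 1.0 / p;
      }
    }
  }

  int nnodes = (int)ser_var.size();
  NumericMatrix nodes(nnodes, 5);
  for (int k = 0; k < nnodes; ++k) {
    nodes(k, 0) = ser_var[k];
    nodes(k, 1) = ser_cut[k];
    nodes(k, 2) = ser_left[k];
    nodes(k, 3) = ser_right[k];
    nodes(k, 4) = ser_mu[k];
  }

  return List::create(
      _["yhat_draws"] = yhat_draws,
      _["sigma_draws"] = sigma_draws,
      _["vip_draws"] = vip_draws,
      _["nodes"] = nodes,
      _["tree_offsets"] = wrap(tree_offsets),
      _["ntree"] = ntree,
      _["nkeep"] = nkeep);
}

// Posterior prediction from a serialized forest. Returns the posterior-mean
// prediction per row of X; if draws = true, the full nkept x nrow matrix.
// thin > 1 uses every thin-th kept draw (ALE calls are prediction-heavy).
// [[Rcpp::export(name = ".bart_predict_cpp")]]
SEXP bart_predict_cpp(NumericMatrix nodes, IntegerVector tree_offsets,
                      int ntree, int nkeep, NumericMatrix X,
                      bool draws, int thin) {
  const int n = X.nrow();
  std::vector<int> use;
  for (int d = 0; d < nkeep; d += thin) use.push_back(d);
  const int nd = (int)use.size();

  NumericMatrix out_draws;
  NumericVector out_mean(n);
  if (draws) out_draws = NumericMatrix(nd, n);

  for (int di = 0; di < nd; ++di) {
    int d = use[di];
    for (int i = 0; i < n; ++i) {
      double pred = 0.0;
      for (int j = 0; j < ntree; ++j) {
        int off = tree_offsets[d * ntree + j];
        int k = 0;
        while (nodes(off + k, 0) >= 0) {
          int v = (int)nodes(off + k, 0);
          k = (X(i, v) <= nodes(off + k, 1)) ? (int)nodes(off + k, 2)
                                             : (int)nodes(off + k, 3);
        }
        pred += nodes(off + k, 4);
      }
      if (draws) out_draws(di, i) = pred;
      out_mean[i] += pred / nd;
    }
  }
  if (draws) return out_draws;
  return out_mean;
}
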