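// Metropolis-within-Gibbs sampler for the symmetric alpha-stable trait model
// on a rooted chronogram. The standardised stable log-density is interpolated
// bilinearly from an (alpha, asinh(z)) grid built in R; the Bergstrom
// power-law series covers the far tail and exact Gaussian handles alpha = 2.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Grid {
  NumericVector alpha_grid;
  NumericMatrix logf; // n_alpha x n_s
  double ds, zmax;
  int n_alpha, n_s;
};

Grid as_grid(const List& g) {
  Grid gr;
  gr.alpha_grid = g["alpha_grid"];
  gr.logf = as<NumericMatrix>(g["logf"]);
  gr.ds = as<double>(g["ds"]);
  gr.zmax = as<double>(g["zmax"]);
  gr.n_alpha = gr.alpha_grid.size();
  gr.n_s = as<int>(g["n_s"]);
  return gr;
}

inline double tail_logpdf(double z, double alpha) {
  double t1 = std::tgamma(alpha + 1.0) * std::sin(M_PI * alpha / 2.0) /
              (M_PI * std::pow(z, alpha + 1.0));
  double t2 = -std::tgamma(2.0 * alpha + 1.0) * std::sin(M_PI * alpha) /
              (2.0 * M_PI * std::pow(z, 2.0 * alpha + 1.0));
  double f = t1 + t2;
  if (f <= 0) f = t1; // second term overshoots only where it is negligible
  return std::log(f);
}

// log density of a stable increment x at dispersion `scale`
double logdstable(double x, double alpha, double scale, const Grid& gr) {
  double a1 = gr.alpha_grid[gr.n_alpha - 1];
  if (alpha > a1) // beyond the last tabulated index: exact Gaussian (alpha=2)
    return R::dnorm(x, 0.0, M_SQRT2 * scale, 1);
  double z = std::fabs(x) / scale;
  if (z > gr.zmax) return tail_logpdf(z, alpha) - std::log(scale);
  // clamp alpha into the tabulated range (sampler support equals the range)
  double a0 = gr.alpha_grid[0];
  double a = std::max(alpha, a0);
  const double* ag = &gr.alpha_grid[0];
  int ia = (int)(std::upper_bound(ag, ag + gr.n_alpha, a) - ag) - 1;
  if (ia < 0) ia = 0;
  if (ia > gr.n_alpha - 2) ia = gr.n_alpha - 2;
  double wa = (a - ag[ia]) / (ag[ia + 1] - ag[ia]);
  double s = std::asinh(z);
  double fs = s / gr.ds;
  int is = std::min((int)fs, gr.n_s - 2);
  double ws = fs - is;
  double lf =
      (1 - wa) * ((1 - ws) * gr.logf(ia, is) + ws * gr.logf(ia, is + 1)) +
      wa * ((1 - ws) * gr.logf(ia + 1, is) + ws * gr.logf(ia + 1, is + 1));
  return lf - std::log(scale);
}

} // namespace

// [[Rcpp::export]]
double cpp_stable_loglik(IntegerMatrix edge, NumericVector elen,
                         NumericVector x, int ntip, double alpha, double cc,
                         List grid) {
  Grid gr = as_grid(grid);
  int E = edge.nrow();
  double ll = 0.0, inva = 1.0 / alpha;
  for (int e = 0; e < E; ++e) {
    double sc = cc * std::pow(elen[e], inva);
    ll += logdstable(x[edge(e, 1) - 1] - x[edge(e, 0) - 1], alpha, sc, gr);
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_run_chain(IntegerMatrix edge, NumericVector elen, int ntip,
                   NumericVector x0, double alpha0, double c0, List grid,
                   List opts) {
  Grid gr = as_grid(grid);
  const int E = edge.nrow();
  const int nn = x0.size();
  const int nint = nn - ntip; // internal nodes, root = index ntip (0-based)

  const int niter = as<int>(opts["iterations"]);
  const int burnin = as<int>(opts["burnin"]);
  const int thin = as<int>(opts["thin"]);
  const bool alpha_fixed = as<bool>(opts["alpha_fixed"]);
  const double alpha_lo = as<double>(opts["alpha_min"]);
  const double alpha_hi = 2.0;
  const double logc_lo = as<double>(opts["logc_lo"]);
  const double logc_hi = as<double>(opts["logc_hi"]);
  const int subtree_every = as<int>(opts["subtree_every"]);

  std::vector<double> x(x0.begin(), x0.end());
  double alpha = alpha0, lc = std::log(c0);

  // incident edges per internal node
  std::vector<std::vector<int>> inc(nint);
  std::vector<std::vector<int>> child_edges(nn);
  for (int e = 0; e < E; ++e) {
    int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    child_edges[p].push_back(e);
    if (p >= ntip) inc[p - ntip].push_back(e);
    if (ch >= ntip) inc[ch - ntip].push_back(e);
  }
  // subtree-shift bookkeeping: shifted set = internal node + its internal
  // descendants; boundary edges have exactly one endpoint shifted
  std::vector<std::vector<int>> sub_nodes(nint), sub_bound(nint);
  for (int v = 0; v < nint; ++v) {
    std::vector<char> in_set(nn, 0);
    std::vector<int> stack{v + ntip};
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      in_set[u] = 1;
      sub_nodes[v].push_back(u);
      for (int e : child_edges[u]) {
        int ch = edge(e, 1) - 1;
        if (ch >= ntip) stack.push_back(ch);
      }
    }
    for (int e = 0; e < E; ++e) {
      int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      if (in_set[p] != in_set[ch]) sub_bound[v].push_back(e);
    }
  }

  // per-edge scales and log-likelihood cache
  std::vector<double> sc(E), ell(E);
  auto refresh_scales = [&](double a, double lcc) {
    double ia = 1.0 / a, c = std::exp(lcc);
    for (int e = 0; e < E; ++e) sc[e] = c * std::pow(elen[e], ia);
  };
  auto edge_ll = [&](int e, double a) {
    return logdstable(x[edge(e, 1) - 1] - x[edge(e, 0) - 1], a, sc[e], gr);
  };
  refresh_scales(alpha, lc);
  double total = 0.0;
  for (int e = 0; e < E; ++e) { ell[e] = edge_ll(e, alpha); total += ell[e]; }
  if (!std::isfinite(total))
    stop("non-finite likelihood at initialization (loglik = %f)", total);

  // adaptive step sizes (Robbins-Monro on log step, burn-in only)
  std::vector<double> lstep_node(nint, std::log(0.5));
  double lstep_alpha = std::log(0.1), lstep_c = std::log(0.3),
         lstep_shift = std::log(0.5);
  long n_node = 0, n_alpha_p = 0, n_c_p = 0, n_shift = 0;
  long a_node = 0, a_alpha = 0, a_c = 0, a_shift = 0;
  auto adapt = [](double& ls, long n, bool acc, double target) {
    double eta = 2.0 / std::pow(10.0 + n, 0.6);
    ls += eta * ((acc ? 1.0 : 0.0) - target);
    ls = std::min(std::max(ls, -12.0), 4.0);
  };

  const int ndraw = (niter - burnin + thin - 1) / thin;
  NumericVector d_alpha(ndraw), d_c(ndraw), d_ll(ndraw);
  NumericMatrix d_node(ndraw, nint);
  double best_ll = -INFINITY, best_alpha = alpha, best_c = std::exp(lc);
  std::vector<double> best_x(x.begin() + ntip, x.end());

  std::vector<double> prop_ell(E);
  int idraw = 0;
  for (int it = 0; it < niter; ++it) {
    bool adapting = it < burnin;
    // --- single-node updates ---
    for (int v = 0; v < nint; ++v) {
      int node = v + ntip;
      double step = std::exp(lstep_node[v]);
      double old = x[node];
      x[node] = old + step * R::norm_rand();
      double dll = 0.0;
      for (size_t j = 0; j < inc[v].size(); ++j)
        prop_ell[j] = edge_ll(inc[v][j], alpha);
      for (size_t j = 0; j < inc[v].size(); ++j) dll += prop_ell[j] - ell[inc[v][j]];
      ++n_node;
      bool acc = std::isfinite(dll) && std::log(R::unif_rand()) < dll;
      if (acc) {
        for (size_t j = 0; j < inc[v].size(); ++j) ell[inc[v][j]] = prop_ell[j];
        total += dll;
        ++a_node;
      } else {
        x[node] = old;
      }
      if (adapting) adapt(lstep_node[v], n_node / nint + 1, acc, 0.44);
    }
    // --- alpha move (reflected random walk, uniform prior) ---
    if (!alpha_fixed) {
      double ap = alpha + std::exp(lstep_alpha) * R::norm_rand();
      for (int guard = 0; guard < 64 && (ap < alpha_lo || ap > alpha_hi); ++guard) {
        if (ap < alpha_lo) ap = 2.0 * alpha_lo - ap;
        if (ap > alpha_hi) ap = 2.0 * alpha_hi - ap;
      }
      ap = std::min(std::max(ap, alpha_lo), alpha_hi);
      double c = std::exp(lc), iap = 1.0 / ap;
      double newtot = 0.0;
      std::vector<double> nsc(E);
      for (int e = 0; e < E; ++e) {
        nsc[e] = c * std::pow(elen[e], iap);
        prop_ell[e] = logdstable(x[edge(e, 1) - 1] - x[edge(e, 0) - 1], ap,
                                 nsc[e], gr);
        newtot += prop_ell[e];
      }
      ++n_alpha_p;
      bool acc = std::isfinite(newtot) && std::log(R::unif_rand()) < newtot - total;
      if (acc) {
        alpha = ap; total = newtot;
        sc = nsc;
        std::copy(prop_ell.begin(), prop_ell.end(), ell.begin());
        ++a_alpha;
      }
      if (adapting) adapt(lstep_alpha, n_alpha_p, acc, 0.3);
    }
    // --- dispersion move (random walk on log c, uniform prior on a box) ---
    {
      double lcp = lc + std::exp(lstep_c) * R::norm_rand();
      ++n_c_p;
      bool acc = false;
      if (lcp >= logc_lo && lcp <= logc_hi) {
        double c = std::exp(lcp), ia2 = 1.0 / alpha;
        double newtot = 0.0;
        std::vector<double> nsc(E);
        for (int e = 0; e < E; ++e) {
          nsc[e] = c * std::pow(elen[e], ia2);
          prop_ell[e] = logdstable(x[edge(e, 1) - 1] - x[edge(e, 0) - 1],
                                   alpha, nsc[e], gr);
          newtot += prop_ell[e];
        }
        acc = std::isfinite(newtot) && std::log(R::unif_rand()) < newtot - total;
        if (acc) {
          lc = lcp; total = newtot;
          sc = nsc;
          std::copy(prop_ell.begin(), prop_ell.end(), ell.begin());
        }
      }
      if (acc) ++a_c;
      if (adapting) adapt(lstep_c, n_c_p, acc, 0.3);
    }
    // --- subtree shift ---
    if (subtree_every > 0 && (it + 1) % subtree_every == 0) {
      int v = (int)(R::unif_rand() * nint);
      if (v == nint) v = nint - 1;
      double delta = std::exp(lstep_shift) * R::norm_rand();
      for (int u : sub_nodes[v]) x[u] += delta;
      double dll = 0.0;
      const std::vector<int>& be = sub_bound[v];
      for (size_t j = 0; j < be.size(); ++j) {
        prop_ell[j] = edge_ll(be[j], alpha);
        dll += prop_ell[j] - ell[be[j]];
      }
      ++n_shift;
      bool acc = std::isfinite(dll) && std::log(R::unif_rand()) < dll;
      if (acc) {
        for (size_t j = 0; j < be.size(); ++j) ell[be[j]] = prop_ell[j];
        total += dll;
        ++a_shift;
      } else {
        for (int u : sub_nodes[v]) x[u] -= delta;
      }
      if (adapting) adapt(lstep_shift, n_shift, acc, 0.234);
    }
    // --- record ---
    if (it >= burnin) {
      if (total > best_ll) {
        best_ll = total; best_alpha = alpha; best_c = std::exp(lc);
        std::copy(x.begin() + ntip, x.end(), best_x.begin());
      }
      if ((it - burnin) % thin == 0 && idraw < ndraw) {
        d_alpha[idraw] = alpha;
        d_c[idraw] = std::exp(lc);
        d_ll[idraw] = total;
        for (int v = 0; v < nint; ++v) d_node(idraw, v) = x[ntip + v];
        ++idraw;
      }
    }
  }

  return List::create(
      _["alpha"] = d_alpha, _["c"] = d_c, _["loglik"] = d_ll,
      _["node"] = d_node,
      _["map"] = List::create(_["alpha"] = best_alpha, _["c"] = best_c,
                              _["node"] = NumericVector(best_x.begin(), best_x.end()),
                              _["loglik"] = best_ll),
      _["accept"] = NumericVector::create(
          _["node"] = n_node ? (double)a_node / n_node : NA_REAL,
          _["alpha"] = n_alpha_p ? (double)a_alpha / n_alpha_p : NA_REAL,
          _["c"] = n_c_p ? (double)a_c / n_c_p : NA_REAL,
          _["shift"] = n_shift ? (double)a_shift / n_shift : NA_REAL));
}
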