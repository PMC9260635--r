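// Core numerical kernels: transition probabilities and Felsenstein pruning
// over compressed site patterns. Kept in C++ so the bootstrap root search
// stays interactive at typical problem sizes.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Matrix exponential of a general square matrix (scaling-and-squaring Pade
// via Armadillo); the fallback when the eigenbasis of Q is ill-conditioned.
// [[Rcpp::export]]
arma::mat expmat_cpp(const arma::mat& A) {
  return arma::expmat(A);
}

namespace {

// One-off spectral factorization of Q so that P(t) for many branch lengths
// costs a K x K complex reconstruction instead of a full Pade pass each
// time. Falls back to expmat per branch when the eigenbasis is unusable.
struct QSpectral {
  arma::cx_vec eigval;
  arma::cx_mat V, Vinv;
  arma::mat Q;
  bool ok = false;

  explicit QSpectral(const arma::mat& Qin) : Q(Qin) {
    arma::cx_mat Vtmp;
    arma::cx_vec lam;
    if (arma::eig_gen(lam, Vtmp, Qin)) {
      arma::cx_mat Vi;
      if (arma::inv(Vi, Vtmp)) {
        // reject near-defective eigenbases
        double cond = arma::norm(Vtmp, 2) * arma::norm(Vi, 2);
        if (std::isfinite(cond) && cond < 1e12) {
          eigval = lam; V = Vtmp; Vinv = Vi; ok = true;
        }
      }
    }
  }

  arma::mat P(const double t) const {
    const int K = Q.n_rows;
    arma::mat out;
    if (ok) {
      arma::cx_mat D = arma::diagmat(arma::exp(eigval * t));
      out = arma::real(V * D * Vinv);
    } else {
      out = arma::expmat(Q * t);
    }
    out.clamp(0.0, arma::datum::inf);
    return out;
  }
};

// peel the whole tree below (and excluding) the edges incident to `root`,
// leaving one conditional-likelihood matrix per root child; shared by the
// full log-likelihood and the root-position profile
struct PeelResult {
  std::vector<arma::mat> partial;  // indexed by node id
  arma::rowvec logscale;
};

PeelResult peel_below_root(const arma::imat& edge,
                           const arma::vec& lengths,
                           const arma::imat& patterns,
                           const QSpectral& spec,
                           const int nnode_total,
                           const int root,
                           const bool skip_root_edges) {
  const int K = spec.Q.n_rows;
  const int ntip = patterns.n_rows;
  const int npat = patterns.n_cols;
  const int nedge = edge.n_rows;

  PeelResult res;
  res.partial.resize(nnode_total + 1);
  res.logscale = arma::rowvec(npat, arma::fill::zeros);
  std::vector<bool> touched(nnode_total + 1, false);

  for (int e = 0; e < nedge; ++e) {
    const int parent = edge(e, 0);
    const int child = edge(e, 1);
    if (skip_root_edges && parent == root) {
      // leave the child's own partial in place for the caller
      if (child <= ntip && !touched[child]) {
        arma::mat ind(K, npat, arma::fill::ones);
        for (int s = 0; s < npat; ++s) {
          const int st = patterns(child - 1, s);
          if (st != 0) {
            ind.col(s).zeros();
            ind(st - 1, s) = 1.0;
          }
        }
        res.partial[child] = std::move(ind);
        touched[child] = true;
      }
      continue;
    }

    arma::mat P = spec.P(lengths(e));

    arma::mat down(K, npat);
    if (child <= ntip) {
      for (int s = 0; s < npat; ++s) {
        const int st = patterns(child - 1, s);
        if (st == 0) down.col(s).ones();
        else down.col(s) = P.col(st - 1);
      }
    } else {
      down = P * res.partial[child];
    }

    if (!touched[parent]) {
      res.partial[parent] = std::move(down);
      touched[parent] = true;
    } else {
      res.partial[parent] %= down;
      // rescale only patterns drifting toward underflow
      arma::rowvec m = arma::max(res.partial[parent], 0);
      for (int s = 0; s < npat; ++s) {
        if (m(s) > 0.0 && m(s) < 1e-120) {
          res.partial[parent].col(s) /= m(s);
          res.logscale(s) += std::log(m(s));
        }
      }
    }
  }
  return res;
}

} // namespace

// Per-pattern log-likelihoods by postorder peeling on a rooted tree.
//
// edge:     (nedge x 2) postorder edge list, 1-based node ids (parent, child)
// lengths:  branch lengths matching edge rows
// patterns: (ntip x npat) integer states, 1..K, 0 = missing
// Q:        (K x K) rate matrix (rows sum to 0)
// root_freq: length-K root state distribution
// [[Rcpp::export]]
arma::vec peel_loglik_cpp(const arma::imat& edge,
                          const arma::vec& lengths,
                          const arma::imat& patterns,
                          const arma::mat& Q,
                          const arma::vec& root_freq,
                          const int nnode_total,
                          const int root) {
  QSpectral spec(Q);
  PeelResult res = peel_below_root(edge, lengths, patterns, spec,
                                   nnode_total, root, false);
  const int npat = patterns.n_cols;
  arma::rowvec site_l = root_freq.t() * res.partial[root];
  arma::vec out(npat);
  for (int s = 0; s < npat; ++s) {
    out(s) = (site_l(s) > 0.0 ? std::log(site_l(s)) : -arma::datum::inf)
      + res.logscale(s);
  }
  return out;
}

// Conditional likelihoods of the two root subtrees, root half-branches
// excluded. Moving the root along its branch then only changes the two
// transition matrices applied on top of these partials, so profiling the
// split fraction is cheap (see root_profile_loglik_cpp).
// [[Rcpp::export]]
List root_partials_cpp(const arma::imat& edge,
                       const arma::vec& lengths,
                       const arma::imat& patterns,
                       const arma::mat& Q,
                       const int nnode_total,
                       const int root) {
  QSpectral spec(Q);
  PeelResult res = peel_below_root(edge, lengths, patterns, spec,
                                   nnode_total, root, true);
  arma::uvec kids;
  std::vector<int> ids;
  for (arma::uword e = 0; e < edge.n_rows; ++e)
    if (edge(e, 0) == root) ids.push_back(edge(e, 1));
  return List::create(
    _["child1"] = ids[0],
    _["child2"] = ids[1],
    _["D1"] = res.partial[ids[0]],
    _["D2"] = res.partial[ids[1]],
    _["logscale"] = res.logscale);
}

// Weighted total log-likelihood for a batch of root positions along the
// root branch. t1/t2 give the two half-branch lengths per position.
// [[Rcpp::export]]
arma::vec root_profile_loglik_cpp(const arma::mat& D1,
                                  const arma::mat& D2,
                                  const arma::rowvec& logscale,
                                  const arma::mat& Q,
                                  const arma::vec& root_freq,
                                  const arma::vec& t1,
                                  const arma::vec& t2,
                                  const arma::vec& weights) {
  QSpectral spec(Q);
  const int npat = D1.n_cols;
  arma::vec out(t1.n_elem);
  for (arma::uword i = 0; i < t1.n_elem; ++i) {
    arma::mat up = (spec.P(t1(i)) * D1) % (spec.P(t2(i)) * D2);
    arma::rowvec site_l = root_freq.t() * up;
    double tot = 0.0;
    for (int s = 0; s < npat; ++s) {
      double v = (site_l(s) > 0.0 ? std::log(site_l(s)) : -arma::datum::inf)
        + logscale(s);
      tot += v * weights(s);
    }
    out(i) = tot;
  }
  return out;
}
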