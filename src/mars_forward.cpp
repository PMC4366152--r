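// Forward pass of multivariate adaptive regression splines (MARS):
// greedy addition of reflected-hinge basis pairs, including products with
// one existing term (interaction degree capped at 2). Candidate gains are
// scored by residual-sum-of-squares reduction, computed by Gram-Schmidt
// projection against the orthonormalised current basis. Backward GCV
// pruning is done on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Term {
  int v1, v2;        // 0-based variable indices, -1 if unused
  double k1, k2;     // knots
  int d1, d2;        // +1: h(x - k), -1: h(k - x)
};

static arma::vec hinge(const arma::vec& x, double knot, int dir) {
  arma::vec h = dir > 0 ? arma::vec(x - knot) : arma::vec(knot - x);
  h.elem(arma::find(h < 0)).zeros();
  return h;
}

// [[Rcpp::export(name = ".mars_forward")]]
List mars_forward(const arma::mat& X, const arma::vec& y, int max_terms,
                  int degree, int max_knots) {
  const int n = X.n_rows, p = X.n_cols;

  // candidate knots per variable: unique observed values (quantile-thinned
  // when a variable has many distinct values)
  std::vector<arma::vec> knots(p);
  for (int j = 0; j < p; ++j) {
    arma::vec u = arma::unique(X.col(j));
    if ((int)u.n_elem > max_knots) {
      arma::vec qs = arma::linspace(0.0, 1.0, max_knots);
      u = arma::quantile(X.col(j), qs);
      u = arma::unique(u);
    }
    knots[j] = u;
  }

  std::vector<Term> terms;
  terms.push_back({-1, -1, 0.0, 0.0, 0, 0}); // intercept
  std::vector<int> events; events.push_back(0); // forward event per term
  int event_id = 0;

  arma::mat B(n, 1, arma::fill::ones);          // basis values
  arma::mat Q(n, 1);                            // orthonormal basis
  Q.col(0).fill(1.0 / std::sqrt((double)n));
  arma::vec r = y - Q.col(0) * arma::dot(Q.col(0), y);
  const double yss = arma::dot(r, r);
  std::vector<double> rss_trace;
  rss_trace.push_back(arma::dot(r, r));
  const double tol = 1e-10;

  while ((int)terms.size() + 2 <= max_terms) {
    int M = terms.size();
    if (M + 1 >= n) break; // guard: effective parameters must stay below n

    double best_gain = 0.0;
    int best_parent = -1, best_v = -1;
    double best_knot = 0.0;
    arma::vec bq1, bq2;
    bool best_has1 = false, best_has2 = false;

    for (int m = 0; m < M; ++m) {
      const Term& tm = terms[m];
      int pdeg = (tm.v1 >= 0) + (tm.v2 >= 0);
      if (pdeg >= degree) continue;
      for (int v = 0; v < p; ++v) {
        if (v == tm.v1 || v == tm.v2) continue;
        const arma::vec xv = X.col(v);
        for (arma::uword ki = 0; ki < knots[v].n_elem; ++ki) {
          double t = knots[v](ki);
          double gain = 0.0;
          arma::vec q1, q2;
          bool has1 = false, has2 = false;

          arma::vec c1 = B.col(m) % hinge(xv, t, +1);
          arma::vec u1 = c1 - Q * (Q.t() * c1);
          double nn1 = arma::dot(u1, u1);
          if (nn1 > tol * std::max(1.0, arma::dot(c1, c1))) {
            q1 = u1 / std::sqrt(nn1);
            double pr = arma::dot(q1, r);
            gain += pr * pr;
            has1 = true;
          }
          arma::vec c2 = B.col(m) % hinge(xv, t, -1);
          arma::vec u2 = c2 - Q * (Q.t() * c2);
          if (has1) u2 -= q1 * arma::dot(q1, c2);
          double nn2 = arma::dot(u2, u2);
          if (nn2 > tol * std::max(1.0, arma::dot(c2, c2))) {
            q2 = u2 / std::sqrt(nn2);
            double pr = arma::dot(q2, r);
            gain += pr * pr;
            has2 = true;
          }
          if ((has1 || has2) && gain > best_gain) {
            best_gain = gain;
            best_parent = m; best_v = v; best_knot = t;
            bq1 = q1; bq2 = q2; best_has1 = has1; best_has2 = has2;
          }
        }
      }
    }

    if (best_parent < 0 || best_gain <= 1e-10 * std::max(yss, 1e-300)) break;

    ++event_id;
    const Term par = terms[best_parent]; // copy: push_back may reallocate
    if (best_has1) {
      Term t1 = par;
      if (t1.v1 < 0) { t1.v1 = best_v; t1.k1 = best_knot; t1.d1 = +1; }
      else           { t1.v2 = best_v; t1.k2 = best_knot; t1.d2 = +1; }
      terms.push_back(t1); events.push_back(event_id);
      B.insert_cols(B.n_cols, B.col(best_parent) % hinge(X.col(best_v), best_knot, +1));
      Q.insert_cols(Q.n_cols, bq1);
      r -= bq1 * arma::dot(bq1, r);
    }
    if (best_has2) {
      Term t2 = par;
      if (t2.v1 < 0) { t2.v1 = best_v; t2.k1 = best_knot; t2.d1 = -1; }
      else           { t2.v2 = best_v; t2.k2 = best_knot; t2.d2 = -1; }
      terms.push_back(t2); events.push_back(event_id);
      B.insert_cols(B.n_cols, B.col(best_parent) % hinge(X.col(best_v), best_knot, -1));
      Q.insert_cols(Q.n_cols, bq2);
      r -= bq2 * arma::dot(bq2, r);
    }
    rss_trace.push_back(arma::dot(r, r));
  }

  int M = terms.size();
  IntegerVector v1(M), v2(M), d1(M), d2(M);
  NumericVector k1(M), k2(M);
  for (int m = 0; m < M; ++m) {
    v1[m] = terms[m].v1 + 1; v2[m] = terms[m].v2 + 1; // 1-based for R, 0 = none
    k1[m] = terms[m].k1; k2[m] = terms[m].k2;
    d1[m] = terms[m].d1; d2[m] = terms[m].d2;
  }
  return List::create(
    Named("B") = B,
    Named("v1") = v1, Named("k1") = k1, Named("d1") = d1,
    Named("v2") = v2, Named("k2") = k2, Named("d2") = d2,
    Named("event") = events,
    Named("rss_trace") = rss_trace);
}
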