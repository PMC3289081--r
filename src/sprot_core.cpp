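// Compiled kernels: Kabsch superposition, all-pairs SM-raw, global
// Needleman-Wunsch with a linear gap model, and the TM-score superposition
// search. These mirror the R reference implementations exactly (same tie
// rules) and exist only for speed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Optimal proper rotation/translation mapping Y onto X (row-vector coords).
static void kabsch_rt(const arma::mat& X, const arma::mat& Y,
                      arma::mat& R, arma::vec& t) {
  arma::rowvec cx = arma::mean(X, 0), cy = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - cx, Yc = Y.each_row() - cy;
  arma::mat H = Yc.t() * Xc;
  if (arma::accu(H % H) < 1e-18) {
    R.eye(3, 3);
  } else {
    arma::mat U, V;
    arma::vec s;
    arma::svd(U, s, V, H);
    double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
    arma::mat D = arma::eye(3, 3);
    D(2, 2) = d;
    R = V * D * U.t();
  }
  t = cx.t() - R * cy.t();
}

static inline double dscore(double d, double ds) {
  double r = d / ds;
  return 1.0 / (1.0 + r * r);
}

// maximum-weight order-preserving matching (global NW, zero gap cost);
// returns the optimal total score only
static double nw0_score(const arma::mat& S) {
  int n = S.n_rows, m = S.n_cols;
  if (n == 0 || m == 0) return 0.0;
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double best = prev[j - 1] + S(i - 1, j - 1);
      if (prev[j] > best) best = prev[j];
      if (cur[j - 1] > best) best = cur[j - 1];
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

static arma::mat as_coords(SEXP m) {
  NumericMatrix nm(m);
  arma::mat out(nm.begin(), nm.nrow(), nm.ncol(), true);
  return out;
}

struct PackedSphere {
  arma::rowvec center;
  arma::mat ub, db, un, dn;
};

static std::vector<PackedSphere> unpack(List spheres) {
  std::vector<PackedSphere> out(spheres.size());
  for (int i = 0; i < spheres.size(); ++i) {
    List s = spheres[i];
    NumericVector c = s["center"];
    out[i].center = arma::rowvec({c[0], c[1], c[2]});
    out[i].ub = as_coords(s["ub"]);
    out[i].db = as_coords(s["db"]);
    out[i].un = as_coords(s["un"]);
    out[i].dn = as_coords(s["dn"]);
  }
  return out;
}

// SM-raw for one sphere pair
static double sm_raw_pair(const PackedSphere& x, const PackedSphere& y,
                          double ds) {
  int n_ub = std::min(x.ub.n_rows, y.ub.n_rows);
  int n_db = std::min(x.db.n_rows, y.db.n_rows);
  int n_seed = 1 + n_ub + n_db;
  arma::mat X(n_seed, 3), Y(n_seed, 3);
  // upstream backbones aligned outward from the centre = suffix rows
  for (int k = 0; k < n_ub; ++k) {
    X.row(k) = x.ub.row(x.ub.n_rows - n_ub + k);
    Y.row(k) = y.ub.row(y.ub.n_rows - n_ub + k);
  }
  X.row(n_ub) = x.center;
  Y.row(n_ub) = y.center;
  for (int k = 0; k < n_db; ++k) {
    X.row(n_ub + 1 + k) = x.db.row(k);
    Y.row(n_ub + 1 + k) = y.db.row(k);
  }
  arma::mat R;
  arma::vec t;
  kabsch_rt(X, Y, R, t);
  arma::mat Yt = Y * R.t();
  Yt.each_row() += t.t();
  double total = 0.0;
  for (int k = 0; k < n_seed; ++k)
    total += dscore(arma::norm(X.row(k) - Yt.row(k)), ds);
  // neighbourhoods: zero-gap NW on post-superposition CA distances
  for (int side = 0; side < 2; ++side) {
    const arma::mat& cx = side == 0 ? x.un : x.dn;
    const arma::mat& cy = side == 0 ? y.un : y.dn;
    if (cx.n_rows == 0 || cy.n_rows == 0) continue;
    arma::mat cyt = cy * R.t();
    cyt.each_row() += t.t();
    arma::mat S(cx.n_rows, cyt.n_rows);
    for (arma::uword i = 0; i < cx.n_rows; ++i)
      for (arma::uword j = 0; j < cyt.n_rows; ++j)
        S(i, j) = dscore(arma::norm(cx.row(i) - cyt.row(j)), ds);
    total += nw0_score(S);
  }
  int max_norm = 1 + n_ub + n_db +
    std::min(x.un.n_rows, y.un.n_rows) + std::min(x.dn.n_rows, y.dn.n_rows);
  return total / max_norm;
}

// [[Rcpp::export]]
NumericMatrix sm_raw_matrix_cpp(List spheres_x, List spheres_y, double d_s) {
  std::vector<PackedSphere> px = unpack(spheres_x), py = unpack(spheres_y);
  NumericMatrix out(px.size(), py.size());
  for (size_t i = 0; i < px.size(); ++i)
    for (size_t j = 0; j < py.size(); ++j)
      out(i, j) = sm_raw_pair(px[i], py[j], d_s);
  return out;
}

// Global alignment maximizing sum(match) + gap * (#gap positions).
// Traceback preference: match, then gap in the row sequence (advance the
// column), then gap in the column sequence. -Inf entries forbid a match.
// [[Rcpp::export]]
IntegerMatrix nw_cpp(NumericMatrix S, double gap) {
  int n = S.nrow(), m = S.ncol();
  if (n == 0 || m == 0) stop("empty score matrix");
  arma::mat M(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) M(0, j) = gap * j;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = gap * i;
    for (int j = 1; j <= m; ++j) {
      double s = S(i - 1, j - 1);
      double best = std::isfinite(s) ? M(i - 1, j - 1) + s : R_NegInf;
      best = std::max(best, M(i, j - 1) + gap);
      best = std::max(best, M(i - 1, j) + gap);
      M(i, j) = best;
    }
  }
  std::vector<int> xi, yi;
  int i = n, j = m;
  while (i > 0 && j > 0) {
    double here = M(i, j), s = S(i - 1, j - 1);
    if (std::isfinite(s) && here == M(i - 1, j - 1) + s) {
      xi.push_back(i);
      yi.push_back(j);
      --i; --j;
    } else if (here == M(i, j - 1) + gap) {
      --j;
    } else {
      --i;
    }
  }
  int np = xi.size();
  IntegerMatrix out(np, 2);
  for (int k = 0; k < np; ++k) {
    out(np - 1 - k, 0) = xi[k];
    out(np - 1 - k, 1) = yi[k];
  }
  return out;
}

// TM-score superposition search over a fixed residue pairing.
// Seeds: all windows of the aligned pairs at lengths LA, LA/2, LA/4
// (minimum 4); each seed superposition is refined by repeating
// {keep pairs closer than a cutoff, re-superpose} to a fixed point, for
// cutoffs d0, d0+1, ..., 8 Angstrom. The score
// (1/LT) * sum_i 1/(1 + (d_i/d0)^2) is evaluated over ALL pairs at every
// visited superposition and the best one is returned.
// [[Rcpp::export]]
List tmscore_cpp(IntegerMatrix pairs, NumericMatrix ca_q, NumericMatrix ca_t,
                 int L_T, double d0_min) {
  int LA = pairs.nrow();
  if (LA == 0) stop("empty pairing");
  double d0 = 1.24 * std::cbrt((double)(L_T - 15)) - 1.8;
  if (L_T < 15) d0 = d0_min;  // cbrt of a negative would go complex in spirit
  if (d0 < d0_min) d0 = d0_min;
  arma::mat Q(LA, 3), T(LA, 3);
  for (int k = 0; k < LA; ++k) {
    int qi = pairs(k, 0) - 1, ti = pairs(k, 1) - 1;
    Q(k, 0) = ca_q(qi, 0); Q(k, 1) = ca_q(qi, 1); Q(k, 2) = ca_q(qi, 2);
    T(k, 0) = ca_t(ti, 0); T(k, 1) = ca_t(ti, 1); T(k, 2) = ca_t(ti, 2);
  }
  std::vector<int> lens;
  lens.push_back(LA);
  if (std::max(LA / 2, 4) < LA) lens.push_back(std::max(LA / 2, 4));
  if (std::max(LA / 4, 4) < LA &&
      std::max(LA / 4, 4) != std::max(LA / 2, 4))
    lens.push_back(std::max(LA / 4, 4));

  double best_score = -1.0;
  arma::mat bestR = arma::eye(3, 3);
  arma::vec bestT = arma::zeros(3);
  arma::vec bestD(LA);

  std::vector<double> cutoffs;
  for (double c = d0; c <= 8.0 + 1e-9; c += 1.0) cutoffs.push_back(c);
  if (cutoffs.empty()) cutoffs.push_back(d0);

  arma::mat R;
  arma::vec t;
  arma::vec d(LA);
  auto evaluate = [&](const std::vector<int>& sel) {
    arma::mat Qs(sel.size(), 3), Ts(sel.size(), 3);
    for (size_t k = 0; k < sel.size(); ++k) {
      Qs.row(k) = Q.row(sel[k]);
      Ts.row(k) = T.row(sel[k]);
    }
    kabsch_rt(Ts, Qs, R, t);  // map query onto target
    arma::mat Qt = Q * R.t();
    Qt.each_row() += t.t();
    double sc = 0.0;
    for (int k = 0; k < LA; ++k) {
      d(k) = arma::norm(Qt.row(k) - T.row(k));
      sc += dscore(d(k), d0);
    }
    sc /= L_T;
    if (sc > best_score) {
      best_score = sc;
      bestR = R;
      bestT = t;
      bestD = d;
    }
    return sc;
  };

  for (int len : lens) {
    for (int start = 0; start + len <= LA; ++start) {
      std::vector<int> seed(len);
      for (int k = 0; k < len; ++k) seed[k] = start + k;
      for (double cutoff : cutoffs) {
        std::vector<int> cur = seed;
        for (int iter = 0; iter < 30; ++iter) {
          evaluate(cur);
          std::vector<int> next;
          for (int k = 0; k < LA; ++k)
            if (d(k) < cutoff) next.push_back(k);
          if (next.empty() || next == cur) break;
          cur = next;
        }
      }
    }
  }
  return List::create(_["score"] = best_score,
                      _["rotation"] = bestR,
                      _["translation"] = bestT,
                      _["d"] = bestD);
}
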