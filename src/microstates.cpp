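// Hot loops of the microstate analysis: the modified k-means restarts and
// the channel-shuffling null of the topographic consistency test. All
// randomness comes from R's RNG (callers set.seed), so results are
// reproducible from R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// column-centered maps, their norms and unit versions
static void center_maps(const arma::mat& X, arma::mat& Xc, arma::rowvec& nrm,
                        arma::mat& U) {
  Xc = X.each_row() - arma::mean(X, 0);
  nrm = arma::sqrt(arma::sum(arma::square(Xc), 0));
  U = Xc;
  for (arma::uword t = 0; t < U.n_cols; ++t) {
    if (nrm(t) > 0) U.col(t) /= nrm(t);
  }
}

static arma::vec unit_center(arma::vec v) {
  v -= arma::mean(v);
  double n = arma::norm(v);
  if (n > 0) v /= n;
  return v;
}

// GEV of a (templates, labels) configuration on unit maps U with weights w
static double config_gev(const arma::mat& Tm, const arma::uvec& lab,
                         const arma::mat& U, const arma::rowvec& w, double W) {
  double s = 0.0;
  for (arma::uword t = 0; t < U.n_cols; ++t) {
    double r = arma::dot(Tm.col(lab(t)), U.col(t));
    s += w(t) * r * r;
  }
  return s / W;
}

// Modified k-means microstate segmentation.
// X: channels x timepoints maps (raw). Restarts are seeded either from
// timepoints (seed_idx: restarts x K, 0-based column indices) or from full
// labelings (seed_labels: restarts x T, 0-based classes; pass a 0-row matrix
// for the unused one). Labeling maximizes the signed spatial correlation
// (ignore_polarity = false) or its absolute value; ties go to the lowest
// class index. After every template update the matched configuration
// (updated templates with the labels that produced them) is scored, and the
// highest-GEV configuration across all restarts and iterations is retained.
// [[Rcpp::export]]
List cpp_modkmeans(const arma::mat& X, int K, const arma::imat& seed_idx,
                   const arma::imat& seed_labels, int max_iter,
                   bool ignore_polarity) {
  const arma::uword T = X.n_cols, C = X.n_rows;
  arma::mat Xc, U;
  arma::rowvec nrm;
  center_maps(X, Xc, nrm, U);
  arma::rowvec w = arma::square(nrm);   // proportional to GFP^2
  double W = arma::accu(w);
  if (W <= 0) stop("all maps are flat; cannot segment");

  const bool label_seeded = seed_labels.n_rows > 0;
  const int restarts = label_seeded ? seed_labels.n_rows : seed_idx.n_rows;

  double best_gev = -1.0;
  arma::mat best_T(C, K, arma::fill::zeros);
  arma::uvec best_lab(T, arma::fill::zeros);
  arma::vec restart_gev(restarts);
  arma::ivec restart_iter(restarts);

  for (int rs = 0; rs < restarts; ++rs) {
    arma::mat Tm(C, K, arma::fill::zeros);
    arma::uvec lab(T, arma::fill::zeros);
    bool tm_valid = false;
    if (label_seeded) {
      for (arma::uword t = 0; t < T; ++t) lab(t) = (arma::uword)seed_labels(rs, t);
    } else {
      for (int k = 0; k < K; ++k) Tm.col(k) = U.col((arma::uword)seed_idx(rs, k));
      tm_valid = true;
    }
    arma::uvec prev = lab + (arma::uword)(T + 1); // cannot match initially
    double rs_best = -1.0;
    int it;
    bool converged = false;
    for (it = 0; it < max_iter && !converged; ++it) {
      if (tm_valid) {
        arma::mat R = Tm.t() * U;            // K x T correlations
        for (arma::uword t = 0; t < T; ++t) {
          arma::uword amax = 0;
          double vmax = -2.0;
          for (int k = 0; k < K; ++k) {
            double v = ignore_polarity ? std::fabs(R(k, t)) : R(k, t);
            if (v > vmax + 1e-15) { vmax = v; amax = k; }
          }
          lab(t) = amax;
        }
        if (arma::all(lab == prev)) { converged = true; break; }
        prev = lab;
      }
      // update step: template = normalized (sign-aligned) mean of members
      arma::mat R0;
      if (ignore_polarity && tm_valid) R0 = Tm.t() * U;
      arma::mat Tnew(C, K);
      for (int k = 0; k < K; ++k) {
        arma::vec m(C, arma::fill::zeros);
        int cnt = 0;
        for (arma::uword t = 0; t < T; ++t) {
          if ((int)lab(t) == k) {
            if (R0.n_rows > 0 && R0(k, t) < 0) m -= Xc.col(t); else m += Xc.col(t);
            ++cnt;
          }
        }
        if (cnt == 0 || arma::norm(m) == 0) {
          // empty class: reseed from the worst-fit datapoint
          arma::uword worst = 0;
          if (tm_valid) {
            arma::mat R1 = Tm.t() * U;
            double wv = 2.0;
            for (arma::uword t = 0; t < T; ++t) {
              double r = R1(lab(t), t);
              if (r * r < wv) { wv = r * r; worst = t; }
            }
          } else {
            worst = arma::index_max(w);  // no templates yet: strongest map
          }
          Tnew.col(k) = U.col(worst);
        } else {
          Tnew.col(k) = unit_center(m);
        }
      }
      Tm = Tnew;
      tm_valid = true;
      double g = config_gev(Tm, lab, U, w, W);
      if (g > rs_best) rs_best = g;
      if (g > best_gev) { best_gev = g; best_T = Tm; best_lab = lab; }
    }
    restart_gev(rs) = rs_best;
    restart_iter(rs) = it;
  }

  return List::create(_["templates"] = best_T,
                      _["labels"] = IntegerVector(best_lab.begin(), best_lab.end()),
                      _["gev"] = best_gev,
                      _["restart_gev"] = NumericVector(restart_gev.begin(), restart_gev.end()),
                      _["restart_iter"] = IntegerVector(restart_iter.begin(), restart_iter.end()));
}

// Spatial correlations of each column map of X with each template (K x T).
// [[Rcpp::export]]
arma::mat cpp_spatial_corr(const arma::mat& templates, const arma::mat& X) {
  arma::mat Xc, U;
  arma::rowvec nrm;
  center_maps(X, Xc, nrm, U);
  return templates.t() * U;
}

// Topographic consistency test null distribution. mats: list of subject
// channels x timepoints matrices (same dims). Observed statistic: GFP of
// the across-subject mean map per timepoint. Null: independently permute
// each subject's channel order, re-average, recompute GFP; n_perm times.
// [[Rcpp::export]]
List cpp_tct(const List& mats, int n_perm) {
  int S = mats.size();
  arma::mat first = as<arma::mat>(mats[0]);
  const arma::uword C = first.n_rows, T = first.n_cols;
  std::vector<arma::mat> X(S);
  for (int s = 0; s < S; ++s) {
    X[s] = as<arma::mat>(mats[s]);
    if (X[s].n_rows != C || X[s].n_cols != T) stop("subject matrices differ in size");
  }
  arma::mat msum(C, T, arma::fill::zeros);
  for (int s = 0; s < S; ++s) msum += X[s];
  msum /= S;
  arma::mat cen = msum.each_row() - arma::mean(msum, 0);
  arma::rowvec obs = arma::sqrt(arma::mean(arma::square(cen), 0));

  RNGScope scope;
  arma::rowvec ge_count(T, arma::fill::zeros);
  arma::rowvec nmean(T, arma::fill::zeros), nsq(T, arma::fill::zeros);
  std::vector<arma::uword> perm(C);
  arma::mat acc(C, T);
  for (int p = 0; p < n_perm; ++p) {
    acc.zeros();
    for (int s = 0; s < S; ++s) {
      // Fisher-Yates using R's RNG
      for (arma::uword i = 0; i < C; ++i) perm[i] = i;
      for (arma::uword i = C - 1; i > 0; --i) {
        arma::uword j = (arma::uword)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      for (arma::uword i = 0; i < C; ++i) acc.row(i) += X[s].row(perm[i]);
    }
    acc /= S;
    arma::mat ac = acc.each_row() - arma::mean(acc, 0);
    arma::rowvec g = arma::sqrt(arma::mean(arma::square(ac), 0));
    ge_count += arma::conv_to<arma::rowvec>::from(g >= obs);
    nmean += g;
    nsq += arma::square(g);
  }
  arma::rowvec pval = (ge_count + 1.0) / (n_perm + 1.0);
  nmean /= n_perm;
  arma::rowvec nsd = arma::sqrt(arma::clamp(nsq / n_perm - arma::square(nmean),
                                            0.0, arma::datum::inf));
  return List::create(_["observed"] = NumericVector(obs.begin(), obs.end()),
                      _["p"] = NumericVector(pval.begin(), pval.end()),
                      _["null_mean"] = NumericVector(nmean.begin(), nmean.end()),
                      _["null_sd"] = NumericVector(nsd.begin(), nsd.end()));
}
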