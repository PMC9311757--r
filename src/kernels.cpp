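#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Area of the union of disks in the plane.
// Slices the bounding interval in x; within each slice the union of the
// y-chords cut by the disks is merged exactly, so the only error is the
// midpoint-rule quadrature in x (O(h^2) away from tangencies).
// [[Rcpp::export(name = ".disk_union_area")]]
double disk_union_area(NumericVector px, NumericVector py, NumericVector r,
                       int n_slices = 4096) {
  int n = px.size();
  if (n == 0) return 0.0;
  double xmin = R_PosInf, xmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, px[i] - r[i]);
    xmax = std::max(xmax, px[i] + r[i]);
  }
  if (!(xmax > xmin)) return 0.0;
  double h = (xmax - xmin) / n_slices;
  double area = 0.0;
  std::vector<std::pair<double, double> > iv;
  iv.reserve(n);
  for (int s = 0; s < n_slices; ++s) {
    double x = xmin + (s + 0.5) * h;
    iv.clear();
    for (int i = 0; i < n; ++i) {
      double dx = x - px[i];
      double d2 = r[i] * r[i] - dx * dx;
      if (d2 > 0.0) {
        double half = std::sqrt(d2);
        iv.push_back(std::make_pair(py[i] - half, py[i] + half));
      }
    }
    if (iv.empty()) continue;
    std::sort(iv.begin(), iv.end());
    double len = 0.0, lo = iv[0].first, hi = iv[0].second;
    for (size_t k = 1; k < iv.size(); ++k) {
      if (iv[k].first > hi) {
        len += hi - lo;
        lo = iv[k].first;
        hi = iv[k].second;
      } else if (iv[k].second > hi) {
        hi = iv[k].second;
      }
    }
    len += hi - lo;
    area += len * h;
  }
  return area;
}

// Free area inside a circular outer boundary of radius rbox (centred at the
// origin) not covered by any of the (probe-expanded) disks.  Same slicing
// scheme; the blocked chords are clipped to the box chord.
// [[Rcpp::export(name = ".free_area_in_circle")]]
double free_area_in_circle(NumericVector px, NumericVector py, NumericVector r,
                           double rbox, int n_slices = 4096) {
  int n = px.size();
  double h = 2.0 * rbox / n_slices;
  double area = 0.0;
  std::vector<std::pair<double, double> > iv;
  iv.reserve(n + 1);
  for (int s = 0; s < n_slices; ++s) {
    double x = -rbox + (s + 0.5) * h;
    double b2 = rbox * rbox - x * x;
    if (b2 <= 0.0) continue;
    double bhalf = std::sqrt(b2);
    double blo = -bhalf, bhi = bhalf;
    iv.clear();
    for (int i = 0; i < n; ++i) {
      double dx = x - px[i];
      double d2 = r[i] * r[i] - dx * dx;
      if (d2 > 0.0) {
        double half = std::sqrt(d2);
        double lo = std::max(py[i] - half, blo);
        double hi = std::min(py[i] + half, bhi);
        if (hi > lo) iv.push_back(std::make_pair(lo, hi));
      }
    }
    double blocked = 0.0;
    if (!iv.empty()) {
      std::sort(iv.begin(), iv.end());
      double lo = iv[0].first, hi = iv[0].second;
      for (size_t k = 1; k < iv.size(); ++k) {
        if (iv[k].first > hi) {
          blocked += hi - lo;
          lo = iv[k].first;
          hi = iv[k].second;
        } else if (iv[k].second > hi) {
          hi = iv[k].second;
        }
      }
      blocked += hi - lo;
    }
    area += (2.0 * bhalf - blocked) * h;
  }
  return area;
}

// Continuous-time Markov chain on a 1D birth-death lattice with absorbing
// boundaries beyond both ends.  States are 0..n-1; a left jump from state 0
// absorbs on the cis side, a right jump from state n-1 on the trans side.
// Uses R's RNG so set.seed() controls reproducibility.
// [[Rcpp::export(name = ".ctmc_escape")]]
List ctmc_escape(NumericVector k_left, NumericVector k_right, int start,
                 int n_traj) {
  int n = k_left.size();
  if (k_right.size() != n) stop("rate vectors differ in length");
  if (start < 0 || start >= n) stop("start state outside the lattice");
  NumericVector times(n_traj);
  IntegerVector side(n_traj);  // 0 = cis (left), 1 = trans (right)
  for (int t = 0; t < n_traj; ++t) {
    int i = start;
    double tau = 0.0;
    for (;;) {
      double kl = k_left[i], kr = k_right[i];
      double ktot = kl + kr;
      tau += R::exp_rand() / ktot;
      if (unif_rand() * ktot < kl) {
        if (--i < 0) { side[t] = 0; break; }
      } else {
        if (++i >= n) { side[t] = 1; break; }
      }
    }
    times[t] = tau;
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["time"] = times, _["side"] = side);
}
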