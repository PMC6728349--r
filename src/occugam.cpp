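#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Polya-Gamma PG(b, c) sampling, Devroye's exact method for PG(1, c).
// Used to make every logistic block of the Gibbs sampler conditionally
// Gaussian.  Uses R's RNG so draws are reproducible under set.seed().
// ---------------------------------------------------------------------------

static const double TRUNC = 0.64;

// log CDF at x of the inverse-Gaussian(mu = 1/z, lambda = 1); valid at z = 0.
static double log_pigauss(double x, double z) {
  double rx = std::sqrt(1.0 / x);
  double lb = R::pnorm(rx * (x * z - 1.0), 0.0, 1.0, 1, 1);
  double la = 2.0 * z + R::pnorm(-rx * (x * z + 1.0), 0.0, 1.0, 1, 1);
  return R::logspace_add(lb, la);
}

// coefficients of the alternating-series representation of the J*(1, z) density
static double a_coef(int n, double x) {
  double np = n + 0.5;
  if (x > TRUNC)
    return M_PI * np * std::exp(-np * np * M_PI * M_PI * x / 2.0);
  return M_PI * np * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * np * np / x);
}

// inverse-Gaussian(1/z, 1) truncated to (0, t]
static double rtigauss(double z, double t) {
  double x;
  if (z < 1.0 / t) {  // mu > t: rejection from truncated inverse-chi^2 form
    while (true) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      if (R::unif_rand() <= std::exp(-0.5 * z * z * x)) return x;
    }
  }
  double mu = 1.0 / z;
  while (true) {  // Michael-Schucany, retry until inside (0, t]
    double y = R::norm_rand();
    y = y * y;
    x = mu + 0.5 * mu * mu * y -
        0.5 * mu * std::sqrt(4.0 * mu * y + mu * mu * y * y);
    if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    if (x <= t) return x;
  }
}

static double rpg1(double c) {
  double z = 0.5 * std::fabs(c);
  double K = M_PI * M_PI * 0.125 + 0.5 * z * z;
  double logp = std::log(M_PI) - std::log(2.0 * K) - K * TRUNC;
  double logq = std::log(2.0) - z + log_pigauss(TRUNC, z);
  double ratio = 1.0 / (1.0 + std::exp(logq - logp));
  while (true) {
    double x;
    if (R::unif_rand() < ratio)
      x = TRUNC + R::exp_rand() / K;
    else
      x = rtigauss(z, TRUNC);
    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    while (true) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break;  // reject this x, redraw
      }
    }
  }
}

//' @noRd
// [[Rcpp::export(name = ".rpg_cpp")]]
NumericVector rpg_cpp(IntegerVector b, NumericVector c) {
  int n = b.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < b[i]; ++j) s += rpg1(c[i]);
    out[i] = s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marginal likelihood of a route-year detection history: z in {0,1} and the
// stop-level availability chain y_1..y_J are summed out by a forward
// recursion with initial probability pi, transitions (theta, theta') and
// emission h_j ~ Bern(y_j * p).
// ---------------------------------------------------------------------------

// P(h | z = 1) by forward recursion; h is a length-J 0/1 array
static double forward_prob(const int* h, int J, double pi, double theta,
                           double thetap, double p) {
  // a0, a1: P(y_j = 0/1, h_1..h_j | z = 1)
  double e1_1 = p, e0_1 = 1.0 - p;  // emission of h=1 / h=0 given y=1
  double a0 = (h[0] == 1) ? 0.0 : (1.0 - pi);
  double a1 = pi * (h[0] == 1 ? e1_1 : e0_1);
  for (int j = 1; j < J; ++j) {
    double b1 = a0 * theta + a1 * thetap;
    double b0 = a0 * (1.0 - theta) + a1 * (1.0 - thetap);
    if (h[j] == 1) {
      a1 = b1 * e1_1;
      a0 = 0.0;
    } else {
      a1 = b1 * e0_1;
      a0 = b0;
    }
  }
  return a0 + a1;
}

//' @noRd
// [[Rcpp::export(name = ".route_marglik_cpp")]]
NumericVector route_marglik_cpp(IntegerMatrix h, NumericVector psi,
                                NumericVector pi, NumericVector theta,
                                NumericVector thetap, NumericVector p) {
  int n = h.nrow(), J = h.ncol();
  NumericVector out(n);
  std::vector<int> row(J);
  for (int i = 0; i < n; ++i) {
    bool any1 = false;
    for (int j = 0; j < J; ++j) {
      row[j] = h(i, j);
      if (row[j] == 1) any1 = true;
    }
    double L1 = forward_prob(row.data(), J, pi[i], theta[i], thetap[i], p[i]);
    double L0 = any1 ? 0.0 : 1.0;
    out[i] = std::log((1.0 - psi[i]) * L0 + psi[i] * L1);
  }
  return out;
}

// Probabilities of all 2^J histories for each route-year, histories in
// lexicographic order (first stop = most significant bit).
//' @noRd
// [[Rcpp::export(name = ".history_probs_cpp")]]
NumericMatrix history_probs_cpp(NumericVector psi, NumericVector pi,
                                NumericVector theta, NumericVector thetap,
                                NumericVector p, int J) {
  int n = psi.size(), H = 1 << J;
  NumericMatrix out(n, H);
  std::vector<int> hist(J);
  for (int idx = 0; idx < H; ++idx) {
    for (int j = 0; j < J; ++j) hist[j] = (idx >> (J - 1 - j)) & 1;
    bool any1 = idx != 0;
    for (int i = 0; i < n; ++i) {
      double L1 =
          forward_prob(hist.data(), J, pi[i], theta[i], thetap[i], p[i]);
      double L0 = any1 ? 0.0 : 1.0;
      out(i, idx) = (1.0 - psi[i]) * L0 + psi[i] * L1;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Forward-filtering backward-sampling draw of (z, y) from their joint full
// conditional given the detection history and current parameters.
// ---------------------------------------------------------------------------

//' @noRd
// [[Rcpp::export(name = ".ffbs_cpp")]]
List ffbs_cpp(IntegerMatrix h, NumericVector psi, NumericVector pi,
              NumericVector theta, NumericVector thetap, NumericVector p) {
  int n = h.nrow(), J = h.ncol();
  IntegerVector z(n);
  IntegerMatrix y(n, J);
  std::vector<double> f0(J), f1(J);  // forward messages
  for (int i = 0; i < n; ++i) {
    double e1_1 = p[i], e0_1 = 1.0 - p[i];
    bool any1 = false;
    for (int j = 0; j < J; ++j)
      if (h(i, j) == 1) any1 = true;
    // forward pass conditional on z = 1
    f0[0] = (h(i, 0) == 1) ? 0.0 : (1.0 - pi[i]);
    f1[0] = pi[i] * (h(i, 0) == 1 ? e1_1 : e0_1);
    for (int j = 1; j < J; ++j) {
      double b1 = f0[j - 1] * theta[i] + f1[j - 1] * thetap[i];
      double b0 = f0[j - 1] * (1.0 - theta[i]) + f1[j - 1] * (1.0 - thetap[i]);
      if (h(i, j) == 1) {
        f1[j] = b1 * e1_1;
        f0[j] = 0.0;
      } else {
        f1[j] = b1 * e0_1;
        f0[j] = b0;
      }
    }
    double L1 = f0[J - 1] + f1[J - 1];
    double L0 = any1 ? 0.0 : 1.0;
    double num = psi[i] * L1, den = num + (1.0 - psi[i]) * L0;
    int zi;
    if (den <= 0.0) {
      zi = 1;  // numerically impossible history: fall back to forced values
      for (int j = 0; j < J; ++j) y(i, j) = h(i, j);
      z[i] = zi;
      continue;
    }
    zi = (R::unif_rand() < num / den) ? 1 : 0;
    z[i] = zi;
    if (zi == 0) {
      for (int j = 0; j < J; ++j) y(i, j) = 0;
      continue;
    }
    // backward sampling of y
    double pr1 = (L1 > 0.0) ? f1[J - 1] / L1 : 0.0;
    y(i, J - 1) = (R::unif_rand() < pr1) ? 1 : 0;
    for (int j = J - 2; j >= 0; --j) {
      double t1 = (y(i, j + 1) == 1) ? thetap[i] : (1.0 - thetap[i]);
      double t0 = (y(i, j + 1) == 1) ? theta[i] : (1.0 - theta[i]);
      double w1 = f1[j] * t1, w0 = f0[j] * t0;
      double tot = w0 + w1;
      y(i, j) = (tot > 0.0 && R::unif_rand() < w1 / tot) ? 1 : 0;
    }
  }
  return List::create(_["z"] = z, _["y"] = y);
}
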