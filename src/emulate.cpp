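#include <Rcpp.h>
#include <cmath>

// Strict IEEE emulation of the angle update rules in single and double
// precision. Every intermediate is stored to its precision; no FMA is
// generated (the loops contain no multiply-add pairs). The float32 golden
// constant is built entirely in single precision, the float64 constant from
// the double evaluation of pi / ((1 + sqrt 5)/2); see the methods vignette
// for why the two constructions differ.

// [[Rcpp::export]]
Rcpp::List golden_constants_cpp() {
  double psi_d = M_PI / ((1.0 + std::sqrt(5.0)) / 2.0);
  float psi_s = ((float)M_PI) * (std::sqrt(5.0f) - 1.0f) / 2.0f;
  double twopi_d = 2.0 * M_PI;
  float twopi_s = (float)(2.0 * M_PI);
  return Rcpp::List::create(
    Rcpp::Named("psi_double") = psi_d,
    Rcpp::Named("psi_single") = (double)psi_s,
    Rcpp::Named("twopi_double") = twopi_d,
    Rcpp::Named("twopi_single") = (double)twopi_s);
}

// [[Rcpp::export]]
Rcpp::NumericVector emulate_product_cpp(Rcpp::NumericVector t,
                                        bool single_prec) {
  // raw rounded product t * psi_1; the exact-remainder reduction by the
  // same-precision two-pi constant is applied on the R side (fmod is exact,
  // so computing it in double arithmetic reproduces fmodf bit-for-bit)
  int n = t.size();
  Rcpp::NumericVector out(n);
  double psi_d = M_PI / ((1.0 + std::sqrt(5.0)) / 2.0);
  float psi_s = ((float)M_PI) * (std::sqrt(5.0f) - 1.0f) / 2.0f;
  for (int k = 0; k < n; ++k) {
    if (single_prec) {
      float phi = (float)t[k] * psi_s;
      out[k] = (double)phi;
    } else {
      out[k] = t[k] * psi_d;
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector emulate_additive_cpp(Rcpp::NumericVector t_out,
                                         bool modular, bool single_prec) {
  // t_out must be sorted ascending; returns phi_t for each requested t
  int n = t_out.size();
  Rcpp::NumericVector out(n);
  long tmax = (long)t_out[n - 1];
  double psi_d = M_PI / ((1.0 + std::sqrt(5.0)) / 2.0);
  float psi_s = ((float)M_PI) * (std::sqrt(5.0f) - 1.0f) / 2.0f;
  float twopi_s = (float)(2.0 * M_PI);
  double twopi_d = 2.0 * M_PI;
  int j = 0;
  if (single_prec) {
    volatile float phi = 0.0f;
    for (long k = 0; k <= tmax; ++k) {
      if (j < n && (long)t_out[j] == k) out[j++] = (double)phi;
      phi = phi + psi_s;
      if (modular && phi >= twopi_s) phi = phi - twopi_s;
    }
  } else {
    volatile double phi = 0.0;
    for (long k = 0; k <= tmax; ++k) {
      if (j < n && (long)t_out[j] == k) out[j++] = phi;
      phi = phi + psi_d;
      if (modular && phi >= twopi_d) phi = phi - twopi_d;
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector emulate_raga_cpp(Rcpp::NumericVector ind, double S_half,
                                     bool single_prec) {
  // angle = ind * (pi / S_half); the base angle constant is rounded once to
  // the working precision, the product once more
  int n = ind.size();
  Rcpp::NumericVector out(n);
  double base_d = M_PI / S_half;
  float base_s = ((float)M_PI) / ((float)S_half);
  for (int k = 0; k < n; ++k) {
    if (single_prec) {
      float phi = (float)ind[k] * base_s;
      out[k] = (double)phi;
    } else {
      double phi = ind[k] * base_d;
      out[k] = phi;
    }
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector float32_round_cpp(Rcpp::NumericVector x) {
  int n = x.size();
  Rcpp::NumericVector out(n);
  for (int k = 0; k < n; ++k) out[k] = (double)(float)x[k];
  return out;
}
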