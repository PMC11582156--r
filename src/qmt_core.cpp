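#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact flow of the affine two-pool longitudinal system dM/dt = A M + b
// over a segment of duration t with piecewise-constant A (2x2) and b.
// The propagator exp(A t) is computed in closed form:
//   exp(A t) = e^{m t} [ cosh(q t) I + sinh(q t)/q (A - m I) ],
// m = tr(A)/2, q^2 = m^2 - det(A).  For the relaxation-exchange matrix
// q^2 = ((a11-a22)/2)^2 + a12*a21 >= 0 (a12, a21 >= 0), so q is real.
struct Flow {
  double e11, e12, e21, e22;  // exp(A t)
  double f1, f2;              // integral term: M(t) = E M(0) + f
};

static inline double sinhc(double x) {
  // sinh(x)/x, stable near zero
  if (std::fabs(x) < 1e-6) return 1.0 + x * x / 6.0;
  return std::sinh(x) / x;
}

static Flow make_flow(double a11, double a12, double a21, double a22,
                      double b1, double b2, double t) {
  double m = 0.5 * (a11 + a22);
  double det = a11 * a22 - a12 * a21;
  double q2 = m * m - det;
  double q = std::sqrt(q2 > 0.0 ? q2 : 0.0);
  double em = std::exp(m * t);
  double ch, shq;  // cosh(q t), sinh(q t)/q * 1
  if (q2 >= 0.0) {
    ch = std::cosh(q * t);
    shq = t * sinhc(q * t);  // sinh(q t)/q
  } else {
    double w = std::sqrt(-q2);
    ch = std::cos(w * t);
    shq = (std::fabs(w * t) < 1e-6) ? t : std::sin(w * t) / w;
  }
  Flow F;
  F.e11 = em * (ch + shq * (a11 - m));
  F.e12 = em * (shq * a12);
  F.e21 = em * (shq * a21);
  F.e22 = em * (ch + shq * (a22 - m));
  // particular solution M_p = -A^{-1} b; f = (I - E) M_p
  double p1 = -( a22 * b1 - a12 * b2) / det;
  double p2 = -(-a21 * b1 + a11 * b2) / det;
  F.f1 = p1 - (F.e11 * p1 + F.e12 * p2);
  F.f2 = p2 - (F.e21 * p1 + F.e22 * p2);
  return F;
}

static inline void apply_flow(const Flow& F, double& m1, double& m2) {
  double n1 = F.e11 * m1 + F.e12 * m2 + F.f1;
  double n2 = F.e21 * m1 + F.e22 * m2 + F.f2;
  m1 = n1; m2 = n2;
}

// One MT cycle: saturation segment (duration tau, rates wa/wb), then
// n_spokes excitation events spaced dts apart (free evolution between),
// then free recovery of t_rec to complete TR.  The readout samples the
// free-pool longitudinal magnetization immediately before each excitation.
//
// Returns the periodic-steady-state signal sin(fa) * <Mza^-> (mean over
// spokes, or first spoke only).
// [[Rcpp::export]]
NumericVector qmt_spectrum_cpp(double r1a, double r1b, double kab, double kba,
                               double m0a, double m0b,
                               NumericVector wa, NumericVector wb,
                               double tau, int n_spokes, double dts,
                               double t_rec, double cos_fa, double sin_fa,
                               bool first_spoke_only) {
  int n = wa.size();
  NumericVector out(n);
  double b1 = r1a * m0a, b2 = r1b * m0b;
  // free-evolution coefficient matrix (no saturation)
  double g11 = -(r1a + kab), g12 = kba, g21 = kab, g22 = -(r1b + kba);
  Flow Fdts = make_flow(g11, g12, g21, g22, b1, b2, dts);
  Flow Frec = make_flow(g11, g12, g21, g22, b1, b2, t_rec);

  for (int i = 0; i < n; ++i) {
    Flow Fsat = make_flow(g11 - wa[i], g12, g21, g22 - wb[i], b1, b2, tau);
    // cycle affine map (P, c), starting at the top of the saturation pulse:
    // propagate columns of the identity plus the zero vector
    double p11 = Fsat.e11, p12 = Fsat.e12, p21 = Fsat.e21, p22 = Fsat.e22;
    double c1 = Fsat.f1, c2 = Fsat.f2;
    for (int k = 0; k < n_spokes; ++k) {
      // excitation scales the free-pool term by cos(fa)
      p11 *= cos_fa; p12 *= cos_fa; c1 *= cos_fa;
      const Flow& F = (k < n_spokes - 1) ? Fdts : Frec;
      double q11 = F.e11 * p11 + F.e12 * p21;
      double q12 = F.e11 * p12 + F.e12 * p22;
      double q21 = F.e21 * p11 + F.e22 * p21;
      double q22 = F.e21 * p12 + F.e22 * p22;
      double d1 = F.e11 * c1 + F.e12 * c2 + F.f1;
      double d2 = F.e21 * c1 + F.e22 * c2 + F.f2;
      p11 = q11; p12 = q12; p21 = q21; p22 = q22; c1 = d1; c2 = d2;
    }
    // steady state: (I - P) M = c
    double det = (1.0 - p11) * (1.0 - p22) - p12 * p21;
    if (std::fabs(det) < 1e-14)
      stop("singular steady-state system (I - P_cycle) for wa=%g, wb=%g",
           wa[i], wb[i]);
    double m1 = ((1.0 - p22) * c1 + p12 * c2) / det;
    double m2 = (p21 * c1 + (1.0 - p11) * c2) / det;
    // readout pass
    apply_flow(Fsat, m1, m2);
    double acc = 0.0;
    for (int k = 0; k < n_spokes; ++k) {
      if (first_spoke_only) {
        if (k == 0) acc = m1;
      } else {
        acc += m1;
      }
      m1 *= cos_fa;
      if (k < n_spokes - 1) apply_flow(Fdts, m1, m2);
    }
    out[i] = sin_fa * (first_spoke_only ? acc : acc / n_spokes);
  }
  return out;
}
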