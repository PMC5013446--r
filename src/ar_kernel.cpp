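#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// d^e with fast paths for the exponents used by the standard presets.
static inline double powfast(double d, double e) {
  if (e == 0.0) return 1.0;
  if (e == 1.0) return d;
  if (e == 2.0) return d * d;
  if (e == 3.0) return d * d * d;
  if (e == -1.0) return 1.0 / d;
  return std::pow(d, e);
}

// Net a-r forces on every node and the total layout energy.
//
// Attraction acts along edges with magnitude att * d^a (toward the
// neighbour); repulsion acts between every distinct pair with magnitude
// rep * s_v * s_w * d^r (away). The energy is the antiderivative of those
// forces: att * d^(a+1)/(a+1) summed over edges minus
// rep * s_v * s_w * d^(r+1)/(r+1) summed over pairs, with the exponent-0
// case replaced by the log limit. Distances are clamped below at dmin so
// coincident points do not produce non-finite forces.
//
// P: n x 2 positions; edges: m x 2 zero-based indices; s: per-node
// repulsion scale (all 1 except the degree-scaled ForceAtlas2 preset).
// [[Rcpp::export]]
List ar_forces_energy(NumericMatrix P, IntegerMatrix edges,
                      double a, double r, double att, double rep,
                      NumericVector s, double dmin) {
  const int n = P.nrow();
  const int m = edges.nrow();
  NumericMatrix F(n, 2);
  double U = 0.0;
  const double a1 = a + 1.0, r1 = r + 1.0;

  // repulsion: all unordered pairs
  const bool inv_linear = (r == -1.0); // all standard presets; avoids sqrt
  const double dmin2 = dmin * dmin;
  for (int v = 0; v < n; ++v) {
    const double xv = P(v, 0), yv = P(v, 1), sv = rep * s[v];
    double fx = 0.0, fy = 0.0;
    for (int w = v + 1; w < n; ++w) {
      const double dx = P(w, 0) - xv, dy = P(w, 1) - yv;
      double d2 = dx * dx + dy * dy;
      if (d2 < dmin2) d2 = dmin2;
      const double c = sv * s[w];
      double gx, gy; // repulsive force on w (equal and opposite on v)
      if (inv_linear) {
        // force magnitude c/d along (dx,dy)/d  ==  c * delta / d^2
        gx = c * dx / d2;
        gy = c * dy / d2;
        U -= 0.5 * c * std::log(d2); // r + 1 == 0 limit
      } else {
        const double d = std::sqrt(d2);
        const double mag = c * powfast(d, r);
        gx = mag * dx / d;
        gy = mag * dy / d;
        U -= (r1 == 0.0) ? c * std::log(d) : c * powfast(d, r1) / r1;
      }
      fx -= gx;
      fy -= gy;
      F(w, 0) += gx;
      F(w, 1) += gy;
    }
    F(v, 0) += fx;
    F(v, 1) += fy;
  }

  // attraction: edges only
  for (int e = 0; e < m; ++e) {
    const int v = edges(e, 0), w = edges(e, 1);
    double dx = P(w, 0) - P(v, 0), dy = P(w, 1) - P(v, 1);
    double d = std::sqrt(dx * dx + dy * dy);
    if (d < dmin) d = dmin;
    const double mag = att * powfast(d, a);
    const double ux = dx / d, uy = dy / d;
    F(v, 0) += mag * ux;
    F(v, 1) += mag * uy;
    F(w, 0) -= mag * ux;
    F(w, 1) -= mag * uy;
    U += (a1 == 0.0) ? att * std::log(d) : att * powfast(d, a1) / a1;
  }

  return List::create(_["forces"] = F, _["energy"] = U);
}
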