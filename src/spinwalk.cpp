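#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Random-walk engine for spins diffusing in a periodic 2D substrate of
// impermeable compartments, accumulating precession phase against a stack of
// field maps (one per fiber-to-field angle) simultaneously along a single
// trajectory pass. Phases are recorded per TR, split at TE, in units of
// radians per tesla, so one trajectory serves any B0 at replay time.
//
// label: nx*ny integer grid (column-major), values 0/1/2
// fields: nx*ny*n_theta relative offsets dB/B0 (dimensionless)
// D_by_label: diffusivity per label, m^2/s
// Returns phase records [n_spins x n_tr x n_theta] for the first (TE) and
// second (TR-TE) segment of every TR, plus start positions, compartments and
// unwrapped net displacements.

static inline int pix(double x, double px_um, int n) {
  int i = (int)std::floor(x / px_um);
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

// [[Rcpp::export]]
List walk_spins_cpp(IntegerVector label, int nx, int ny, double px_um,
                    NumericVector fields, int n_theta,
                    NumericVector D_by_label, double dt, double TR, double TE,
                    int n_tr, int n_spins, double gamma_bar) {
  const double L = nx * px_um;
  const int steps_te = (int)std::lround(TE / dt);
  const int steps_tr = (int)std::lround(TR / dt);
  if (std::fabs(steps_tr * dt - TR) > 1e-12 || std::fabs(steps_te * dt - TE) > 1e-12)
    stop("dt must divide both TE and TR");
  const double two_pi_gb_dt = 2.0 * M_PI * gamma_bar * dt;

  NumericVector ph1(
      (R_xlen_t)n_spins * n_tr * n_theta);  // [spin, tr, theta]
  NumericVector ph2((R_xlen_t)n_spins * n_tr * n_theta);
  IntegerVector comp(n_spins);
  NumericVector x0(n_spins), y0(n_spins), dx_net(n_spins), dy_net(n_spins);

  std::vector<double> acc(n_theta);

  for (int s = 0; s < n_spins; ++s) {
    double x = unif_rand() * L;
    double y = unif_rand() * L;
    int lab = label[pix(x, px_um, nx) + nx * pix(y, px_um, ny)];
    comp[s] = lab;
    x0[s] = x; y0[s] = y;
    double ux = 0.0, uy = 0.0;  // unwrapped displacement
    const double sd_um = std::sqrt(2.0 * D_by_label[lab] * dt) * 1e6;

    for (int tr = 0; tr < n_tr; ++tr) {
      for (int seg = 0; seg < 2; ++seg) {
        const int nstep = (seg == 0) ? steps_te : (steps_tr - steps_te);
        for (int t = 0; t < n_theta; ++t) acc[t] = 0.0;
        for (int st = 0; st < nstep; ++st) {
          if (sd_um > 0.0) {
            // rejection-resample steps that would cross a compartment boundary
            for (int attempt = 0; attempt < 1000; ++attempt) {
              const double sx = norm_rand() * sd_um;
              const double sy = norm_rand() * sd_um;
              double xn = x + sx, yn = y + sy;
              xn -= L * std::floor(xn / L);
              yn -= L * std::floor(yn / L);
              const int ln = label[pix(xn, px_um, nx) + nx * pix(yn, px_um, ny)];
              if (ln == lab) {
                x = xn; y = yn; ux += sx; uy += sy;
                break;
              }
            }
          }
          const R_xlen_t p = pix(x, px_um, nx) + (R_xlen_t)nx * pix(y, px_um, ny);
          for (int t = 0; t < n_theta; ++t)
            acc[t] += fields[p + (R_xlen_t)nx * ny * t];
        }
        NumericVector& tgt = (seg == 0) ? ph1 : ph2;
        for (int t = 0; t < n_theta; ++t)
          tgt[s + (R_xlen_t)n_spins * (tr + (R_xlen_t)n_tr * t)] =
              acc[t] * two_pi_gb_dt;
      }
    }
    dx_net[s] = ux; dy_net[s] = uy;
  }

  ph1.attr("dim") = IntegerVector::create(n_spins, n_tr, n_theta);
  ph2.attr("dim") = IntegerVector::create(n_spins, n_tr, n_theta);
  return List::create(_["phase_te"] = ph1, _["phase_rest"] = ph2,
                      _["compartment"] = comp, _["x0"] = x0, _["y0"] = y0,
                      _["dx_net"] = dx_net, _["dy_net"] = dy_net);
}

// Replay the pc-bSSFP sequence over recorded phase histories for one
// fiber-to-field angle. Magnetization is tracked per spin in the frame
// demodulated by the current RF pulse phase: each TR applies an instantaneous
// rotation by `alpha` about x, relaxation/precession over the TE segment
// (recorded phase scaled by B0), a readout after n_dummy TRs, then the
// remaining segment including the frame shift -phi_j. Returns complex
// per-compartment sums (PD-weighted) for each phase cycle.
//
// phase_te/phase_rest: [n_spins x n_tr] slices for this theta (radians/T)

// [[Rcpp::export]]
ComplexMatrix replay_bssfp_cpp(NumericMatrix phase_te, NumericMatrix phase_rest,
                               IntegerVector comp, NumericVector T1_by_label,
                               NumericVector T2_by_label,
                               NumericVector pd_by_label, NumericVector phis,
                               double TR, double TE, double alpha_rad,
                               double B0, int n_dummy) {
  const int n_spins = phase_te.nrow();
  const int n_tr = phase_te.ncol();
  const int n_phi = phis.size();
  const int n_lab = T1_by_label.size();
  if (n_tr < n_dummy + 1) stop("phase records must cover n_dummy + 1 TRs");

  const double ca = std::cos(alpha_rad), sa = std::sin(alpha_rad);
  std::vector<double> E1a(n_lab), E2a(n_lab), E1b(n_lab), E2b(n_lab);
  for (int l = 0; l < n_lab; ++l) {
    E1a[l] = std::exp(-TE / T1_by_label[l]);
    E2a[l] = std::exp(-TE / T2_by_label[l]);
    E1b[l] = std::exp(-(TR - TE) / T1_by_label[l]);
    E2b[l] = std::exp(-(TR - TE) / T2_by_label[l]);
  }

  ComplexMatrix out(n_phi, n_lab);  // PD-weighted compartment sums at TE
  std::vector<double> re(n_phi * n_lab, 0.0), im(n_phi * n_lab, 0.0);

  for (int s = 0; s < n_spins; ++s) {
    const int lab = comp[s];
    const double pd = pd_by_label[lab];
    for (int j = 0; j < n_phi; ++j) {
      const double phi = phis[j];
      double mx = 0.0, my = 0.0, mz = 1.0;
      for (int tr = 0; tr <= n_dummy; ++tr) {
        // RF rotation about x
        double my2 = ca * my - sa * mz;
        double mz2 = sa * my + ca * mz;
        my = my2; mz = mz2;
        // TE segment: relax, precess by recorded phase * B0
        double b1 = phase_te(s, tr) * B0;
        double c1 = std::cos(b1), s1 = std::sin(b1);
        double mx1 = E2a[lab] * (c1 * mx - s1 * my);
        double my1 = E2a[lab] * (s1 * mx + c1 * my);
        mx = mx1; my = my1;
        mz = E1a[lab] * mz + (1.0 - E1a[lab]);
        if (tr == n_dummy) break;  // readout at TE of the final TR
        // remaining segment: recorded phase * B0 minus the RF frame shift
        double b2 = phase_rest(s, tr) * B0 - phi;
        double c2 = std::cos(b2), s2 = std::sin(b2);
        double mx2 = E2b[lab] * (c2 * mx - s2 * my);
        double my2b = E2b[lab] * (s2 * mx + c2 * my);
        mx = mx2; my = my2b;
        mz = E1b[lab] * mz + (1.0 - E1b[lab]);
      }
      re[j + n_phi * lab] += pd * mx;
      im[j + n_phi * lab] += pd * my;
    }
  }
  for (int l = 0; l < n_lab; ++l)
    for (int j = 0; j < n_phi; ++j) {
      out(j, l).r = re[j + n_phi * l];
      out(j, l).i = im[j + n_phi * l];
    }
  return out;
}
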