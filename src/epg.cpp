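// Compiled engine for the MP2RAGE extended-phase-graph simulation and the
// streaming Monte-Carlo CNR kernel.  The exported R functions epg operators
// (R/epg.R) are the readable reference implementation; this file must agree
// with them exactly (tested in test-sequence.R).

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

static const double TRUNC_AMP = 1e-10;  // configuration amplitudes below this
                                        // at the leading order are dropped

namespace {

struct EPGState {
  int K;     // allocated maximum order
  int kact;  // highest currently active order
  std::vector<cplx> Fp, Fm, Z;
  double PD;
  EPGState(int K_, double PD_)
      : K(K_), kact(0), Fp(K_ + 2), Fm(K_ + 2), Z(K_ + 2), PD(PD_) {
    Z[0] = PD_;
  }
};

inline double deg2rad(double d) { return d * M_PI / 180.0; }

inline double mod360(double x) { return x - 360.0 * std::floor(x / 360.0); }

// Standard EPG rotation: mixes (F+(k), F-(k), Z(k)) at every order with the
// 3x3 matrix for flip alpha about an axis at azimuth phi (radians).
void rf_rot(EPGState &s, double alpha, double phi) {
  const double ca = std::cos(alpha), sa = std::sin(alpha);
  const double ch = std::cos(alpha / 2.0), sh = std::sin(alpha / 2.0);
  const double c2 = ch * ch, s2 = sh * sh;
  const cplx i1(0.0, 1.0);
  const cplx eip(std::cos(phi), std::sin(phi));
  const cplx e2ip = eip * eip;
  const cplx t11 = c2, t12 = e2ip * s2, t13 = -i1 * eip * sa;
  const cplx t21 = std::conj(e2ip) * s2, t22 = c2, t23 = i1 * std::conj(eip) * sa;
  const cplx t31 = -0.5 * i1 * std::conj(eip) * sa, t32 = 0.5 * i1 * eip * sa,
             t33 = ca;
  for (int k = 0; k <= s.kact; ++k) {
    const cplx fp = s.Fp[k], fm = s.Fm[k], z = s.Z[k];
    s.Fp[k] = t11 * fp + t12 * fm + t13 * z;
    s.Fm[k] = t21 * fp + t22 * fm + t23 * z;
    s.Z[k] = t31 * fp + t32 * fm + t33 * z;
  }
}

// E2 decay on transverse, E1 decay plus recovery toward PD on longitudinal.
// useT2 = false annihilates the transverse configurations (ideal spoiling).
void relax(EPGState &s, double dt, double T1, double T2, bool useT2) {
  const double E1 = std::exp(-dt / T1);
  const double E2 = useT2 ? std::exp(-dt / T2) : 0.0;
  for (int k = 0; k <= s.kact; ++k) {
    s.Fp[k] *= E2;
    s.Fm[k] *= E2;
    s.Z[k] *= E1;
  }
  s.Z[0] += s.PD * (1.0 - E1);
}

// Diffusion attenuation for one TR_GRE interval during which the dephasing
// moment grows linearly by one unit of order.  att* are precomputed per order.
void diffuse(EPGState &s, const std::vector<double> &attFp,
             const std::vector<double> &attFm, const std::vector<double> &attZ) {
  for (int k = 0; k <= s.kact; ++k) {
    s.Fp[k] *= attFp[k];
    s.Fm[k] *= attFm[k];
    s.Z[k] *= attZ[k];
  }
}

// Gradient shift: F(k) -> F(k+1); the new F+(0) enters from conj(F-(1)).
void shift(EPGState &s) {
  const int ka = s.kact;
  const int newka = std::min(ka + 1, s.K);
  const cplx oldFm1 = s.Fm[1];
  for (int k = newka; k >= 1; --k) s.Fp[k] = s.Fp[k - 1];
  s.Fp[0] = std::conj(oldFm1);
  for (int k = 0; k <= newka; ++k) s.Fm[k] = s.Fm[k + 1];
  s.kact = newka;
  while (s.kact > 0 && std::abs(s.Fp[s.kact]) < TRUNC_AMP &&
         std::abs(s.Fm[s.kact]) < TRUNC_AMP && std::abs(s.Z[s.kact]) < TRUNC_AMP) {
    s.Fp[s.kact] = s.Fm[s.kact] = s.Z[s.kact] = cplx(0.0);
    --s.kact;
  }
}

// Adiabatic inversion with efficiency eff followed by a crusher: all Z scaled
// by -eff, transverse configurations destroyed.
void invert(EPGState &s, double eff) {
  for (int k = 0; k <= s.kact; ++k) {
    s.Z[k] *= -eff;
    s.Fp[k] = cplx(0.0);
    s.Fm[k] = cplx(0.0);
  }
}

struct SeqPar {
  double TR, TRgre, TI1, TI2, inc, dephTR, voxel, eff;
  int nExc, kCenter;
  double TA, TB, TC;
};

SeqPar seq_from_list(const List &seq) {
  SeqPar p;
  p.TR = as<double>(seq["TR_MP2RAGE"]);
  p.TRgre = as<double>(seq["TR_GRE"]);
  p.TI1 = as<double>(seq["TI1"]);
  p.TI2 = as<double>(seq["TI2"]);
  p.nExc = as<int>(seq["nExc"]);
  p.kCenter = as<int>(seq["kCenter"]);
  p.inc = as<double>(seq["phase_increment"]);
  p.dephTR = as<double>(seq["dephasing_per_tr"]);
  p.voxel = as<double>(seq["voxel_size"]);
  p.eff = as<double>(seq["eff"]);
  p.TA = p.TI1 - p.kCenter * p.TRgre;
  p.TB = p.TI2 - p.TI1 - p.nExc * p.TRgre;
  p.TC = p.TR - p.TI2 - (p.nExc - p.kCenter) * p.TRgre;
  if (p.TA < -1e-9 || p.TB < -1e-9 || p.TC < -1e-9)
    stop("infeasible TI/TR combination");
  return p;
}

// One steady-state simulation; returns demodulated complex center-of-k-space
// signals (multiplied by i so that +Mz maps to a positive real signal).
void simulate_one(const SeqPar &p, double T1, double T2, double PD, double D,
                  double a1deg, double a2deg, double b1, bool useT2,
                  bool useDiff, bool useRF, int maxCycles, double tol,
                  cplx &S1, cplx &S2, int &cycles, bool &converged) {
  const int K = 2 * p.nExc + 2;
  EPGState s(K, PD);
  const double a1 = deg2rad(a1deg * b1), a2 = deg2rad(a2deg * b1);

  std::vector<double> attFp(K + 2, 1.0), attFm(K + 2, 1.0), attZ(K + 2, 1.0);
  const bool doDiff = useDiff && D > 0.0;
  if (doDiff) {
    const double kg = 2.0 * M_PI * p.dephTR / p.voxel;        // rad/mm
    const double base = kg * kg * (p.TRgre / 1000.0) * D;     // dimensionless
    for (int k = 0; k <= K + 1; ++k) {
      attFp[k] = std::exp(-base * (k * (double)k + k + 1.0 / 3.0));
      attFm[k] = std::exp(-base * (k * (double)k - k + 1.0 / 3.0));
      attZ[k] = std::exp(-base * (k * (double)k));
    }
  }

  cplx S1p(0.0), S2p(0.0);
  converged = false;
  cycles = 0;
  for (int c = 0; c < maxCycles; ++c) {
    ++cycles;
    invert(s, p.eff);
    relax(s, p.TA, T1, T2, useT2);
    for (int blk = 0; blk < 2; ++blk) {
      const double a = (blk == 0) ? a1 : a2;
      for (int j = 0; j < p.nExc; ++j) {
        const int n = blk * p.nExc + j;  // pulse counter, reset each cycle
        const double phiDeg =
            useRF ? mod360(p.inc * 0.5 * n * (n + 1.0)) : 0.0;
        const double phi = deg2rad(phiDeg);
        rf_rot(s, a, phi);
        if (j == p.kCenter) {
          const cplx sig =
              cplx(0.0, 1.0) * s.Fp[0] * std::exp(cplx(0.0, -phi));
          if (blk == 0) S1 = sig; else S2 = sig;
        }
        relax(s, p.TRgre, T1, T2, useT2);
        if (useT2) {
          if (doDiff) diffuse(s, attFp, attFm, attZ);
          shift(s);
        }
      }
      relax(s, (blk == 0) ? p.TB : p.TC, T1, T2, useT2);
    }
    const double delta = std::abs(S1 - S1p) + std::abs(S2 - S2p);
    const double scale = std::abs(S1) + std::abs(S2) + 1e-30;
    if (c > 0 && delta <= tol * scale) {
      converged = true;
      break;
    }
    S1p = S1;
    S2p = S2;
  }
}

}  // namespace

// [[Rcpp::export]]
List epg_simulate_cpp(List seq, NumericVector tissue, double alpha1,
                      double alpha2, double b1, bool useT2, bool useDiffusion,
                      bool useRFSpoiling, int maxCycles, double tol) {
  SeqPar p = seq_from_list(seq);
  cplx S1, S2;
  int cycles;
  bool conv;
  simulate_one(p, tissue[0], tissue[1], tissue[2], tissue[3], alpha1, alpha2,
               b1, useT2, useDiffusion, useRFSpoiling, maxCycles, tol, S1, S2,
               cycles, conv);
  return List::create(
      _["S1"] = Rcomplex{S1.real(), S1.imag()},
      _["S2"] = Rcomplex{S2.real(), S2.imag()}, _["cycles"] = cycles,
      _["converged"] = conv);
}

// Simulate all (alpha1, alpha2, B1 scale, tissue) combinations; returns a
// complex array with dim (2, nTissue, nB1, nAlpha2, nAlpha1).
// tissues: rows = tissue, columns = T1, T2, PD, D.
// [[Rcpp::export]]
ComplexVector epg_grid_cpp(List seq, NumericMatrix tissues,
                           NumericVector alpha1, NumericVector alpha2,
                           NumericVector b1, bool useT2, bool useDiffusion,
                           bool useRFSpoiling, int maxCycles, double tol) {
  SeqPar p = seq_from_list(seq);
  const int nT = tissues.nrow(), nB = b1.size(), n2 = alpha2.size(),
            n1 = alpha1.size();
  ComplexVector out(2 * nT * nB * n2 * n1);
  int idx = 0;
  for (int i1 = 0; i1 < n1; ++i1) {
    Rcpp::checkUserInterrupt();
    for (int i2 = 0; i2 < n2; ++i2) {
      for (int ib = 0; ib < nB; ++ib) {
        for (int t = 0; t < nT; ++t) {
          cplx S1, S2;
          int cycles;
          bool conv;
          simulate_one(p, tissues(t, 0), tissues(t, 1), tissues(t, 2),
                       tissues(t, 3), alpha1[i1], alpha2[i2], b1[ib], useT2,
                       useDiffusion, useRFSpoiling, maxCycles, tol, S1, S2,
                       cycles, conv);
          // layout: signal index fastest, then tissue, B1, alpha2, alpha1
          const int base = 2 * (t + nT * (ib + nB * (i2 + n2 * i1)));
          out[base] = Rcomplex{S1.real(), S1.imag()};
          out[base + 1] = Rcomplex{S2.real(), S2.imag()};
          (void)idx;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(2, nT, nB, n2, n1);
  return out;
}

namespace {

// CNR of the four contrast channels for one (alpha1, alpha2) cell:
//   0: UNI WM-GM, 1: UNI GM-CSF, 2: FLAWS_min GM-WM, 3: FLAWS_min GM-CSF.
// S points at 2 x 3 x nB1 complex signals (signal, tissue WM/GM/CSF, B1).
// Complex Gaussian noise of SD sigma per channel is drawn nReps times from
// R's RNG; CNR = mean(difference)/SD(difference), averaged over B1 scales.
void cell_cnrs(const Rcomplex *S, int nB, double sigma, int nReps,
               double *avg4, double *perB1 /* 4 x nB or nullptr */) {
  for (int c = 0; c < 4; ++c) avg4[c] = 0.0;
  for (int ib = 0; ib < nB; ++ib) {
    double s1r[3], s1i[3], s2r[3], s2i[3];
    for (int t = 0; t < 3; ++t) {
      const Rcomplex a = S[0 + 2 * t + 6 * ib];
      const Rcomplex b = S[1 + 2 * t + 6 * ib];
      s1r[t] = a.r; s1i[t] = a.i; s2r[t] = b.r; s2i[t] = b.i;
    }
    double sum[4] = {0, 0, 0, 0}, sq[4] = {0, 0, 0, 0};
    for (int r = 0; r < nReps; ++r) {
      double u[3], f[3];
      for (int t = 0; t < 3; ++t) {
        const double x1 = s1r[t] + sigma * ::norm_rand();
        const double y1 = s1i[t] + sigma * ::norm_rand();
        const double x2 = s2r[t] + sigma * ::norm_rand();
        const double y2 = s2i[t] + sigma * ::norm_rand();
        const double dd = x1 * x1 + y1 * y1 + x2 * x2 + y2 * y2;
        u[t] = (dd > 0.0) ? (x1 * x2 + y1 * y2) / dd : 0.0;
        const double m1 = std::sqrt(x1 * x1 + y1 * y1);
        const double m2 = std::sqrt(x2 * x2 + y2 * y2);
        const double ms = m1 + m2;
        f[t] = (ms > 0.0) ? ((m1 < m2) ? m1 : m2) / ms : 0.0;
      }
      const double d0 = u[0] - u[1];  // UNI WM-GM
      const double d1 = u[1] - u[2];  // UNI GM-CSF
      const double d2 = f[1] - f[0];  // FLAWS_min GM-WM
      const double d3 = f[1] - f[2];  // FLAWS_min GM-CSF
      sum[0] += d0; sq[0] += d0 * d0;
      sum[1] += d1; sq[1] += d1 * d1;
      sum[2] += d2; sq[2] += d2 * d2;
      sum[3] += d3; sq[3] += d3 * d3;
    }
    for (int c = 0; c < 4; ++c) {
      const double mean = sum[c] / nReps;
      const double var = (sq[c] - nReps * mean * mean) / (nReps - 1.0);
      const double cnr = (var > 0.0) ? mean / std::sqrt(var) : 0.0;
      if (perB1) perB1[c + 4 * ib] = cnr;
      avg4[c] += cnr / nB;
    }
  }
}

}  // namespace

// Per-B1 CNRs for one flip-angle cell: returns 4 x nB1 matrix.
// [[Rcpp::export]]
NumericMatrix mc_cnr_cell_cpp(ComplexVector S, double sigma, int nReps) {
  IntegerVector dim = S.attr("dim");
  if (dim.size() != 3 || dim[0] != 2 || dim[1] != 3)
    stop("signal array must have dim (2, 3, nB1)");
  const int nB = dim[2];
  NumericMatrix out(4, nB);
  double avg4[4];
  cell_cnrs(&S[0], nB, sigma, nReps, avg4, &out[0]);
  return out;
}

// B1-averaged CNRs over a flip-angle grid: S has dim (2, 3, nB1, nA2, nA1);
// returns 4 x (nA2*nA1) with alpha2 varying fastest.
// [[Rcpp::export]]
NumericMatrix mc_cnr_grid_cpp(ComplexVector S, double sigma, int nReps) {
  IntegerVector dim = S.attr("dim");
  if (dim.size() != 5 || dim[0] != 2 || dim[1] != 3)
    stop("signal array must have dim (2, 3, nB1, nA2, nA1)");
  const int nB = dim[2], nCell = dim[3] * dim[4];
  NumericMatrix out(4, nCell);
  double avg4[4];
  for (int cell = 0; cell < nCell; ++cell) {
    if (cell % 8 == 0) Rcpp::checkUserInterrupt();
    cell_cnrs(&S[2 * 3 * nB * cell], nB, sigma, nReps, avg4, nullptr);
    for (int c = 0; c < 4; ++c) out(c, cell) = avg4[c];
  }
  return out;
}
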