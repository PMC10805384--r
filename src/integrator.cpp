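// Fixed-step RK4 integrator for the nine-population mean-field model.
//
// Per projection (target a <- source b) the state is (V_ab, V'_ab, phi_ab,
// phi'_ab): second-order synaptic dynamics driven by the delayed field
//   (1/(ab)) V'' + (1/a + 1/b) V' + V = s_ab * nu_ab * phi_ab(t - tau_ab)
// and the spatially uniform mode of the damped wave equation
//   (1/g^2) phi'' + (2/g) phi' + phi = Q_b(t).
// Each population additionally carries one external afferent (V_ext, V'_ext)
// driven, unscaled, by a per-step piecewise-constant drive (mean + noise).
//
// Delay lines are ring buffers of committed phi samples; RK4 stage times are
// served by linear interpolation (config validation keeps dt <= tau/4 for
// every delayed projection, so stage lookups never need future samples).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Deriv {
  std::vector<double> dV, dVd, dP, dPd, dVe, dVed;
};

// [[Rcpp::export]]
List mf_integrate_cpp(NumericVector Qmax, NumericVector theta,
                      NumericVector sigma,
                      IntegerVector tgt, IntegerVector src,
                      NumericVector nu, NumericVector tau,
                      NumericVector gamma_, NumericVector alpha,
                      NumericVector beta, NumericVector hscale,
                      NumericVector ext_alpha, NumericVector ext_beta,
                      NumericMatrix drive,  // (nsteps+1) x P, volts
                      double dt, int nsteps, int record_every,
                      NumericVector init_V, NumericVector init_Vd,
                      NumericVector init_P, NumericVector init_Pd,
                      NumericVector init_Ve, NumericVector init_Ved,
                      int perturb_step, NumericVector perturb_V,
                      NumericVector perturb_Ve) {
  const int P = Qmax.size();
  const int J = tgt.size();

  std::vector<double> V(init_V.begin(), init_V.end());
  std::vector<double> Vd(init_Vd.begin(), init_Vd.end());
  std::vector<double> Ph(init_P.begin(), init_P.end());
  std::vector<double> Phd(init_Pd.begin(), init_Pd.end());
  std::vector<double> Ve(init_Ve.begin(), init_Ve.end());
  std::vector<double> Ved(init_Ved.begin(), init_Ved.end());

  // ring buffers for delayed phi
  std::vector<int> buflen(J), bufpos(J, 0);
  std::vector<std::vector<double> > buf(J);
  std::vector<double> dlag(J);  // tau / dt (fractional allowed)
  for (int j = 0; j < J; ++j) {
    dlag[j] = tau[j] / dt;
    buflen[j] = (tau[j] > 0.0) ? (int)std::ceil(dlag[j]) + 3 : 1;
    buf[j].assign(buflen[j], Ph[j]);
  }

  const int nrec = nsteps / record_every + 1;
  NumericMatrix Qrec(nrec, P), Vrec(nrec, J), Verec(nrec, P);
  NumericVector trec(nrec);

  std::vector<double> Va(P), Q(P);
  auto popQ = [&](const std::vector<double>& Vs,
                  const std::vector<double>& Ves) {
    for (int a = 0; a < P; ++a) Va[a] = Ves[a];
    for (int j = 0; j < J; ++j) Va[tgt[j]] += Vs[j];
    for (int a = 0; a < P; ++a)
      Q[a] = Qmax[a] / (1.0 + std::exp(-(Va[a] - theta[a]) / sigma[a]));
  };

  // delayed phi at stage offset c (fraction of a step before commit of step n)
  auto phidel = [&](int j, double c, const std::vector<double>& Phs) {
    if (tau[j] <= 0.0) return Phs[j];
    double back = dlag[j] - c;  // steps before the last committed sample
    int k = (int)std::floor(back);
    double f = back - k;
    int n = buflen[j];
    int i1 = ((bufpos[j] - k) % n + n) % n;       // sample k steps back
    int i2 = ((bufpos[j] - k - 1) % n + n) % n;   // k+1 steps back
    return (1.0 - f) * buf[j][i1] + f * buf[j][i2];
  };

  Deriv d1, d2, d3, d4;
  for (Deriv* d : {&d1, &d2, &d3, &d4}) {
    d->dV.resize(J); d->dVd.resize(J); d->dP.resize(J); d->dPd.resize(J);
    d->dVe.resize(P); d->dVed.resize(P);
  }
  std::vector<double> tV(J), tVd(J), tP(J), tPd(J), tVe(P), tVed(P);

  auto deriv = [&](Deriv& out, const std::vector<double>& Vs,
                   const std::vector<double>& Vds,
                   const std::vector<double>& Phs,
                   const std::vector<double>& Phds,
                   const std::vector<double>& Ves,
                   const std::vector<double>& Veds,
                   int step, double c) {
    popQ(Vs, Ves);
    for (int j = 0; j < J; ++j) {
      double a = alpha[j], b = beta[j];
      double drive_j = hscale[j] * nu[j] * phidel(j, c, Phs);
      out.dV[j] = Vds[j];
      out.dVd[j] = a * b * (drive_j - Vs[j]) - (a + b) * Vds[j];
      double g = gamma_[j];
      out.dP[j] = Phds[j];
      out.dPd[j] = g * g * (Q[src[j]] - Phs[j]) - 2.0 * g * Phds[j];
    }
    for (int a = 0; a < P; ++a) {
      double al = ext_alpha[a], be = ext_beta[a];
      double u = drive(step, a);  // held constant across the step
      out.dVe[a] = Veds[a];
      out.dVed[a] = al * be * (u - Ves[a]) - (al + be) * Veds[a];
    }
  };

  int irec = 0;
  auto record = [&](int step) {
    popQ(V, Ve);
    for (int a = 0; a < P; ++a) { Qrec(irec, a) = Q[a]; Verec(irec, a) = Ve[a]; }
    for (int j = 0; j < J; ++j) Vrec(irec, j) = V[j];
    trec[irec] = step * dt;
    ++irec;
  };
  record(0);

  for (int step = 0; step < nsteps; ++step) {
    if (perturb_step >= 0 && step == perturb_step) {
      for (int j = 0; j < J; ++j) V[j] += perturb_V[j];
      for (int a = 0; a < P; ++a) Ve[a] += perturb_Ve[a];
    }

    deriv(d1, V, Vd, Ph, Phd, Ve, Ved, step, 0.0);
    for (int j = 0; j < J; ++j) {
      tV[j] = V[j] + 0.5 * dt * d1.dV[j];  tVd[j] = Vd[j] + 0.5 * dt * d1.dVd[j];
      tP[j] = Ph[j] + 0.5 * dt * d1.dP[j]; tPd[j] = Phd[j] + 0.5 * dt * d1.dPd[j];
    }
    for (int a = 0; a < P; ++a) {
      tVe[a] = Ve[a] + 0.5 * dt * d1.dVe[a]; tVed[a] = Ved[a] + 0.5 * dt * d1.dVed[a];
    }
    deriv(d2, tV, tVd, tP, tPd, tVe, tVed, step, 0.5);
    for (int j = 0; j < J; ++j) {
      tV[j] = V[j] + 0.5 * dt * d2.dV[j];  tVd[j] = Vd[j] + 0.5 * dt * d2.dVd[j];
      tP[j] = Ph[j] + 0.5 * dt * d2.dP[j]; tPd[j] = Phd[j] + 0.5 * dt * d2.dPd[j];
    }
    for (int a = 0; a < P; ++a) {
      tVe[a] = Ve[a] + 0.5 * dt * d2.dVe[a]; tVed[a] = Ved[a] + 0.5 * dt * d2.dVed[a];
    }
    deriv(d3, tV, tVd, tP, tPd, tVe, tVed, step, 0.5);
    for (int j = 0; j < J; ++j) {
      tV[j] = V[j] + dt * d3.dV[j];  tVd[j] = Vd[j] + dt * d3.dVd[j];
      tP[j] = Ph[j] + dt * d3.dP[j]; tPd[j] = Phd[j] + dt * d3.dPd[j];
    }
    for (int a = 0; a < P; ++a) {
      tVe[a] = Ve[a] + dt * d3.dVe[a]; tVed[a] = Ved[a] + dt * d3.dVed[a];
    }
    deriv(d4, tV, tVd, tP, tPd, tVe, tVed, step, 1.0);

    for (int j = 0; j < J; ++j) {
      V[j]  += dt / 6.0 * (d1.dV[j]  + 2*d2.dV[j]  + 2*d3.dV[j]  + d4.dV[j]);
      Vd[j] += dt / 6.0 * (d1.dVd[j] + 2*d2.dVd[j] + 2*d3.dVd[j] + d4.dVd[j]);
      Ph[j] += dt / 6.0 * (d1.dP[j]  + 2*d2.dP[j]  + 2*d3.dP[j]  + d4.dP[j]);
      Phd[j]+= dt / 6.0 * (d1.dPd[j] + 2*d2.dPd[j] + 2*d3.dPd[j] + d4.dPd[j]);
    }
    for (int a = 0; a < P; ++a) {
      Ve[a] += dt / 6.0 * (d1.dVe[a] + 2*d2.dVe[a] + 2*d3.dVe[a] + d4.dVe[a]);
      Ved[a]+= dt / 6.0 * (d1.dVed[a] + 2*d2.dVed[a] + 2*d3.dVed[a] + d4.dVed[a]);
    }

    // commit phi samples to the delay lines
    for (int j = 0; j < J; ++j) {
      bufpos[j] = (bufpos[j] + 1) % buflen[j];
      buf[j][bufpos[j]] = Ph[j];
    }

    if ((step + 1) % record_every == 0) record(step + 1);

    if ((step & 1023) == 0) {
      for (int j = 0; j < J; ++j) {
        if (!std::isfinite(V[j])) {
          return List::create(_["ok"] = false, _["bad_target"] = tgt[j] + 1,
                              _["t"] = step * dt);
        }
      }
    }
  }
  for (int j = 0; j < J; ++j)
    if (!std::isfinite(V[j]))
      return List::create(_["ok"] = false, _["bad_target"] = tgt[j] + 1,
                          _["t"] = nsteps * dt);

  return List::create(_["ok"] = true, _["t"] = trec, _["Q"] = Qrec,
                      _["Vab"] = Vrec, _["Vext"] = Verec,
                      _["final_V"] = NumericVector(V.begin(), V.end()),
                      _["final_Vd"] = NumericVector(Vd.begin(), Vd.end()));
}
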