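#include <Rcpp.h>
#include <cmath>

// Discrete stochastic update loop for the built-in presets.
//
// One "time step" is one update attempt. Event weights at state (I, J),
// with x = eps*I, y = eps*J:
//   symmetric differentiation  L*S*P      (I,J) -> (I-1, J+2)
//   symmetric proliferation    L*S*(1-P)  (I,J) -> (I+1, J)
//   asymmetric division        L*(1-S)    (I,J) -> (I,   J+1)
//   death                      D          (I,J) -> (I,   J-1)
//   influx                     E          (I,J) -> (I+1, J)
// Division weights are zeroed at I = 0 and the death weight at J = 0, so the
// populations never go negative. When the weight sum W exceeds 1 events are
// drawn with probabilities w/W; otherwise each weight is a literal Bernoulli
// probability and the update may be a "none" event. For the closed D = 1 - L
// presets W == 1 exactly, so every update is an event.
//
// RNG protocol (mirrored exactly by the pure-R stepper): when an injury is
// configured, each update first consumes one uniform for the injury draw;
// an injury update in removal mode consumes nothing further. Every normal
// update consumes exactly one uniform for the event draw.
//
// Event codes: 0 none, 1 diff, 2 prolif, 3 asym, 4 death, 5 influx,
// 6 injury.

namespace {

struct Rates {
  double L, P, D, E;
};

inline Rates preset_rates(int preset, double x, double y, double h,
                          bool influx) {
  Rates r;
  switch (preset) {
  case 3: {
    double u = 1.0 - std::exp(-x);
    r.L = (u + y <= 0.0) ? 0.0 : u / (u + y); // origin limit

    r.P = 1.0 - std::exp(-3.0 * y);
    r.D = 1.0 - r.L;
    r.E = 0.0;
    break;
  }
  case 5: {
    double t = std::tanh(x);
    r.L = 2.0 * t / (2.0 * t + 0.4);
    r.P = std::tanh(x + 0.1 * y);
    r.D = 1.0 - r.L;
    r.E = 0.0;
    break;
  }
  default: { // follicle variant
    double t = std::tanh(x);
    r.L = 0.9 * t / (2.0 * t + 0.4);
    r.P = std::tanh(x + 0.1 * y);
    r.D = h + 0.01 * y;
    r.E = influx ? 0.02 / (1.0 + x) : 0.0;
    break;
  }
  }
  return r;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List sim_core_native(int preset, double epsilon, double symmetry,
                           double h, bool influx, int steps, int I0, int J0,
                           bool stop_on_extinction, double injury_prob,
                           double injury_frac, int injury_target,
                           int injury_mode, double injury_mult, int burn_in,
                           bool keep_path) {
  long long I = I0, J = J0;
  const double S = symmetry;

  Rcpp::IntegerVector pI, pJ, pev;
  if (keep_path) {
    pI = Rcpp::IntegerVector(steps);
    pJ = Rcpp::IntegerVector(steps);
    pev = Rcpp::IntegerVector(steps);
  }

  // streaming post-burn-in moment sums
  double n = 0.0, sI = 0.0, sJ = 0.0, sII = 0.0, sJJ = 0.0, sIJ = 0.0;

  int done = 0;
  std::string status = "completed";

  for (int step = 1; step <= steps; ++step) {
    int ev = 0;
    bool injured = false;
    double dmult = 1.0;

    if (injury_prob > 0.0) {
      double u0 = unif_rand();
      injured = (u0 < injury_prob);
    }

    if (injured && injury_mode == 0) { // removal
      if (injury_target == 0 || injury_target == 2) { // differentiated/both
        long long rem = (long long)std::floor(injury_frac * (double)J + 0.5);
        J -= rem;
        if (J < 0) J = 0;
      }
      if (injury_target == 1 || injury_target == 2) { // stem/both
        long long rem = (long long)std::floor(injury_frac * (double)I + 0.5);
        I -= rem;
        if (I < 0) I = 0;
      }
      ev = 6;
    } else {
      if (injured && injury_mode == 1) dmult = injury_mult;
      double x = epsilon * (double)I, y = epsilon * (double)J;
      Rates r = preset_rates(preset, x, y, h, influx);
      double D = r.D * dmult;
      double w1 = (I > 0) ? r.L * S * r.P : 0.0;
      double w2 = (I > 0) ? r.L * S * (1.0 - r.P) : 0.0;
      double w3 = (I > 0) ? r.L * (1.0 - S) : 0.0;
      double w4 = (J > 0) ? D : 0.0;
      double w5 = r.E;
      double W = w1 + w2 + w3 + w4 + w5;
      if (W <= 0.0) {
        status = "frozen";
        break;
      }
      double thr = (W > 1.0) ? W : 1.0;
      double u = unif_rand() * thr;
      if (u < w1) {
        --I; J += 2; ev = 1;
      } else if (u < w1 + w2) {
        ++I; ev = 2;
      } else if (u < w1 + w2 + w3) {
        ++J; ev = 3;
      } else if (u < w1 + w2 + w3 + w4) {
        --J; ev = 4;
      } else if (u < W) {
        ++I; ev = 5;
      } // else: none
    }

    if (keep_path) {
      pI[step - 1] = (int)I;
      pJ[step - 1] = (int)J;
      pev[step - 1] = ev;
    }
    if (step > burn_in) {
      n += 1.0;
      double di = (double)I, dj = (double)J;
      sI += di; sJ += dj;
      sII += di * di; sJJ += dj * dj; sIJ += di * dj;
    }
    done = step;
    if (stop_on_extinction && (I == 0 || J == 0)) {
      status = "extinct";
      break;
    }
  }

  if (keep_path && done < steps) {
    pI = Rcpp::IntegerVector(pI.begin(), pI.begin() + done);
    pJ = Rcpp::IntegerVector(pJ.begin(), pJ.begin() + done);
    pev = Rcpp::IntegerVector(pev.begin(), pev.begin() + done);
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("steps_done") = done, Rcpp::Named("status") = status,
      Rcpp::Named("final_I") = (double)I, Rcpp::Named("final_J") = (double)J,
      Rcpp::Named("n") = n, Rcpp::Named("sI") = sI, Rcpp::Named("sJ") = sJ,
      Rcpp::Named("sII") = sII, Rcpp::Named("sJJ") = sJJ,
      Rcpp::Named("sIJ") = sIJ);
  if (keep_path) {
    out["I"] = pI;
    out["J"] = pJ;
    out["event"] = pev;
  }
  return out;
}
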