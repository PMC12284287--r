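#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step explicit integration of a single-compartment membrane with a
// hyperpolarization-activated (sag) conductance:
//
//   Cm dV/dt = -(V - EL)/Rin - gh * m * (V - Eh) + I(t)
//   tauh dm/dt = m_inf(V) - m,   m_inf(V) = 1 / (1 + exp((V + 80)/6))
//
// Units: mV, ms, pA, MOhm, pF, nS.  (V - EL)/Rin is in nA, hence the factor
// 1000 to pA.  Action potentials are pasted as a voltage template anchored at
// the threshold crossing; m is frozen while a template is being written.
//
// forced_idx (0-based sample indices) paste the template unconditionally and
// are used for spontaneous firing at zero holding current.

static inline double m_inf(double v) {
  return 1.0 / (1.0 + std::exp((v + 80.0) / 6.0));
}

// [[Rcpp::export(name = ".integrate_membrane")]]
List integrate_membrane(NumericVector current_pA, double dt,
                        double EL, double Rin, double Cm,
                        double gh, double tauh, double Eh,
                        double VT, NumericVector tmpl,
                        IntegerVector forced_idx,
                        double V0, bool allow_spikes) {
  const int n = current_pA.size();
  const int nt = tmpl.size();
  NumericVector V(n);
  std::vector<int> thr_idx;   // template start (threshold) samples, 0-based
  double v = V0;
  double m = m_inf(V0);
  int paste_until = -1;       // last sample index of an active template
  int paste_start = -1;
  int fptr = 0;
  const int nforced = forced_idx.size();

  for (int i = 0; i < n; ++i) {
    bool force = false;
    if (fptr < nforced && forced_idx[fptr] == i) {
      force = true;
      ++fptr;
    }
    if (i <= paste_until) {
      V[i] = tmpl[i - paste_start];
      v = V[i];
      continue;
    }
    if (i > 0) {
      double I_ion = -(v - EL) * 1000.0 / Rin;
      if (gh > 0.0) I_ion += -gh * m * (v - Eh);
      double dv = (I_ion + current_pA[i - 1]) * dt / Cm;
      double mi = m_inf(v);
      if (tauh > 0.0) m += dt * (mi - m) / tauh; else m = mi;
      v += dv;
    }
    bool fire = force || (allow_spikes && nt > 0 && v >= VT);
    if (fire && nt > 0) {
      paste_start = i;
      paste_until = std::min(n - 1, i + nt - 1);
      thr_idx.push_back(i);
      V[i] = tmpl[0];
      v = V[i];
      // template end voltage carries over; m stays frozen during the paste
    } else {
      V[i] = v;
    }
  }

  return List::create(_["voltage"] = V,
                      _["threshold_idx"] = wrap(thr_idx));
}
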