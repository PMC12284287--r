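#include <Rcpp.h>
using namespace Rcpp;

// AP detection scan: upward dV/dt criterion crossings followed by a voltage
// maximum above 0 mV within the search window; detections inside the
// refractory merge window are merged (first kept).  Returns 0-based peak and
// crossing (onset) indices.

// [[Rcpp::export(name = ".detect_peaks")]]
List detect_peaks(NumericVector v, double dt, double criterion,
                  int win, int merge_win) {
  const int n = v.size();
  std::vector<int> peaks, onsets;
  double prev_d = R_NegInf;
  int last_peak = -merge_win - 1;
  for (int i = 0; i < n - 1; ++i) {
    double d = (v[i + 1] - v[i]) / dt;
    if (d >= criterion && prev_d < criterion) {
      int jmax = std::min(n - 1, i + win);
      int pk = i;
      double vmax = v[i];
      for (int j = i + 1; j <= jmax; ++j)
        if (v[j] > vmax) { vmax = v[j]; pk = j; }
      if (vmax > 0.0) {
        if (peaks.empty() || (pk != last_peak && pk - last_peak >= merge_win)) {
          peaks.push_back(pk);
          onsets.push_back(i);
          last_peak = pk;
        }
      }
    }
    prev_d = d;
  }
  return List::create(_["peaks"] = wrap(peaks), _["onsets"] = wrap(onsets));
}
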