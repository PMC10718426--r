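// Event-driven cell-level simulator of the microchannel and Gillespie
// simulation of the Moran chain.  Uses R's RNG stream (via unif_rand /
// exp_rand) so runs are reproducible with set.seed() from R; replicates
// consume a single stream sequentially.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Pick a cell index (0-based) proportionally to fitness: label 1 has
// weight w, label 2 has weight 1.  total_w = w*n1 + (N - n1).
static inline int pick_cell(const std::vector<int>& cells, double w,
                            double total_w) {
  double u = unif_rand() * total_w;
  double acc = 0.0;
  const int N = (int)cells.size();
  for (int i = 0; i < N; ++i) {
    acc += (cells[i] == 1) ? w : 1.0;
    if (u <= acc) return i;
  }
  return N - 1;
}

// One division event on the channel; updates cells and n1 in place.
// Returns nothing; time accrual is handled by the caller (every event,
// including null ones, advances the clock at total rate r*(N-1)).
static inline void channel_event(std::vector<int>& cells, double w, int& n1) {
  const int N = (int)cells.size();
  const double W = w * n1 + (double)(N - n1);
  const int i = pick_cell(cells, w, W);
  const bool right = unif_rand() < (double)i / (double)(N - 1);
  if (right) {
    if (i == N - 1) return;  // daughter inserted past the end and expelled
    const int expelled = cells[N - 1];
    for (int j = N - 1; j > i + 1; --j) cells[j] = cells[j - 1];
    cells[i + 1] = cells[i];
    n1 += (cells[i] == 1) - (expelled == 1);
  } else {
    if (i == 0) return;
    const int expelled = cells[0];
    for (int j = 0; j < i - 1; ++j) cells[j] = cells[j + 1];
    cells[i - 1] = cells[i];
    n1 += (cells[i] == 1) - (expelled == 1);
  }
}

// [[Rcpp::export]]
List cpp_channel_run(IntegerVector cells0, double w, double r,
                     double max_events) {
  const int N = cells0.size();
  std::vector<int> cells(cells0.begin(), cells0.end());
  int n1 = 0;
  for (int c : cells) if (c == 1) ++n1;
  const double total_rate = r * (double)(N - 1);
  double t = 0.0, ev = 0.0;
  while (n1 > 0 && n1 < N) {
    if (ev >= max_events)
      stop("event cap reached before fixation (%.0f events)", ev);
    ev += 1.0;
    t += exp_rand() / total_rate;
    channel_event(cells, w, n1);
  }
  return List::create(_["winner"] = (n1 == N) ? 1 : 2, _["time"] = t,
                      _["events"] = ev);
}

// [[Rcpp::export]]
DataFrame cpp_channel_ensemble(IntegerVector cells0, double w, double r,
                               int reps, double max_events) {
  IntegerVector winner(reps);
  NumericVector time(reps);
  for (int k = 0; k < reps; ++k) {
    List res = cpp_channel_run(cells0, w, r, max_events);
    winner[k] = as<int>(res["winner"]);
    time[k] = as<double>(res["time"]);
    if (k % 4096 == 0) checkUserInterrupt();
  }
  return DataFrame::create(_["winner"] = winner, _["time"] = time);
}

// Repeatedly sample a single division event (cell index and direction)
// from the same fixed configuration, without applying it.  Used to probe
// the microscopic selection and direction-bias laws.  Returns a matrix
// with columns: 1-based cell position, direction (1 = right, 0 = left).
// [[Rcpp::export]]
IntegerMatrix cpp_channel_probe(IntegerVector cells0, double w, int reps) {
  const int N = cells0.size();
  std::vector<int> cells(cells0.begin(), cells0.end());
  int n1 = 0;
  for (int c : cells) if (c == 1) ++n1;
  const double W = w * n1 + (double)(N - n1);
  IntegerMatrix out(reps, 2);
  for (int k = 0; k < reps; ++k) {
    const int i = pick_cell(cells, w, W);
    out(k, 0) = i + 1;
    out(k, 1) = (unif_rand() < (double)i / (double)(N - 1)) ? 1 : 0;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_moran_run(int N, double w, double r, int n0) {
  int n = n0;
  double t = 0.0;
  while (n > 0 && n < N) {
    const double D = (double)(N - n) + w * (double)n;
    const double up = r * w * (double)n * (double)(N - n) / D;
    const double down = r * (double)n * (double)(N - n) / D;
    const double tot = up + down;
    t += exp_rand() / tot;
    n += (unif_rand() * tot < up) ? 1 : -1;
  }
  return List::create(_["winner"] = (n == N) ? 1 : 2, _["time"] = t);
}

// [[Rcpp::export]]
DataFrame cpp_moran_ensemble(int N, double w, double r, int n0, int reps) {
  IntegerVector winner(reps);
  NumericVector time(reps);
  for (int k = 0; k < reps; ++k) {
    List res = cpp_moran_run(N, w, r, n0);
    winner[k] = as<int>(res["winner"]);
    time[k] = as<double>(res["time"]);
    if (k % 4096 == 0) checkUserInterrupt();
  }
  return DataFrame::create(_["winner"] = winner, _["time"] = time);
}
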