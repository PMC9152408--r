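#include <Rcpp.h>
using namespace Rcpp;

// Iterated-conditional-modes sweeps for a unary + 4-neighbour Potts energy.
//
// energy: (h*w) x K unary energies, pixels in column-major order.
// labels: h x w initial labels in 0..K-1.
// Each raster-order sweep (row by row, left to right) sets every pixel to
// the class minimising unary + beta * (# disagreeing 4-neighbours); ties
// break to the lowest class id. Stops when a sweep changes nothing or
// max_sweeps is reached. Total energy is recorded after each sweep.

static double total_energy(const NumericMatrix& energy,
                           const IntegerMatrix& lab, double beta) {
  int h = lab.nrow(), w = lab.ncol();
  double e = 0.0;
  for (int c = 0; c < w; ++c)
    for (int r = 0; r < h; ++r) {
      e += energy(r + c * h, lab(r, c));
      if (r + 1 < h && lab(r, c) != lab(r + 1, c)) e += beta;
      if (c + 1 < w && lab(r, c) != lab(r, c + 1)) e += beta;
    }
  return e;
}

// [[Rcpp::export(name = ".icm_sweeps")]]
List icm_sweeps(NumericMatrix energy, IntegerMatrix labels, double beta,
                int max_sweeps) {
  int h = labels.nrow(), w = labels.ncol(), K = energy.ncol();
  IntegerMatrix lab = clone(labels);
  std::vector<double> trace;
  trace.push_back(total_energy(energy, lab, beta));
  int sweeps = 0;
  bool changed = true;
  while (changed && sweeps < max_sweeps) {
    changed = false;
    ++sweeps;
    for (int r = 0; r < h; ++r) {
      for (int c = 0; c < w; ++c) {
        int p = r + c * h;
        int best = 0;
        double best_cost = R_PosInf;
        for (int k = 0; k < K; ++k) {
          double cost = energy(p, k);
          if (r > 0 && lab(r - 1, c) != k) cost += beta;
          if (r + 1 < h && lab(r + 1, c) != k) cost += beta;
          if (c > 0 && lab(r, c - 1) != k) cost += beta;
          if (c + 1 < w && lab(r, c + 1) != k) cost += beta;
          if (cost < best_cost) { best_cost = cost; best = k; }
        }
        if (best != lab(r, c)) { lab(r, c) = best; changed = true; }
      }
    }
    trace.push_back(total_energy(energy, lab, beta));
  }
  return List::create(_["labels"] = lab, _["sweeps"] = sweeps,
                      _["energy_trace"] = wrap(trace));
}
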