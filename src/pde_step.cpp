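#include <Rcpp.h>
using namespace Rcpp;

// Explicit-Euler integration of the coupled worm/oxygen equations on a
// periodic N x N grid, in conservative flux form:
//   dW/dt = div( D_W(O) grad W + beta(O) W grad O )
//   dO/dt = D_O lap O + f (O_am - O) - k_c W
// Diffusive and aerotactic face coefficients use the arithmetic mean of O
// (and of W for the advective weight) at cell faces, so the W update
// telescopes and conserves mass exactly up to the positivity clamp.

// [[Rcpp::export]]
List pde_steps_cpp(NumericMatrix W0, NumericMatrix O0, int nsteps,
                   double dt, double dx,
                   double a, double b, double c, double tau,
                   double D_O, double f, double k_c, double O_am,
                   double abort_factor) {
  const int N = W0.nrow();
  if (W0.ncol() != N || O0.nrow() != N || O0.ncol() != N)
    stop("fields must be square matrices of equal size");

  std::vector<double> W(W0.begin(), W0.end());
  std::vector<double> O(O0.begin(), O0.end());
  std::vector<double> dW(N * N), dO(N * N);
  std::vector<int> nxt(N);
  for (int i = 0; i < N; ++i) nxt[i] = (i + 1) % N;

  const double inv_dx = 1.0 / dx;
  const double inv_dx2 = inv_dx * inv_dx;
  const double inv_2tau = 1.0 / (2.0 * tau);

  double mass0 = 0.0;
  for (int i = 0; i < N * N; ++i) mass0 += W[i];
  const double w_abort = abort_factor * (mass0 / (N * N));

  long clamp_W_events = 0, clamp_O_events = 0;
  double clamped_mass = 0.0;
  bool aborted = false;
  int steps_done = 0;

  for (int s = 0; s < nsteps; ++s) {
    std::fill(dW.begin(), dW.end(), 0.0);

    for (int j = 0; j < N; ++j) {
      const int jn = nxt[j];
      for (int i = 0; i < N; ++i) {
        const int in = nxt[i];
        const int id = i + N * j;
        const int idx_e = in + N * j;   // east neighbour (next row index)
        const int idx_n = i + N * jn;   // north neighbour (next column)

        // east face
        {
          double Of = 0.5 * (O[id] + O[idx_e]);
          double V = (a * Of + b) * Of + c;
          double Dw = V * V * inv_2tau;
          double beta = V * (2.0 * a * Of + b) * inv_2tau;
          double G = Dw * (W[idx_e] - W[id]) * inv_dx +
                     beta * 0.5 * (W[id] + W[idx_e]) * (O[idx_e] - O[id]) * inv_dx;
          dW[id] += G * inv_dx;
          dW[idx_e] -= G * inv_dx;
        }
        // north face
        {
          double Of = 0.5 * (O[id] + O[idx_n]);
          double V = (a * Of + b) * Of + c;
          double Dw = V * V * inv_2tau;
          double beta = V * (2.0 * a * Of + b) * inv_2tau;
          double G = Dw * (W[idx_n] - W[id]) * inv_dx +
                     beta * 0.5 * (W[id] + W[idx_n]) * (O[idx_n] - O[id]) * inv_dx;
          dW[id] += G * inv_dx;
          dW[idx_n] -= G * inv_dx;
        }
        // oxygen: 5-point Laplacian + penetration - consumption
        // (uses east/north from this cell and west/south via the wrap pass)
        dO[id] = f * (O_am - O[id]) - k_c * W[id];
      }
    }
    // oxygen Laplacian in the same face-telescoping form: each undirected
    // face contributes +g to one cell and -g to its neighbour
    for (int j = 0; j < N; ++j) {
      const int jn = nxt[j];
      for (int i = 0; i < N; ++i) {
        const int in = nxt[i];
        const int id = i + N * j;
        const int idx_e = in + N * j;
        const int idx_n = i + N * jn;
        double ge = (O[idx_e] - O[id]) * inv_dx2;
        double gn = (O[idx_n] - O[id]) * inv_dx2;
        dO[id] += D_O * (ge + gn);
        dO[idx_e] -= D_O * ge;
        dO[idx_n] -= D_O * gn;
      }
    }

    double mass_before = 0.0, mass_after = 0.0, wmax = 0.0;
    bool any_neg = false;
    for (int id = 0; id < N * N; ++id) {
      W[id] += dt * dW[id];
      O[id] += dt * dO[id];
      if (W[id] < 0.0) any_neg = true;
      mass_before += W[id];
      if (O[id] < 0.0) { O[id] = 0.0; ++clamp_O_events; }
      else if (O[id] > O_am) { O[id] = O_am; ++clamp_O_events; }
      if (std::abs(W[id]) > wmax) wmax = std::abs(W[id]);
    }
    double clamped_step = 0.0;
    if (any_neg) {
      for (int id = 0; id < N * N; ++id) {
        if (W[id] < 0.0) { clamped_step -= W[id]; W[id] = 0.0; ++clamp_W_events; }
        mass_after += W[id];
      }
      clamped_mass += clamped_step;
      if (mass_after > 0.0) {
        double scale = mass_before / mass_after;
        for (int id = 0; id < N * N; ++id) W[id] *= scale;
      }
    }
    ++steps_done;
    // divergence detectors: runaway amplitude, non-finite values, or a
    // positivity clamp removing a macroscopic mass fraction in one step
    // (the signature of an oscillating over-CFL update, which the clamp
    // itself would otherwise keep bounded)
    if (wmax > w_abort || !std::isfinite(wmax) ||
        (mass0 > 0.0 && clamped_step > 0.2 * mass0)) {
      aborted = true;
      break;
    }
  }

  NumericMatrix Wout(N, N), Oout(N, N);
  std::copy(W.begin(), W.end(), Wout.begin());
  std::copy(O.begin(), O.end(), Oout.begin());
  return List::create(_["W"] = Wout, _["O"] = Oout,
                      _["steps_done"] = steps_done,
                      _["aborted"] = aborted,
                      _["clamp_W_events"] = (double)clamp_W_events,
                      _["clamp_O_events"] = (double)clamp_O_events,
                      _["clamped_mass"] = clamped_mass);
}
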