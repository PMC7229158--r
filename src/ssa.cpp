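#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Promoter states are coded 0 = C (deep inactive), 1 = B (primed), 2 = A (active).
// Reactions: C->B (alpha), B->C (beta), B->A (lambda), A->B (nu),
// transcription in A (K), decay of each mRNA (n * delta).

// One exact (direct-method) Gillespie step. Returns the waiting time, or a
// negative value when every propensity is zero (absorbing state).
static double ssa_step(int &state, int &mrna, double alpha, double beta,
                       double lambda, double nu, double K, double delta) {
  double a_switch1 = 0.0, a_switch2 = 0.0, a_tx = 0.0;
  if (state == 0) {
    a_switch1 = alpha;            // C -> B
  } else if (state == 1) {
    a_switch1 = beta;             // B -> C
    a_switch2 = lambda;           // B -> A
  } else {
    a_switch1 = nu;               // A -> B
    a_tx = K;                     // A -> A + mRNA
  }
  double a_decay = mrna * delta;
  double a0 = a_switch1 + a_switch2 + a_tx + a_decay;
  if (a0 <= 0.0) return -1.0;

  double dt = exp_rand() / a0;
  double u = unif_rand() * a0;
  if (u < a_switch1) {
    state = (state == 0) ? 1 : (state == 1 ? 0 : 1);
  } else if (u < a_switch1 + a_switch2) {
    state = 2;                    // B -> A
  } else if (u < a_switch1 + a_switch2 + a_tx) {
    mrna += 1;
  } else {
    mrna -= 1;
  }
  return dt;
}

// [[Rcpp::export]]
List ssa_trajectory_cpp(double alpha, double beta, double lambda, double nu,
                        double K, double delta, double t_end,
                        int state0, int mrna0, double max_events) {
  RNGScope scope;
  std::vector<double> times;
  std::vector<int> states, mrnas;
  times.push_back(0.0); states.push_back(state0); mrnas.push_back(mrna0);

  double t = 0.0;
  int state = state0, mrna = mrna0;
  double n_events = 0.0;
  while (true) {
    int s_next = state, m_next = mrna;
    double dt = ssa_step(s_next, m_next, alpha, beta, lambda, nu, K, delta);
    if (dt < 0.0) break;                 // absorbing: no further events
    if (t + dt > t_end) break;           // first event past the horizon
    t += dt; state = s_next; mrna = m_next;
    times.push_back(t); states.push_back(state); mrnas.push_back(mrna);
    if (++n_events >= max_events)
      stop("event cap reached (%.0f events before t_end)", max_events);
  }
  return List::create(_["times"] = wrap(times), _["states"] = wrap(states),
                      _["mrna"] = wrap(mrnas));
}

// Independent single-cell snapshots: each cell runs from its own initial
// promoter state (mRNA 0) to t_relax; only the terminal state is kept.
// [[Rcpp::export]]
List ssa_population_cpp(double alpha, double beta, double lambda, double nu,
                        double K, double delta, double t_relax,
                        IntegerVector init_states, double max_events) {
  RNGScope scope;
  int n_cells = init_states.size();
  IntegerVector counts(n_cells), final_states(n_cells);
  for (int i = 0; i < n_cells; ++i) {
    double t = 0.0, n_events = 0.0;
    int state = init_states[i], mrna = 0;
    while (true) {
      int s_next = state, m_next = mrna;
      double dt = ssa_step(s_next, m_next, alpha, beta, lambda, nu, K, delta);
      if (dt < 0.0) break;
      if (t + dt > t_relax) break;
      t += dt; state = s_next; mrna = m_next;
      if (++n_events >= max_events)
        stop("event cap reached in cell %d", i + 1);
    }
    counts[i] = mrna; final_states[i] = state;
  }
  return List::create(_["counts"] = counts, _["states"] = final_states);
}
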