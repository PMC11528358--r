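#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time stochastic SIS core.
//
// P(i, j) is the per-step probability that infected j transmits to
// susceptible i (already includes the age susceptibility increment and the
// edge-weight exponent, clamped to [0, 1]).  Transmission is evaluated
// synchronously against the step-start infected set: each susceptible runs
// one independent Bernoulli trial per infected neighbour.  Durations are
// decremented after transmission, so an individual recovering at step t
// cannot transmit at step t + 1.  dr > 0 inserts a dormant recovered period
// before return to S; the analysis default is dr = 0 (pure SIS).
//
// Uses R's RNG (unif_rand), so results are reproducible under set.seed().

// [[Rcpp::export]]
List sis_run_cpp(NumericMatrix P, IntegerVector duration,
                 NumericVector step_cost, IntegerVector init_infected,
                 int n_steps, int dr) {
  const int n = P.nrow();
  if (P.ncol() != n) stop("P must be square");
  if (duration.size() != n || step_cost.size() != n)
    stop("duration/step_cost length must match network size");
  if (init_infected.size() < 1) stop("at least one initially infected individual required");

  std::vector<int> inf_left(n, 0), rec_left(n, 0);
  std::vector<int> n_inf(n, 0), inf_steps(n, 0);
  std::vector<double> cost(n, 0.0);
  NumericVector prevalence(n_steps);

  // per-infection event log
  std::vector<int> ev_id, ev_start, ev_dur, ev_served;
  std::vector<int> open_event(n, -1);

  for (int k = 0; k < init_infected.size(); ++k) {
    int i = init_infected[k] - 1;
    if (i < 0 || i >= n) stop("initial infected index out of range");
    if (inf_left[i] > 0) continue;  // duplicate seed
    inf_left[i] = duration[i];
    n_inf[i] += 1;
    ev_id.push_back(i + 1); ev_start.push_back(0);
    ev_dur.push_back(duration[i]); ev_served.push_back(0);
    open_event[i] = (int) ev_id.size() - 1;
  }

  std::vector<int> infected, susceptible, newly;
  infected.reserve(n); susceptible.reserve(n); newly.reserve(n);

  for (int t = 1; t <= n_steps; ++t) {
    infected.clear(); susceptible.clear(); newly.clear();
    for (int i = 0; i < n; ++i) {
      if (inf_left[i] > 0) infected.push_back(i);
      else if (rec_left[i] == 0) susceptible.push_back(i);
    }

    // transmission trials against the step-start infected set
    for (size_t s = 0; s < susceptible.size(); ++s) {
      const int i = susceptible[s];
      bool hit = false;
      for (size_t q = 0; q < infected.size(); ++q) {
        const double p = P(i, infected[q]);
        if (p > 0.0 && unif_rand() < p) hit = true;
      }
      if (hit) newly.push_back(i);
    }

    // cost accrual and duration countdown for the step-start infected
    for (size_t q = 0; q < infected.size(); ++q) {
      const int j = infected[q];
      cost[j] += step_cost[j];
      inf_steps[j] += 1;
      ev_served[open_event[j]] += 1;
      if (--inf_left[j] == 0) {
        open_event[j] = -1;
        if (dr > 0) rec_left[j] = dr;
      }
    }

    // recovered-period countdown (individuals dormant at step start)
    for (int i = 0; i < n; ++i)
      if (rec_left[i] > 0 && inf_left[i] == 0) rec_left[i] -= 1;

    // new infections take effect at the end of the step
    for (size_t s = 0; s < newly.size(); ++s) {
      const int i = newly[s];
      inf_left[i] = duration[i];
      n_inf[i] += 1;
      ev_id.push_back(i + 1); ev_start.push_back(t);
      ev_dur.push_back(duration[i]); ev_served.push_back(0);
      open_event[i] = (int) ev_id.size() - 1;
    }

    int cur = 0;
    for (int i = 0; i < n; ++i) if (inf_left[i] > 0) ++cur;
    prevalence[t - 1] = (double) cur / n;
  }

  return List::create(
    _["cost"] = NumericVector(cost.begin(), cost.end()),
    _["n_infections"] = IntegerVector(n_inf.begin(), n_inf.end()),
    _["infected_steps"] = IntegerVector(inf_steps.begin(), inf_steps.end()),
    _["prevalence"] = prevalence,
    _["events"] = DataFrame::create(
      _["individual"] = IntegerVector(ev_id.begin(), ev_id.end()),
      _["start_step"] = IntegerVector(ev_start.begin(), ev_start.end()),
      _["duration_assigned"] = IntegerVector(ev_dur.begin(), ev_dur.end()),
      _["steps_served"] = IntegerVector(ev_served.begin(), ev_served.end())));
}
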