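#include <Rcpp.h>
using namespace Rcpp;

// Ornstein-Uhlenbeck leaky accumulator run over one stimulus block.
//
// Per sample: X <- (1 + lambda) * X + g * M_t + eps_t, eps_t ~ N(0, sigma^2).
// When |X| >= theta a response is emitted at that sample (direction =
// sign(X)) and X is reset to 0 from the next sample onward.
//
// Closed loop: a press that claims a still-running response period
// terminates it, and the remaining samples up to the period's nominal end
// are re-drawn from the baseline noise distribution (one Gaussian value per
// piecewise-constant interval, clamped to [-1, 1]), exactly as the task
// returns the stimulus to baseline after a correct/incorrect response.
// Period attribution replicates the scoring rule (including the tolerance
// window after the nominal end) so that scoring the emitted presses against
// the realised block reproduces the same outcomes.
//
// Periods are described by parallel vectors (onset_s, end_s = nominal end
// clipped to block end, is_response). iv_of_samp maps each sample to its
// noise interval (1-based); uses R's RNG (seed with set.seed in R).
// [[Rcpp::export]]
List ou_simulate_cpp(NumericVector coherence,
                     IntegerVector iv_of_samp,
                     NumericVector period_onset_s,
                     NumericVector period_end_s,
                     LogicalVector period_is_response,
                     double lambda, double theta, double g, double sigma,
                     double dt, double tolerance_s, double sd_baseline,
                     bool closed_loop, bool keep_trajectory) {
  int n = coherence.size();
  int n_per = period_onset_s.size();
  NumericVector coh = clone(coherence);
  std::vector<bool> claimed(n_per, false);
  std::vector<double> actual_end(period_end_s.begin(), period_end_s.end());

  std::vector<int> resp_sample;
  std::vector<double> resp_time;
  std::vector<int> resp_dir;
  NumericVector traj(keep_trajectory ? n : 0);

  double X = 0.0;
  for (int s = 0; s < n; ++s) {
    double eps = (sigma > 0.0) ? R::rnorm(0.0, sigma) : 0.0;
    X = (1.0 + lambda) * X + g * coh[s] + eps;
    if (keep_trajectory) traj[s] = X;
    if (std::fabs(X) >= theta * (1.0 - 1e-12)) {
      double t = s * dt;
      int dir = (X > 0) ? 1 : -1;
      resp_sample.push_back(s + 1);
      resp_time.push_back(t);
      resp_dir.push_back(dir);
      if (closed_loop) {
        // attribution mirrors score_responses(): running unclaimed period
        // first, then the tolerance window after an unclaimed nominal end
        int j = -1;
        for (int p = 0; p < n_per; ++p) {
          if (period_is_response[p] && !claimed[p] &&
              period_onset_s[p] <= t && t < actual_end[p]) { j = p; break; }
        }
        if (j < 0) {
          for (int p = 0; p < n_per; ++p) {
            if (period_is_response[p] && !claimed[p] &&
                t >= period_end_s[p] && t < period_end_s[p] + tolerance_s) {
              j = p; break;
            }
          }
        }
        if (j >= 0) {
          claimed[j] = true;
          if (t < actual_end[j]) {
            actual_end[j] = t;
            // stimulus returns to baseline for the rest of the period
            int end_samp = (int)std::lround(period_end_s[j] / dt);
            if (end_samp > n) end_samp = n;
            double v = 0.0;
            int cur_iv = -1;
            for (int u = s + 1; u < end_samp; ++u) {
              if (iv_of_samp[u] != cur_iv) {
                cur_iv = iv_of_samp[u];
                v = R::rnorm(0.0, sd_baseline);
                if (v > 1.0) v = 1.0;
                if (v < -1.0) v = -1.0;
              }
              coh[u] = v;
            }
          }
        }
      }
      X = 0.0;  // reset applies from the next sample
    }
  }

  return List::create(
    _["resp_sample"] = wrap(resp_sample),
    _["resp_time"] = wrap(resp_time),
    _["resp_dir"] = wrap(resp_dir),
    _["coherence"] = coh,
    _["trajectory"] = traj);
}
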