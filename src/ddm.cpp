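#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama first-passage simulation of the unbiased Wiener diffusion.
// method 0 = plain Euler; method 1 = Euler with the diffusion-bridge crossing
// correction (accounts for within-step boundary crossings, removing the
// O(sqrt(dt)) discretisation bias of the plain scheme).
// Trials that fail to absorb within max_time are resampled; the count of
// resampled attempts is returned so callers can log it.
// [[Rcpp::export]]
List ddm_sim_cpp(int n, double v, double a, double ter, double s,
                 double dt, double start_frac, double max_time, int method) {
  if (n < 1) stop("n must be >= 1");
  if (a <= 0 || s <= 0 || dt <= 0) stop("a, s and dt must be positive");
  NumericVector rt(n), dtime(n);
  IntegerVector correct(n);
  int resamples = 0;
  const double sq = s * std::sqrt(dt);
  const double s2dt = s * s * dt;
  const int max_steps = (int)std::ceil(max_time / dt);
  for (int i = 0; i < n; ++i) {
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    bool done = false;
    int hit = 0;
    int step = 0;
    while (!done) {
      double x = start_frac * a;
      step = 0;
      while (step < max_steps) {
        double x0 = x;
        x += v * dt + sq * norm_rand();
        ++step;
        if (x >= a) { hit = 1; done = true; break; }
        if (x <= 0.0) { hit = 0; done = true; break; }
        if (method == 1) {
          // bridge probability that the path crossed a boundary inside the step
          double p_up = std::exp(-2.0 * (a - x0) * (a - x) / s2dt);
          if (unif_rand() < p_up) { hit = 1; done = true; break; }
          double p_dn = std::exp(-2.0 * x0 * x / s2dt);
          if (unif_rand() < p_dn) { hit = 0; done = true; break; }
        }
      }
      if (!done) ++resamples;  // timeout: redraw the whole trial
    }
    correct[i] = hit;
    dtime[i] = step * dt;
    rt[i] = dtime[i] + ter;
  }
  return List::create(_["rt"] = rt, _["correct"] = correct,
                      _["decision_time"] = dtime,
                      _["n_resampled"] = resamples);
}
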