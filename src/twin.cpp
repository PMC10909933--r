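#include <Rcpp.h>
using namespace Rcpp;

// Delayed Kuramoto network, Euler-Maruyama.
//
//   dtheta_i = [omega_i + (K/N) sum_j c_ij sin(theta_j(t - tau_ij) - theta_i)] dt
//              + sqrt(dt) * d_t * dW
//
// Delays are given in integer steps; a ring buffer of length max(tau)+1 holds
// the history.  History before t = 0 is backfilled by backward extrapolation
// at the intrinsic frequency: theta_i(-m dt) = theta0_i - omega_i * m * dt.
//
// Optional extras (used by the synthetic-EEG source model and the TMS reset):
//  * reset_step[i] >= 0 forces theta_i to reset_value at that step,
//  * extra_idx + k_extra_t adds a decaying all-to-all coupling among a node
//    subset (holds post-reset coherence with a controlled time constant),
//  * d_t is a per-step noise scale (scalar noise = constant vector).
//
// Noise is drawn from R's RNG (norm_rand), so set.seed() in R makes runs
// bit-reproducible and two calls with the same seed share the noise stream.
// [[Rcpp::export]]
List twin_integrate_cpp(NumericMatrix C, IntegerMatrix tau_steps,
                        NumericVector omega, double K, NumericVector d_t,
                        double dt, int n_steps, NumericVector theta0,
                        IntegerVector reset_step, double reset_value,
                        IntegerVector extra_idx, NumericVector k_extra_t,
                        int store_every) {
  const int n = C.nrow();
  const double TWOPI = 2.0 * M_PI;
  int max_tau = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (tau_steps(i, j) > max_tau) max_tau = tau_steps(i, j);
  const int H = max_tau + 1;

  // ring buffers, column = t mod H; sin/cos of the history are cached so
  // the O(n^2) coupling loop is pure multiply-add:
  //   sin(th_j(t-tau) - th_i) = sin th_j cos th_i - cos th_j sin th_i
  NumericMatrix hist(n, H), hist_s(n, H), hist_c(n, H);
  std::vector<double> theta(n);
  for (int i = 0; i < n; ++i) theta[i] = theta0[i];
  // backfill: the slot that step t reads for delay tau is (t - 1 - tau) mod H
  for (int m = 0; m < H; ++m) {
    int col = ((-m) % H + H) % H;
    for (int i = 0; i < n; ++i) {
      double v = theta0[i] - omega[i] * m * dt;
      hist(i, col) = v;
      hist_s(i, col) = std::sin(v);
      hist_c(i, col) = std::cos(v);
    }
  }

  const int n_store = n_steps / store_every;
  NumericMatrix out(n, n_store + 1);
  for (int i = 0; i < n; ++i)
    out(i, 0) = std::atan2(std::sin(theta[i]), std::cos(theta[i]));

  const int n_extra = extra_idx.size();
  const bool has_extra = n_extra > 0 && k_extra_t.size() > 0;
  const double sqdt = std::sqrt(dt);
  std::vector<double> dtheta(n);

  GetRNGstate();
  int store_col = 1;
  const double* Sp = REAL(hist_s);
  const double* Cp = REAL(hist_c);
  const double* Wp = REAL(C);
  const int* Tp = INTEGER(tau_steps);
  std::vector<double> sin_i(n), cos_i(n);
  for (int t = 1; t <= n_steps; ++t) {
    const double dnow = d_t[(t - 1) % d_t.size()];
    const int tcur = (t - 1) % H;
    for (int i = 0; i < n; ++i) {
      sin_i[i] = std::sin(theta[i]);
      cos_i[i] = std::cos(theta[i]);
    }
    for (int i = 0; i < n; ++i) {
      double acc_s = 0.0, acc_c = 0.0;   // sum c_ij sin/cos th_j(t-tau)
      const double* wrow = Wp + (R_xlen_t)i;      // column-major: stride n
      const int* trow = Tp + (R_xlen_t)i;
      for (int j = 0; j < n; ++j) {
        const double cij = wrow[(R_xlen_t)j * n];
        int slot = tcur - trow[(R_xlen_t)j * n];
        if (slot < 0) slot += H;                  // tau <= H-1
        acc_s += cij * Sp[(R_xlen_t)slot * n + j];
        acc_c += cij * Cp[(R_xlen_t)slot * n + j];
      }
      const double coup = acc_s * cos_i[i] - acc_c * sin_i[i];
      dtheta[i] = omega[i] + (K / n) * coup;
    }
    if (has_extra) {
      const double ke = k_extra_t[(t - 1) % k_extra_t.size()];
      if (ke != 0.0) {
        for (int a = 0; a < n_extra; ++a) {
          const int i = extra_idx[a];
          double coup = 0.0;
          for (int b = 0; b < n_extra; ++b) {
            const int j = extra_idx[b];
            coup += std::sin(theta[j] - theta[i]);
          }
          dtheta[i] += (ke / n_extra) * coup;
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      double v = theta[i] + dt * dtheta[i] + sqdt * dnow * norm_rand();
      if (reset_step[i] == t) v = reset_value;
      // wrap to (-pi, pi]; ceil-based to avoid fmod (glibc version skew)
      v -= TWOPI * std::ceil((v - M_PI) / TWOPI);
      theta[i] = v;
      const int col = t % H;
      hist(i, col) = v;
      hist_s(i, col) = std::sin(v);
      hist_c(i, col) = std::cos(v);
    }
    if (t % store_every == 0 && store_col <= n_store) {
      for (int i = 0; i < n; ++i) out(i, store_col) = theta[i];
      ++store_col;
    }
    if (t % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();

  for (int i = 0; i < n * (n_store + 1); ++i) {
    if (!R_finite(out[i]))
      stop("non-finite phase produced at storage index %d; check dt/K/noise", i);
  }
  return List::create(_["theta"] = out, _["max_tau_steps"] = max_tau);
}

// LZ76 complexity: number of phrases in the exhaustive-history parsing.
// A new phrase is the shortest extension of the current position that is not
// a substring of everything seen so far (copy-extension allowed, i.e. the
// search window ends one symbol before the end of the candidate phrase).
// The final, possibly still-reproducible, suffix counts as one phrase.
// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  const int n = s.size();
  if (n == 0) stop("empty sequence");
  int c = 1;     // phrase count; first symbol is always one phrase
  int p = 1;     // start of current phrase (0-based)
  while (p < n) {
    int l = 1;   // candidate phrase length
    // grow l while s[p..p+l-1] occurs in s[0..p+l-2]; a match ending at
    // p+l-2 must start at or before p-1, so start < p is the exact window
    while (p + l <= n) {
      bool found = false;
      for (int start = 0; start < p; ++start) {
        bool ok = true;
        for (int m = 0; m < l; ++m) {
          if (s[start + m] != s[p + m]) { ok = false; break; }
        }
        if (ok) { found = true; break; }
      }
      if (!found) break;
      ++l;
    }
    if (p + l > n) { ++c; break; }  // exhausted while reproducible
    ++c;
    p += l;
  }
  return c;
}
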