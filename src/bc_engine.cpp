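#include <Rcpp.h>
using namespace Rcpp;

// Stepping kernel for the bounded-confidence model with one active noise
// type. All randomness comes from R's global RNG stream so that a run is
// fully determined by set.seed() on the R side, and so that the pure-R
// simulation_step() can reproduce the stream draw-for-draw.

static const int MAX_ATTEMPTS = 1000000;

// noise_type codes: 0 none, 1 ambiguity, 2 selectivity, 3 adaptation,
//                   4 exogenous
// dist codes:       0 gaussian, 1 bounded_uniform
// regime codes:     0 one_to_one, 1 many_to_one, 2 one_to_many

static inline double draw_dev(double nu, int dist) {
  if (dist == 0) return norm_rand() * nu;
  return -nu + 2.0 * nu * unif_rand();
}

// additive deviation around `anchor`, resampled (never clipped) until the
// result lies in the opinion space [0,1]
static inline double trunc_add(double anchor, double nu, int dist) {
  for (int a = 0; a < MAX_ATTEMPTS; ++a) {
    double v = anchor + draw_dev(nu, dist);
    if (v >= 0.0 && v <= 1.0) return v;
  }
  Rcpp::stop("truncated-noise resampling exceeded the attempt cap");
  return NA_REAL; // unreachable
}

// one receiver update in a dyadic exchange, from the sender's pre-step
// opinion; draws whatever noise the active type requires
static inline double dyad_update(double xr, double xs, double mu, double eps,
                                 int noise_type, double nu, int dist) {
  switch (noise_type) {
  case 1: { // ambiguity: noisy message, truncated to [0,1]
    double msg = (nu > 0.0) ? trunc_add(xs, nu, dist) : xs;
    if (std::fabs(msg - xr) <= eps) return xr + mu * (msg - xr);
    return xr;
  }
  case 2: { // selectivity: noisy confidence bound
    double thr = eps + ((nu > 0.0) ? draw_dev(nu, dist) : 0.0);
    if (std::fabs(xs - xr) <= thr) return xr + mu * (xs - xr);
    return xr;
  }
  case 3: { // adaptation: post-update shift, truncated to [0,1]
    if (std::fabs(xs - xr) <= eps) {
      double base = xr + mu * (xs - xr);
      return (nu > 0.0) ? trunc_add(base, nu, dist) : base;
    }
    return xr;
  }
  default: { // none / exogenous (jumps handled outside the dyad)
    if (std::fabs(xs - xr) <= eps) return xr + mu * (xs - xr);
    return xr;
  }
  }
}

// [[Rcpp::export]]
List bc_run_cpp(NumericVector init, int steps, double mu, double eps,
                int noise_type, double nu, int dist, int regime, int k,
                IntegerMatrix edges, IntegerVector record_steps) {
  int n = init.size();
  if (n < 2) stop("need at least two agents");
  NumericVector x = clone(init);
  int n_rec = record_steps.size();
  NumericMatrix snaps(n_rec, n);
  IntegerVector counts(n);
  std::vector<int> idx(n);
  std::vector<int> oth(n - 1);
  int rec_ptr = 0;
  if (rec_ptr < n_rec && record_steps[rec_ptr] == 0) {
    snaps(rec_ptr, _) = x;
    ++rec_ptr;
  }
  int m_edges = edges.nrow();
  bool exo = (noise_type == 4 && nu > 0.0);

  for (int step = 1; step <= steps; ++step) {
    if (step % 16384 == 0) Rcpp::checkUserInterrupt();

    if (regime == 0) {
      // dyadic exchange: both members update symmetrically from each
      // other's pre-step opinions, independent noise per direction
      int i, j;
      if (m_edges > 0) {
        int e = (int)(unif_rand() * m_edges);
        i = edges(e, 0);
        j = edges(e, 1);
      } else {
        i = (int)(unif_rand() * n);
        do {
          j = (int)(unif_rand() * n);
        } while (j == i);
      }
      double xi = x[i], xj = x[j];
      double ni = dyad_update(xi, xj, mu, eps, noise_type, nu, dist);
      double nj = dyad_update(xj, xi, mu, eps, noise_type, nu, dist);
      x[i] = ni;
      x[j] = nj;
      counts[i]++;
      counts[j]++;
    } else if (regime == 1) {
      // many-to-one: one receiver hears k senders, updates once toward the
      // mean of the accepted messages; senders do not update
      int r = (int)(unif_rand() * n);
      int nn = n - 1;
      for (int t = 0; t < nn; ++t) oth[t] = (t < r) ? t : t + 1;
      for (int l = 0; l < k; ++l) {
        int rr = l + (int)(unif_rand() * (nn - l));
        std::swap(oth[l], oth[rr]);
      }
      double xr = x[r];
      long double sum = 0.0; // match R's long-double sum() accumulation
      int cnt = 0;
      for (int l = 0; l < k; ++l) {
        int s = oth[l];
        counts[s]++;
        double xs = x[s];
        if (noise_type == 1) {
          double msg = (nu > 0.0) ? trunc_add(xs, nu, dist) : xs;
          if (std::fabs(msg - xr) <= eps) { sum += msg; cnt++; }
        } else if (noise_type == 2) {
          double thr = eps + ((nu > 0.0) ? draw_dev(nu, dist) : 0.0);
          if (std::fabs(xs - xr) <= thr) { sum += xs; cnt++; }
        } else {
          if (std::fabs(xs - xr) <= eps) { sum += xs; cnt++; }
        }
      }
      counts[r]++;
      if (cnt > 0) {
        double base = xr + mu * ((double)sum / cnt - xr);
        if (noise_type == 3 && nu > 0.0) base = trunc_add(base, nu, dist);
        x[r] = base;
      }
    } else {
      // one-to-many: one sender broadcasts to k receivers; under ambiguity
      // the broadcast is a single noisy signal shared by every receiver
      int s = (int)(unif_rand() * n);
      int nn = n - 1;
      for (int t = 0; t < nn; ++t) oth[t] = (t < s) ? t : t + 1;
      for (int l = 0; l < k; ++l) {
        int rr = l + (int)(unif_rand() * (nn - l));
        std::swap(oth[l], oth[rr]);
      }
      double xs = x[s];
      double msg = xs;
      if (noise_type == 1 && nu > 0.0) msg = trunc_add(xs, nu, dist);
      counts[s]++;
      for (int l = 0; l < k; ++l) {
        int r = oth[l];
        counts[r]++;
        double xr = x[r];
        if (noise_type == 1) {
          if (std::fabs(msg - xr) <= eps) x[r] = xr + mu * (msg - xr);
        } else if (noise_type == 2) {
          double thr = eps + ((nu > 0.0) ? draw_dev(nu, dist) : 0.0);
          if (std::fabs(xs - xr) <= thr) x[r] = xr + mu * (xs - xr);
        } else if (noise_type == 3) {
          if (std::fabs(xs - xr) <= eps) {
            double base = xr + mu * (xs - xr);
            if (nu > 0.0) base = trunc_add(base, nu, dist);
            x[r] = base;
          }
        } else {
          if (std::fabs(xs - xr) <= eps) x[r] = xr + mu * (xs - xr);
        }
      }
    }

    // exogenous jumps: every agent independently, with probability omega=nu,
    // jumps by a truncated deviation -- separate from the social exchange
    if (exo) {
      int nj = (int)R::rbinom((double)n, nu);
      if (nj > 0) {
        for (int t = 0; t < n; ++t) idx[t] = t;
        for (int l = 0; l < nj; ++l) {
          int rr = l + (int)(unif_rand() * (n - l));
          std::swap(idx[l], idx[rr]);
        }
        for (int l = 0; l < nj; ++l)
          x[idx[l]] = trunc_add(x[idx[l]], nu, dist);
      }
    }

    if (rec_ptr < n_rec && record_steps[rec_ptr] == step) {
      snaps(rec_ptr, _) = x;
      ++rec_ptr;
    }
  }

  return List::create(_["snapshots"] = snaps, _["interactions"] = counts);
}
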