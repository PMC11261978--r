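#include <Rcpp.h>
using namespace Rcpp;

// ---- helpers -------------------------------------------------------------

// Invert the 3-D mean-cosine relation A3(kappa) = coth(kappa) - 1/kappa = a
// (von Mises-Fisher concentration for a given mean reorientation cosine).
static double vmf_kappa3(double a) {
  if (a < 1e-12) return 0.0;
  // Banerjee approximation, then Newton polish
  double k = a * (3.0 - a * a) / (1.0 - a * a);
  for (int i = 0; i < 50; ++i) {
    double c = 1.0 / std::tanh(k);
    double f = c - 1.0 / k - a;
    double fp = 1.0 / (k * k) - (c * c - 1.0);
    double step = f / fp;
    if (!std::isfinite(step)) break;
    k -= step;
    if (k <= 0) k = 1e-8;
    if (std::fabs(step) < 1e-12 * std::max(1.0, k)) break;
  }
  return k;
}

// Sample cos(theta) from the 3-D vMF angular density with concentration kappa.
static double vmf_cos3(double kappa) {
  if (kappa < 1e-10) return 2.0 * unif_rand() - 1.0;
  double u = unif_rand();
  // inverse CDF of w ~ exp(kappa*w) on [-1,1]
  return 1.0 + std::log(u + (1.0 - u) * std::exp(-2.0 * kappa)) / kappa;
}

struct Dir3 { double x, y, z; };

static void normalize3(Dir3 &e) {
  double n = std::sqrt(e.x * e.x + e.y * e.y + e.z * e.z);
  e.x /= n; e.y /= n; e.z /= n;
}

// random unit vector perpendicular to e
static Dir3 perp_unit(const Dir3 &e) {
  Dir3 v;
  do {
    v.x = norm_rand(); v.y = norm_rand(); v.z = norm_rand();
    double d = v.x * e.x + v.y * e.y + v.z * e.z;
    v.x -= d * e.x; v.y -= d * e.y; v.z -= d * e.z;
  } while (v.x * v.x + v.y * v.y + v.z * v.z < 1e-12);
  normalize3(v);
  return v;
}

// reorient e after a tumble: new direction with <cos> = alpha about old e
static Dir3 tumble_reorient(const Dir3 &e, double alpha) {
  double w;
  if (alpha >= 0) {
    w = vmf_cos3(vmf_kappa3(alpha));
  } else {
    w = -vmf_cos3(vmf_kappa3(-alpha));
  }
  Dir3 v = perp_unit(e);
  double s = std::sqrt(std::max(0.0, 1.0 - w * w));
  Dir3 out;
  out.x = w * e.x + s * v.x;
  out.y = w * e.y + s * v.y;
  out.z = w * e.z + s * v.z;
  normalize3(out);
  return out;
}

// rotational diffusion during a run, one step of size dt
static void rot_diffuse3(Dir3 &e, double Dr, double dt) {
  if (Dr <= 0) return;
  double sd = std::sqrt(2.0 * Dr * dt);
  Dir3 v = perp_unit(e);
  Dir3 w;  // second perpendicular = e x v
  w.x = e.y * v.z - e.z * v.y;
  w.y = e.z * v.x - e.x * v.z;
  w.z = e.x * v.y - e.y * v.x;
  double a = sd * norm_rand(), b = sd * norm_rand();
  e.x += a * v.x + b * w.x;
  e.y += a * v.y + b * w.y;
  e.z += a * v.z + b * w.z;
  normalize3(e);
}

// 2-D: wrapped reorientation with <cos> = alpha via von Mises (Best-Fisher)
static double vm_angle2(double alpha) {
  if (std::fabs(alpha) < 1e-10) return M_PI * (2.0 * unif_rand() - 1.0);
  double a = std::fabs(alpha);
  // invert I1/I0(kappa) = a (crude init + Newton on log scale not needed:
  // use the standard approximation, adequate for sampling)
  double k = (2.0 * a - a * a * a) / (1.0 - a * a);
  double tau = 1.0 + std::sqrt(1.0 + 4.0 * k * k);
  double rho = (tau - std::sqrt(2.0 * tau)) / (2.0 * k);
  double r = (1.0 + rho * rho) / (2.0 * rho);
  double theta;
  for (;;) {
    double u1 = unif_rand(), u2 = unif_rand();
    double z = std::cos(M_PI * u1);
    double f = (1.0 + r * z) / (r + z);
    double c = k * (r - f);
    if (c * (2.0 - c) - u2 > 0 || std::log(c / u2) + 1.0 - c >= 0) {
      double u3 = unif_rand();
      theta = (u3 < 0.5 ? -1.0 : 1.0) * std::acos(f);
      break;
    }
  }
  if (alpha < 0) theta = M_PI - theta;
  return theta;
}

// ---- run-and-tumble trajectory ------------------------------------------

// [[Rcpp::export]]
List cpp_run_tumble(double duration, double dt, double speed,
                    double run_rate, double tumble_duration_mean,
                    double persistence, double rot_diffusion, int dimensions) {
  int n = (int)std::floor(duration / dt + 0.5);
  NumericVector vx(n), x(n);
  IntegerVector running(n);
  if (n == 0) {
    return List::create(_["vx"] = vx, _["x"] = x, _["running"] = running);
  }
  bool in_run = true;
  double t_remaining = tumble_duration_mean > 0 ? 0.0 : 0.0;
  double pos = 0.0;
  if (dimensions == 3) {
    Dir3 e;
    e.x = norm_rand(); e.y = norm_rand(); e.z = norm_rand();
    normalize3(e);
    for (int i = 0; i < n; ++i) {
      if (in_run) {
        vx[i] = speed * e.x;
        running[i] = 1;
        pos += speed * e.x * dt;
        x[i] = pos;
        rot_diffuse3(e, rot_diffusion, dt);
        if (unif_rand() < run_rate * dt) {
          if (tumble_duration_mean > 0) {
            in_run = false;
            t_remaining = exp_rand() * tumble_duration_mean;
          } else {
            e = tumble_reorient(e, persistence);
          }
        }
      } else {
        vx[i] = 0.0;
        running[i] = 0;
        x[i] = pos;
        t_remaining -= dt;
        if (t_remaining <= 0) {
          in_run = true;
          e = tumble_reorient(e, persistence);
        }
      }
    }
  } else {  // 2-D
    double th = M_PI * (2.0 * unif_rand() - 1.0);
    for (int i = 0; i < n; ++i) {
      if (in_run) {
        vx[i] = speed * std::cos(th);
        running[i] = 1;
        pos += vx[i] * dt;
        x[i] = pos;
        if (rot_diffusion > 0) th += std::sqrt(2.0 * rot_diffusion * dt) * norm_rand();
        if (unif_rand() < run_rate * dt) {
          if (tumble_duration_mean > 0) {
            in_run = false;
            t_remaining = exp_rand() * tumble_duration_mean;
          } else {
            th += vm_angle2(persistence);
          }
        }
      } else {
        vx[i] = 0.0;
        running[i] = 0;
        x[i] = pos;
        t_remaining -= dt;
        if (t_remaining <= 0) {
          in_run = true;
          th += vm_angle2(persistence);
        }
      }
    }
  }
  return List::create(_["vx"] = vx, _["x"] = x, _["running"] = running);
}

// ---- kinase dynamics driven by an arrival-count series -------------------

// Integrates a(t) = a0 - int Kr(t-t') (r(t')-r0) dt' + n(t) at the count grid.
// tau1 == 0 uses the exact delta-lobe form; tau1 >= 2*dt uses a fast
// exponential filter state. n(t) is an exact-discretization OU process.
// [[Rcpp::export]]
NumericVector cpp_kinase_trace(NumericVector counts, double dt, double r0,
                               double Gr, double tau1, double tau2,
                               double Dn, double taun, double a0) {
  int n = counts.size();
  NumericVector a(n);
  double F2 = 0.0, F1 = 0.0;  // slow and fast kernel lobes
  double phin = std::exp(-dt / taun);
  double sdn = std::sqrt(Dn * taun * (1.0 - phin * phin));
  double noise = std::sqrt(Dn * taun) * norm_rand();
  double d2 = std::exp(-dt / tau2);
  double d1 = tau1 > 0 ? std::exp(-dt / tau1) : 0.0;
  for (int i = 0; i < n; ++i) {
    double dN = counts[i] - r0 * dt;  // arrival excess in this bin
    double fast;
    if (tau1 > 0) {
      F1 = d1 * F1 + dN;
      fast = F1 / tau1;
    } else {
      fast = dN / dt;
    }
    a[i] = a0 - Gr * (fast - F2 / tau2) + noise;
    F2 = d2 * F2 + dN;
    noise = phin * noise + sdn * norm_rand();
  }
  return a;
}

// ---- OU + white measurement noise marginal log-likelihood ----------------

// Scalar Kalman filter for y_k = x_k + e_k, x_{k+1} = phi x_k + w_k,
// Var w = q, Var e = r, x stationary at start. Used by fit_noise_params.
// [[Rcpp::export]]
double cpp_ou_loglik(NumericVector y, double phi, double q, double r) {
  int n = y.size();
  double xhat = 0.0;
  double P = q / (1.0 - phi * phi);
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double S = P + r;
    double innov = y[i] - xhat;
    ll += -0.5 * (std::log(2.0 * M_PI * S) + innov * innov / S);
    double K = P / S;
    xhat = xhat + K * innov;
    P = (1.0 - K) * P;
    xhat = phi * xhat;
    P = phi * phi * P + q;
  }
  return ll;
}

// ---- chemotaxis with sensory readouts ------------------------------------

// Agents run-and-tumble in an exponential gradient c(x) = c0 * exp(g x).
// Tumble rate lambda = lambda0 * (1 - beta * xhat), clipped at zero.
// readout: 0 = ideal (extended Kalman filter on molecule arrivals),
//          1 = kinase deviation -(a - a0) / sd_readout,
//          2 = optimal causal estimate from kinase activity (steady-state
//              filter with matrices Phi (3x3), Kg (3), Hm (3) supplied).
// Returns per-cell time-averaged vx and the clipped-rate fraction.
// [[Rcpp::export]]
List cpp_chemotaxis(int n_cells, double duration, double dt, double burnin,
                    double speed, double run_rate, double tumble_duration_mean,
                    double persistence, double rot_diffusion,
                    double c0, double g_um, double kD,
                    double Gr, double tau2, double Dn, double taun, double a0,
                    int readout, double beta, double sd_readout,
                    double tau_v, double sigma_s2,
                    NumericMatrix Phi, NumericVector Kg, NumericVector Hm,
                    NumericVector Bd) {
  NumericVector mean_vx(n_cells);
  double clipped = 0.0, steps_counted = 0.0;
  int n = (int)std::floor(duration / dt + 0.5);
  int nburn = (int)std::floor(burnin / dt + 0.5);
  double phin = std::exp(-dt / taun);
  double sdn = std::sqrt(Dn * taun * (1.0 - phin * phin));
  double d2 = std::exp(-dt / tau2);

  for (int cell = 0; cell < n_cells; ++cell) {
    Dir3 e;
    e.x = norm_rand(); e.y = norm_rand(); e.z = norm_rand();
    normalize3(e);
    bool in_run = true;
    double t_remaining = 0.0, pos = 0.0, sum_vx = 0.0;
    int n_used = 0;
    // kinase state
    double F2 = 0.0, noise = std::sqrt(Dn * taun) * norm_rand();
    // ideal EKF state: (s, L), P 2x2
    double sh = 0.0, Lh = 0.0;
    double P11 = sigma_s2, P12 = 0.0, P22 = 1e-6;
    // kinase-estimate filter state
    double z0 = 0.0, z1 = 0.0, z2 = 0.0;
    double xhat = 0.0;

    for (int i = 0; i < n; ++i) {
      double vx = in_run ? speed * e.x : 0.0;
      pos += vx * dt;
      double rate = kD * c0 * std::exp(g_um * pos);
      double Nk = (rate * dt < 1e8) ? R::rpois(rate * dt) : rate * dt;
      if (readout == 0) {
        // EKF predict
        double f11 = 1.0 - dt / tau_v;
        double sh_p = f11 * sh;
        double Lh_p = Lh + sh * dt;
        double A11 = f11 * f11 * P11 + 2.0 * sigma_s2 / tau_v * dt;
        double A12 = f11 * (P12 + P11 * dt);
        double A22 = P22 + 2.0 * dt * P12 + dt * dt * P11;
        // EKF update with y = Nk/dt, E[y] = kD c0 exp(Lh)
        double rhat = kD * c0 * std::exp(Lh_p);
        double H2 = rhat;
        double Rd = rhat / dt;
        double S = H2 * H2 * A22 + Rd;
        double innov = Nk / dt - rhat;
        double K1 = A12 * H2 / S, K2 = A22 * H2 / S;
        sh = sh_p + K1 * innov;
        Lh = Lh_p + K2 * innov;
        P11 = A11 - K1 * H2 * A12;
        P12 = A12 - K1 * H2 * A22;
        P22 = A22 - K2 * H2 * A22;
        xhat = sh / sd_readout;
      } else {
        double dN = Nk - kD * c0 * dt;
        double a = a0 - Gr * (dN / dt - F2 / tau2) + noise;
        F2 = d2 * F2 + dN;
        noise = phin * noise + sdn * norm_rand();
        if (readout == 1) {
          xhat = -(a - a0) / sd_readout;
        } else {
          // steady-state causal filter on y = a - a0
          double y = a - a0;
          double innov = y - (Hm[0] * z0 + Hm[1] * z1 + Hm[2] * z2);
          double u0 = z0 + Kg[0] * innov;
          double u1 = z1 + Kg[1] * innov;
          double u2 = z2 + Kg[2] * innov;
          z0 = Phi(0, 0) * u0 + Phi(0, 1) * u1 + Phi(0, 2) * u2 + Bd[0] * y;
          z1 = Phi(1, 0) * u0 + Phi(1, 1) * u1 + Phi(1, 2) * u2 + Bd[1] * y;
          z2 = Phi(2, 0) * u0 + Phi(2, 1) * u1 + Phi(2, 2) * u2 + Bd[2] * y;
          xhat = u0 / sd_readout;
        }
      }
      // behavior
      if (in_run) {
        rot_diffuse3(e, rot_diffusion, dt);
        double lam = run_rate * (1.0 - beta * xhat);
        if (i >= nburn) {
          steps_counted += 1.0;
          if (lam < 0) clipped += 1.0;
        }
        if (lam < 0) lam = 0;
        if (unif_rand() < lam * dt) {
          if (tumble_duration_mean > 0) {
            in_run = false;
            t_remaining = exp_rand() * tumble_duration_mean;
          } else {
            e = tumble_reorient(e, persistence);
          }
        }
      } else {
        t_remaining -= dt;
        if (t_remaining <= 0) {
          in_run = true;
          e = tumble_reorient(e, persistence);
        }
      }
      if (i >= nburn) { sum_vx += vx; n_used++; }
    }
    mean_vx[cell] = sum_vx / std::max(1, n_used);
  }
  return List::create(_["mean_vx"] = mean_vx,
                      _["clip_fraction"] = clipped / std::max(1.0, steps_counted));
}
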