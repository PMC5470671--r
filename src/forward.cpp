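// Forward integration of the induced-response state equation
//   dg/dt = exp(logtau) * (A g + C u(t)),  u(t) Gaussian cue bump
// g stacks spectral power (percent change from baseline) over
// sources x frequencies. RK4 at a fixed step; sensitivities to the
// free parameters are propagated alongside the state so model
// inversion gets an analytic Jacobian.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double cue_input(double t, double center, double sigma) {
  double z = (t - center) / sigma;
  return std::exp(-0.5 * z * z);
}

// [[Rcpp::export]]
arma::mat rk4_forward_cpp(const arma::mat& A, const arma::vec& Cvec,
                          double logtau, double t0, double dt, int nsteps,
                          double u_center, double u_sigma,
                          const arma::vec& g0) {
  const double kappa = std::exp(logtau);
  const uword n = A.n_rows;
  mat out(n, nsteps + 1);
  vec g = g0;
  out.col(0) = g;
  for (int k = 0; k < nsteps; ++k) {
    double t = t0 + k * dt;
    vec k1 = kappa * (A * g + Cvec * cue_input(t, u_center, u_sigma));
    vec g2 = g + 0.5 * dt * k1;
    vec k2 = kappa * (A * g2 + Cvec * cue_input(t + 0.5 * dt, u_center, u_sigma));
    vec g3 = g + 0.5 * dt * k2;
    vec k3 = kappa * (A * g3 + Cvec * cue_input(t + 0.5 * dt, u_center, u_sigma));
    vec g4 = g + dt * k3;
    vec k4 = kappa * (A * g4 + Cvec * cue_input(t + dt, u_center, u_sigma));
    g += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    out.col(k + 1) = g;
  }
  return out;
}

// Derivative of the augmented state [g | s_1 ... s_p].
// par_type: 0 = entry of A at (par_row, par_col); 1 = entry of C at
// par_row; 2 = global logtau scaling.
static mat aug_deriv(const mat& G, double t, const mat& A, const vec& Cvec,
                     double kappa, double u_center, double u_sigma,
                     const ivec& par_row, const ivec& par_col,
                     const ivec& par_type) {
  const double u = cue_input(t, u_center, u_sigma);
  mat M = kappa * (A * G);
  M.col(0) += kappa * u * Cvec;
  const uword p = par_row.n_elem;
  for (uword j = 0; j < p; ++j) {
    if (par_type[j] == 0) {
      M(par_row[j], j + 1) += kappa * G(par_col[j], 0);
    } else if (par_type[j] == 1) {
      M(par_row[j], j + 1) += kappa * u;
    } else {
      M.col(j + 1) += M.col(0);
    }
  }
  return M;
}

// [[Rcpp::export]]
Rcpp::List rk4_sensitivities_cpp(const arma::mat& A, const arma::vec& Cvec,
                                 double logtau, double t0, double dt, int nsteps,
                                 double u_center, double u_sigma,
                                 const arma::ivec& par_row, const arma::ivec& par_col,
                                 const arma::ivec& par_type,
                                 const arma::ivec& obs_step) {
  const double kappa = std::exp(logtau);
  const uword n = A.n_rows;
  const uword p = par_row.n_elem;
  const uword nobs = obs_step.n_elem;
  mat G(n, p + 1, fill::zeros); // g(t0) = 0, s(t0) = 0
  mat gobs(n, nobs);
  mat S(n * nobs, p);

  uword oi = 0;
  auto record = [&](int k) {
    while (oi < nobs && obs_step[oi] == k) {
      gobs.col(oi) = G.col(0);
      for (uword j = 0; j < p; ++j)
        S(span(oi * n, oi * n + n - 1), span(j, j)) = G.col(j + 1);
      ++oi;
    }
  };
  record(0);
  for (int k = 0; k < nsteps; ++k) {
    double t = t0 + k * dt;
    mat k1 = aug_deriv(G, t, A, Cvec, kappa, u_center, u_sigma, par_row, par_col, par_type);
    mat k2 = aug_deriv(G + 0.5 * dt * k1, t + 0.5 * dt, A, Cvec, kappa, u_center, u_sigma, par_row, par_col, par_type);
    mat k3 = aug_deriv(G + 0.5 * dt * k2, t + 0.5 * dt, A, Cvec, kappa, u_center, u_sigma, par_row, par_col, par_type);
    mat k4 = aug_deriv(G + dt * k3, t + dt, A, Cvec, kappa, u_center, u_sigma, par_row, par_col, par_type);
    G += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    record(k + 1);
  }
  return Rcpp::List::create(Rcpp::Named("g") = gobs, Rcpp::Named("S") = S);
}
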