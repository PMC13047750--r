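#include <Rcpp.h>
using namespace Rcpp;

// PoP-ORL trial loop shared by the likelihood, the MAP objective and the
// generative simulator. Decks are 1..4 (canonical A..D), choice is 1 = play,
// 0 = pass (timeouts arrive already coded as pass). Outcomes are raw currency;
// EV updates use outcome / outcome_scale, EF updates use sign(outcome).
// Valence gating: outcome >= 0 learns at a_rew, outcome < 0 at a_pun. With
// fictive updating on, unpresented decks receive EF updates toward
// -sign(outcome) / fictive_att at the opposite-valence learning rate.

static inline double sgn(double x) { return (x > 0) - (x < 0); }

// stable log Bernoulli-logistic terms: log p(play) and log p(pass) at value V
static inline void log_probs(double V, double &logp, double &log1mp) {
  if (V > 0) {
    double e = std::exp(-V);
    logp = -std::log1p(e);
    log1mp = -V - std::log1p(e);
  } else {
    double e = std::exp(V);
    logp = V - std::log1p(e);
    log1mp = -std::log1p(e);
  }
}

static double orl_loglik_core(const int *deck, const int *choice,
                              const double *outcome, int n,
                              double a_rew, double a_pun, double beta_f,
                              double beta_b, double outcome_scale,
                              bool fictive, double fictive_att) {
  double EV[4] = {0, 0, 0, 0}, EF[4] = {0, 0, 0, 0};
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int j = deck[t] - 1;
    double V = EV[j] + EF[j] * beta_f + beta_b;
    double logp, log1mp;
    log_probs(V, logp, log1mp);
    ll += (choice[t] == 1) ? logp : log1mp;
    if (choice[t] == 1) {
      double x = outcome[t];
      double lr = (x >= 0) ? a_rew : a_pun;
      EV[j] += lr * (x / outcome_scale - EV[j]);
      EF[j] += lr * (sgn(x) - EF[j]);
      if (fictive) {
        double lrf = (x >= 0) ? a_pun : a_rew;
        double target = -sgn(x) / fictive_att;
        for (int k = 0; k < 4; ++k)
          if (k != j) EF[k] += lrf * (target - EF[k]);
      }
    }
  }
  return ll;
}

// [[Rcpp::export]]
double orl_loglik_cpp(IntegerVector deck, IntegerVector choice,
                      NumericVector outcome, double a_rew, double a_pun,
                      double beta_f, double beta_b, double outcome_scale,
                      bool fictive, double fictive_att) {
  return orl_loglik_core(deck.begin(), choice.begin(), outcome.begin(),
                         deck.size(), a_rew, a_pun, beta_f, beta_b,
                         outcome_scale, fictive, fictive_att);
}

// penalized negative log posterior on the unconstrained scale:
// theta = (probit A_rew, probit A_pun, beta_f, beta_b), independent normal
// priors N(mu, sd) on each coordinate.
static double orl_map_obj_core(const double *theta, const int *deck,
                               const int *choice, const double *outcome, int n,
                               const double *mu, const double *sd,
                               double outcome_scale, bool fictive,
                               double fictive_att) {
  double a_rew = R::pnorm(theta[0], 0.0, 1.0, 1, 0);
  double a_pun = R::pnorm(theta[1], 0.0, 1.0, 1, 0);
  double ll = orl_loglik_core(deck, choice, outcome, n, a_rew, a_pun, theta[2],
                              theta[3], outcome_scale, fictive, fictive_att);
  double lp = 0.0;
  for (int i = 0; i < 4; ++i) lp += R::dnorm(theta[i], mu[i], sd[i], 1);
  return -(ll + lp);
}

// [[Rcpp::export]]
double orl_map_obj_cpp(NumericVector theta, IntegerVector deck,
                       IntegerVector choice, NumericVector outcome,
                       NumericVector mu, NumericVector sd,
                       double outcome_scale, bool fictive,
                       double fictive_att) {
  return orl_map_obj_core(theta.begin(), deck.begin(), choice.begin(),
                          outcome.begin(), deck.size(), mu.begin(), sd.begin(),
                          outcome_scale, fictive, fictive_att);
}

// central-difference gradient of the penalized objective; keeps the whole
// optimizer inner loop out of R.
// [[Rcpp::export]]
NumericVector orl_map_grad_cpp(NumericVector theta, IntegerVector deck,
                               IntegerVector choice, NumericVector outcome,
                               NumericVector mu, NumericVector sd,
                               double outcome_scale, bool fictive,
                               double fictive_att) {
  const double h = 1e-5;
  NumericVector g(4);
  double th[4];
  for (int i = 0; i < 4; ++i) th[i] = theta[i];
  for (int i = 0; i < 4; ++i) {
    double t0 = th[i];
    th[i] = t0 + h;
    double up = orl_map_obj_core(th, deck.begin(), choice.begin(),
                                 outcome.begin(), deck.size(), mu.begin(),
                                 sd.begin(), outcome_scale, fictive,
                                 fictive_att);
    th[i] = t0 - h;
    double dn = orl_map_obj_core(th, deck.begin(), choice.begin(),
                                 outcome.begin(), deck.size(), mu.begin(),
                                 sd.begin(), outcome_scale, fictive,
                                 fictive_att);
    th[i] = t0;
    g[i] = (up - dn) / (2 * h);
  }
  return g;
}

// Generative agent on a fixed schedule. sched is an n_presentations x 4
// matrix of per-deck outcome sequences (column j = outcome of the k-th play
// on deck j). Uses R's RNG so set.seed() governs reproducibility. When
// timeout_prob > 0 a timeout uniform is drawn first on every trial; a timed
// out trial is a forced pass and consumes no choice draw.
// [[Rcpp::export]]
List orl_simulate_cpp(IntegerVector deck, NumericMatrix sched, double a_rew,
                      double a_pun, double beta_f, double beta_b,
                      double outcome_scale, bool fictive, double fictive_att,
                      double timeout_prob) {
  int n = deck.size();
  IntegerVector choice(n), timeout(n);
  NumericVector outcome(n);
  double EV[4] = {0, 0, 0, 0}, EF[4] = {0, 0, 0, 0};
  int plays[4] = {0, 0, 0, 0};
  RNGScope scope;
  for (int t = 0; t < n; ++t) {
    int j = deck[t] - 1;
    if (timeout_prob > 0 && unif_rand() < timeout_prob) {
      choice[t] = 0;
      timeout[t] = 1;
      continue;
    }
    double V = EV[j] + EF[j] * beta_f + beta_b;
    double p = 1.0 / (1.0 + std::exp(-V));
    int play = unif_rand() < p ? 1 : 0;
    choice[t] = play;
    if (play) {
      if (plays[j] >= sched.nrow()) stop("outcome schedule exhausted for deck %d", j + 1);
      double x = sched(plays[j], j);
      plays[j]++;
      outcome[t] = x;
      double lr = (x >= 0) ? a_rew : a_pun;
      EV[j] += lr * (x / outcome_scale - EV[j]);
      EF[j] += lr * (sgn(x) - EF[j]);
      if (fictive) {
        double lrf = (x >= 0) ? a_pun : a_rew;
        double target = -sgn(x) / fictive_att;
        for (int k = 0; k < 4; ++k)
          if (k != j) EF[k] += lrf * (target - EF[k]);
      }
    }
  }
  return List::create(_["choice"] = choice, _["timeout"] = timeout,
                      _["outcome"] = outcome);
}
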