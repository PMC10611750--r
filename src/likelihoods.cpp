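#include <Rcpp.h>
using namespace Rcpp;

// Layout convention: layout(t, (r-1)*3 + c - 1) = image id (1..9) shown at
// category row r, column c on trial t. Each image appears exactly once per
// trial, so each of the three columns holds three distinct images.

static inline void column_images(const IntegerMatrix& layout, int t, int col,
                                 int out[3]) {
  for (int r = 0; r < 3; ++r) out[r] = layout(t, r * 3 + col) - 1;
}

// Forward filter for the hidden Markov observer. Event order within a trial:
// choice from the current belief -> outcome observed -> emission update and
// renormalisation -> transition smear -> next trial. Returns the belief held
// *before* each trial's choice (n x 9) and the per-trial log choice
// probability. choice is 1..3 (NA = skipped trial: no likelihood term, no
// belief change). reward is 0/1.
// [[Rcpp::export]]
List hmm_filter_cpp(IntegerMatrix layout, IntegerVector choice,
                    IntegerVector reward, IntegerVector game,
                    double q, double p, double tr, double power,
                    bool reset_each_game) {
  const int n = choice.size();
  NumericMatrix beliefs(n, 9);
  NumericVector logp(n);
  double a[9];
  int cur_game = NA_INTEGER;
  bool started = false;

  for (int t = 0; t < n; ++t) {
    if (!started || (reset_each_game && game[t] != cur_game)) {
      for (int i = 0; i < 9; ++i) a[i] = 1.0 / 9.0;
      started = true;
    }
    cur_game = game[t];
    for (int i = 0; i < 9; ++i) beliefs(t, i) = a[i];

    if (choice[t] == NA_INTEGER) {
      logp[t] = NA_REAL;
      continue;
    }
    const int ch = choice[t] - 1;
    if (ch < 0 || ch > 2) stop("invalid choice column at trial %d", t + 1);

    // probability matching over column belief masses (optionally sharpened)
    double colsum[3] = {0.0, 0.0, 0.0};
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) {
        int img = layout(t, r * 3 + c) - 1;
        colsum[c] += (power == 1.0) ? a[img] : std::pow(a[img], power);
      }
    double tot = colsum[0] + colsum[1] + colsum[2];
    double pc = colsum[ch] / tot;
    if (!R_finite(pc) || pc <= 0.0)
      stop("non-finite choice probability at trial %d", t + 1);
    logp[t] = std::log(pc);

    // emission update: chosen features scored with q, unchosen with p
    const double lik_ch = reward[t] ? q : 1.0 - q;
    const double lik_un = reward[t] ? 1.0 - p : p;
    bool chosen[9] = {false, false, false, false, false,
                      false, false, false, false};
    int imgs[3];
    column_images(layout, t, ch, imgs);
    for (int r = 0; r < 3; ++r) chosen[imgs[r]] = true;
    double s = 0.0;
    for (int i = 0; i < 9; ++i) {
      a[i] *= chosen[i] ? lik_ch : lik_un;
      if (a[i] < 1e-300) a[i] = 1e-300;  // underflow guard on long sessions
      s += a[i];
    }
    for (int i = 0; i < 9; ++i) a[i] /= s;

    // transition: diagonal 1 - tr, off-diagonal tr/8
    for (int i = 0; i < 9; ++i)
      a[i] = (1.0 - tr) * a[i] + (tr / 8.0) * (1.0 - a[i]);
  }
  return List::create(_["beliefs"] = beliefs, _["logp"] = logp);
}

// [[Rcpp::export]]
double hmm_loglik_cpp(IntegerMatrix layout, IntegerVector choice,
                      IntegerVector reward, IntegerVector game,
                      double q, double p, double tr, double power,
                      bool reset_each_game) {
  const int n = choice.size();
  double a[9];
  double ll = 0.0;
  int cur_game = NA_INTEGER;
  bool started = false;

  for (int t = 0; t < n; ++t) {
    if (!started || (reset_each_game && game[t] != cur_game)) {
      for (int i = 0; i < 9; ++i) a[i] = 1.0 / 9.0;
      started = true;
    }
    cur_game = game[t];
    if (choice[t] == NA_INTEGER) continue;
    const int ch = choice[t] - 1;

    double colsum[3] = {0.0, 0.0, 0.0};
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) {
        int img = layout(t, r * 3 + c) - 1;
        colsum[c] += (power == 1.0) ? a[img] : std::pow(a[img], power);
      }
    double pc = colsum[ch] / (colsum[0] + colsum[1] + colsum[2]);
    if (!R_finite(pc) || pc <= 0.0)
      stop("non-finite choice probability at trial %d", t + 1);
    ll += std::log(pc);

    const double lik_ch = reward[t] ? q : 1.0 - q;
    const double lik_un = reward[t] ? 1.0 - p : p;
    bool chosen[9] = {false, false, false, false, false,
                      false, false, false, false};
    int imgs[3];
    column_images(layout, t, ch, imgs);
    for (int r = 0; r < 3; ++r) chosen[imgs[r]] = true;
    double s = 0.0;
    for (int i = 0; i < 9; ++i) {
      a[i] *= chosen[i] ? lik_ch : lik_un;
      if (a[i] < 1e-300) a[i] = 1e-300;
      s += a[i];
    }
    for (int i = 0; i < 9; ++i) a[i] /= s;
    for (int i = 0; i < 9; ++i)
      a[i] = (1.0 - tr) * a[i] + (tr / 8.0) * (1.0 - a[i]);
  }
  return ll;
}

// Rescorla-Wagner feature learner over the 9 images. variant: 0 = ba
// (single alpha, no forgetting), 1 = baf (adds forgetting of the six
// unchosen images), 2 = bafc (valence-split learning rates modulated by a
// confidence trace). Values reset to 0 at each game start when
// reset_each_game; confidence (bafc) is initialised once per session.
// [[Rcpp::export]]
double rl_loglik_cpp(IntegerMatrix layout, IntegerVector choice,
                     IntegerVector reward, IntegerVector game,
                     double alpha_p, double alpha_n, double beta,
                     double phi, double gamma, double kappa,
                     int variant, bool reset_each_game) {
  const int n = choice.size();
  double v[9];
  for (int i = 0; i < 9; ++i) v[i] = 0.0;
  double conf = 0.5;
  double ll = 0.0;
  int cur_game = NA_INTEGER;
  bool started = false;

  for (int t = 0; t < n; ++t) {
    if (!started || (reset_each_game && game[t] != cur_game)) {
      for (int i = 0; i < 9; ++i) v[i] = 0.0;
      started = true;
    }
    cur_game = game[t];
    if (choice[t] == NA_INTEGER) continue;
    const int ch = choice[t] - 1;

    double V[3];
    for (int c = 0; c < 3; ++c) {
      double s = 0.0;
      for (int r = 0; r < 3; ++r) s += v[layout(t, r * 3 + c) - 1];
      V[c] = s / 3.0;
    }
    double m = std::max(V[0], std::max(V[1], V[2]));
    double e0 = std::exp(beta * (V[0] - m));
    double e1 = std::exp(beta * (V[1] - m));
    double e2 = std::exp(beta * (V[2] - m));
    double denom = e0 + e1 + e2;
    double pc = (ch == 0 ? e0 : (ch == 1 ? e1 : e2)) / denom;
    if (!R_finite(pc) || pc <= 0.0)
      stop("non-finite choice probability at trial %d", t + 1);
    ll += std::log(pc);

    double delta = (double)reward[t] - V[ch];
    double alpha_t;
    if (variant == 2) {
      conf += gamma * ((2.0 - std::fabs(delta)) / 2.0 - conf);
      alpha_t = (delta > 0.0) ? (alpha_p + kappa * conf) / (1.0 + kappa * conf)
                              : alpha_n / (1.0 + kappa * conf);
    } else {
      alpha_t = (delta > 0.0) ? alpha_p : alpha_n;
    }

    bool in_choice[9] = {false, false, false, false, false,
                         false, false, false, false};
    int imgs[3];
    column_images(layout, t, ch, imgs);
    for (int r = 0; r < 3; ++r) in_choice[imgs[r]] = true;
    for (int i = 0; i < 9; ++i) {
      if (in_choice[i])
        v[i] += alpha_t * delta;
      else if (variant >= 1)
        v[i] *= (1.0 - phi);  // relax unchosen values toward the initial 0
    }
  }
  return ll;
}
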