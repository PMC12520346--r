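// Core numerics: task input synthesis, batched forward simulation of the
// excitatory/inhibitory rate RNN, decision extraction, and BPTT training
// with the Dale sign-constraint projection. Neurons are ordered excitatory
// first (columns 0..n_exc-1 of W_rec), inhibitory last.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

typedef std::mt19937_64 rng_t;

static inline void fill_randn(mat &m, rng_t &rng) {
  std::normal_distribution<double> nd(0.0, 1.0);
  double *p = m.memptr();
  const uword n = m.n_elem;
  for (uword i = 0; i < n; ++i) p[i] = nd(rng);
}

// Fill the input cube (n_channels x n_trials x n_steps) for a set of trials.
// Channels: 0 vis+, 1 vis-, 2 aud+, 3 aud-, 4 cue (optional).
// u_t = relu(u0 + task drive + (1/alpha)*sqrt(2*alpha*sigma_in^2) * N(0,1)).
static void fill_inputs(cube &U, const ivec &modality, const vec &freq,
                        int t_fix, double alpha, double u0, double sigma_in,
                        double gain, bool cue_on, double cue_amp,
                        double f_min, double f_max, rng_t &rng) {
  const uword B = U.n_cols, T = U.n_slices, C = U.n_rows;
  const double noise_scale = (1.0 / alpha) * std::sqrt(2.0 * alpha * sigma_in * sigma_in);
  std::normal_distribution<double> nd(0.0, 1.0);
  for (uword t = 0; t < T; ++t) {
    mat &s = U.slice(t);
    const bool stim = ((int)t >= t_fix);
    for (uword i = 0; i < B; ++i) {
      const double ap = gain * (freq(i) - f_min) / (f_max - f_min);
      const double an = gain - gain * (freq(i) - f_min) / (f_max - f_min);
      const bool vis = modality(i) == 0 || modality(i) == 2;
      const bool aud = modality(i) == 1 || modality(i) == 2;
      s(0, i) = u0 + ((stim && vis) ? ap : 0.0);
      s(1, i) = u0 + ((stim && vis) ? an : 0.0);
      s(2, i) = u0 + ((stim && aud) ? ap : 0.0);
      s(3, i) = u0 + ((stim && aud) ? an : 0.0);
      if (C > 4) s(4, i) = (cue_on && stim) ? cue_amp : 0.0;
      for (uword c = 0; c < C; ++c) {
        double v = s(c, i) + ((sigma_in > 0.0) ? noise_scale * nd(rng) : 0.0);
        s(c, i) = v > 0.0 ? v : 0.0;
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_make_inputs(const arma::ivec &modality, const arma::vec &freq,
                           int t_fix, int t_stim, int n_channels,
                           double alpha, double u0, double sigma_in,
                           double gain, bool cue_on, double cue_amp,
                           double f_min, double f_max, double seed) {
  rng_t rng((uint64_t)seed);
  cube U(n_channels, modality.n_elem, t_fix + t_stim);
  fill_inputs(U, modality, freq, t_fix, alpha, u0, sigma_in, gain, cue_on,
              cue_amp, f_min, f_max, rng);
  return U;
}

struct ForwardOut {
  cube Z;          // 2 x B x T
  cube rates;      // N x B x T (optional)
  cube fix_traces; // N x B x t_fix (optional)
  mat win_rates;   // N x B mean rate over the final `win` steps (optional)
};

// mode: 0 none, 1 modulatory current, 2 lesion (rate clamp)
static void forward_pass(const mat &Win, const mat &Wrec, const mat &Wout,
                         const vec &b_rec, const vec &b_inp, const vec &b_out,
                         int n_exc, const cube &U, double alpha,
                         double sigma_rec, rng_t &rng, ForwardOut &out,
                         bool want_rates, bool want_select, int t_fix, int win,
                         int mode, const uvec &target, double b_per,
                         double sigma_per,
                         std::vector<mat> *store_X = nullptr,
                         std::vector<mat> *store_R = nullptr,
                         rng_t *per_rng = nullptr) {
  const uword N = Wrec.n_rows, B = U.n_cols, T = U.n_slices;
  const double rec_scale = std::sqrt(2.0 * alpha * sigma_rec * sigma_rec);
  const double per_scale = std::sqrt(2.0 * alpha * sigma_per * sigma_per);
  mat X(N, B, fill::zeros), R(N, B, fill::zeros), noise(N, B);
  mat per_noise;
  if (mode == 1 && target.n_elem > 0) per_noise.set_size(target.n_elem, B);
  out.Z.set_size(2, B, T);
  if (want_rates) out.rates.set_size(N, B, T);
  if (want_select) {
    out.fix_traces.set_size(N, B, t_fix);
    out.win_rates.zeros(N, B);
  }
  for (uword t = 0; t < T; ++t) {
    mat drive = Wrec * R;
    drive.each_col() += b_rec + b_inp;
    drive += Win * U.slice(t);
    if (mode == 1 && target.n_elem > 0) drive.rows(target) += b_per;
    if (sigma_rec > 0.0) {
      fill_randn(noise, rng);
      X = (1.0 - alpha) * X + alpha * drive + rec_scale * noise;
    } else {
      X = (1.0 - alpha) * X + alpha * drive;
    }
    if (mode == 1 && target.n_elem > 0 && sigma_per > 0.0) {
      // private stream keeps the shared recurrent-noise draws identical to
      // a matched-seed baseline run
      fill_randn(per_noise, per_rng ? *per_rng : rng);
      X.rows(target) += per_scale * per_noise;
    }
    R = clamp(X, 0.0, datum::inf);
    if (mode == 2 && target.n_elem > 0) R.rows(target).zeros();
    out.Z.slice(t) = Wout * R.rows(0, n_exc - 1);
    out.Z.slice(t).each_col() += b_out;
    if (want_rates) out.rates.slice(t) = R;
    if (want_select) {
      if ((int)t < t_fix) out.fix_traces.slice(t) = R;
      if ((int)t >= (int)T - win) out.win_rates += R / (double)win;
    }
    if (store_X) { (*store_X)[t] = X; (*store_R)[t] = R; }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_forward(const arma::mat &Win, const arma::mat &Wrec,
                       const arma::mat &Wout, const arma::vec &b_rec,
                       const arma::vec &b_inp, const arma::vec &b_out,
                       int n_exc, const arma::cube &U, double alpha,
                       double sigma_rec, double seed, bool want_rates,
                       bool want_select, int t_fix, int win, int mode,
                       const arma::uvec &target, double b_per,
                       double sigma_per) {
  rng_t rng((uint64_t)seed);
  rng_t per_rng(((uint64_t)seed) ^ 0x9E3779B97F4A7C15ULL);
  ForwardOut out;
  forward_pass(Win, Wrec, Wout, b_rec, b_inp, b_out, n_exc, U, alpha,
               sigma_rec, rng, out, want_rates, want_select, t_fix, win, mode,
               target, b_per, sigma_per, nullptr, nullptr, &per_rng);
  Rcpp::List res = Rcpp::List::create(Rcpp::Named("outputs") = out.Z);
  if (want_rates) res["rates"] = out.rates;
  if (want_select) {
    res["fix_traces"] = out.fix_traces;
    res["win_rates"] = out.win_rates;
  }
  return res;
}

// First-crossing decision rule. Returns B x 3 matrix:
// col 0 status (0 valid, 1 invalid_pre_stimulus, 2 no_decision),
// col 1 choice (1 high, 0 low, NA when no decision),
// col 2 decision step (1-based, NA when no decision).
// [[Rcpp::export]]
arma::mat cpp_decisions(const arma::cube &Z, double threshold, int onset_index) {
  const uword B = Z.n_cols, T = Z.n_slices;
  mat res(B, 3);
  res.col(1).fill(datum::nan);
  res.col(2).fill(datum::nan);
  for (uword i = 0; i < B; ++i) {
    int step = -1;
    for (uword t = 0; t < T; ++t) {
      const double d = Z(1, i, t) - Z(0, i, t);
      if (std::abs(d) > threshold) { step = (int)t; break; }
    }
    if (step < 0) {
      res(i, 0) = 2;
    } else if (step < onset_index) {
      res(i, 0) = 1;
      res(i, 1) = Z(1, i, step) - Z(0, i, step) > 0 ? 1 : 0;
      res(i, 2) = step + 1;
    } else {
      res(i, 0) = 0;
      res(i, 1) = Z(1, i, step) - Z(0, i, step) > 0 ? 1 : 0;
      res(i, 2) = step + 1;
    }
  }
  return res;
}

// Masked-MSE loss and BPTT gradients w.r.t. the trainable parameters
// {W_rec, b_rec, b_inp, b_out}, given stored forward quantities.
struct Grads {
  mat gWrec;
  vec gb_rec, gb_inp, gb_out;
  double loss;
};

static void bptt_backward(const mat &Wrec, const mat &Wout, int n_exc,
                          const std::vector<mat> &Xs,
                          const std::vector<mat> &Rs, const cube &Z,
                          const cube &targ, const vec &mask, double alpha,
                          Grads &g) {
  const uword N = Wrec.n_rows, B = Z.n_cols, T = Z.n_slices;
  g.gWrec.zeros(N, N);
  g.gb_rec.zeros(N);
  g.gb_out.zeros(2);
  g.loss = 0.0;
  mat gX(N, B, fill::zeros);
  const double denom = (double)B * T; // x N_out; factor 2 cancels below
  for (int t = (int)T - 1; t >= 0; --t) {
    mat err = Z.slice(t) - targ.slice(t);
    g.loss += mask(t) * accu(square(err)) / (denom * 2.0);
    mat gZ = (mask(t) / denom) * err; // dL/dz (2 * 1/2 cancelled)
    mat gR = Wrec.t() * (alpha * gX);
    gR.rows(0, n_exc - 1) += Wout.t() * gZ;
    gX = (1.0 - alpha) * gX + gR % conv_to<mat>::from(Xs[t] > 0.0);
    if (t > 0) g.gWrec += (alpha * gX) * Rs[t - 1].t();
    g.gb_rec += alpha * sum(gX, 1);
    g.gb_out += sum(gZ, 1);
  }
  g.gb_inp = g.gb_rec;
}

// [[Rcpp::export]]
Rcpp::List cpp_bptt_grads(const arma::mat &Win, const arma::mat &Wrec,
                          const arma::mat &Wout, const arma::vec &b_rec,
                          const arma::vec &b_inp, const arma::vec &b_out,
                          int n_exc, const arma::cube &U,
                          const arma::cube &targets, const arma::vec &mask,
                          double alpha, double sigma_rec, double seed) {
  rng_t rng((uint64_t)seed);
  const uword T = U.n_slices;
  std::vector<mat> Xs(T), Rs(T);
  ForwardOut out;
  uvec dummy;
  forward_pass(Win, Wrec, Wout, b_rec, b_inp, b_out, n_exc, U, alpha,
               sigma_rec, rng, out, false, false, 0, 0, 0, dummy, 0, 0,
               &Xs, &Rs);
  Grads g;
  bptt_backward(Wrec, Wout, n_exc, Xs, Rs, out.Z, targets, mask, alpha, g);
  return Rcpp::List::create(
      Rcpp::Named("loss") = g.loss, Rcpp::Named("gWrec") = g.gWrec,
      Rcpp::Named("gb_rec") = g.gb_rec, Rcpp::Named("gb_inp") = g.gb_inp,
      Rcpp::Named("gb_out") = g.gb_out, Rcpp::Named("outputs") = out.Z);
}

static void sample_conditions(ivec &modality, vec &freq, double f_min,
                              double f_max, rng_t &rng) {
  std::uniform_int_distribution<int> mdist(0, 2);
  std::uniform_int_distribution<int> fdist(0, (int)(f_max - f_min));
  for (uword i = 0; i < modality.n_elem; ++i) {
    modality(i) = mdist(rng);
    freq(i) = f_min + fdist(rng);
  }
}

// Validation: fraction of valid trials and fraction correct among valid.
static void validate_now(const mat &Win, const mat &Wrec, const mat &Wout,
                         const vec &b_rec, const vec &b_inp, const vec &b_out,
                         int n_exc, int n_val, int t_fix, int t_stim,
                         int n_channels, double alpha, double u0,
                         double sigma_in, double gain, bool cue_on,
                         double cue_amp, double f_min, double f_max,
                         double f_thr, double sigma_rec, double dec_thr,
                         rng_t &rng, double &valid_frac, double &correct_frac) {
  ivec modality(n_val);
  vec freq(n_val);
  sample_conditions(modality, freq, f_min, f_max, rng);
  cube U(n_channels, n_val, t_fix + t_stim);
  fill_inputs(U, modality, freq, t_fix, alpha, u0, sigma_in, gain, cue_on,
              cue_amp, f_min, f_max, rng);
  ForwardOut out;
  uvec dummy;
  forward_pass(Win, Wrec, Wout, b_rec, b_inp, b_out, n_exc, U, alpha,
               sigma_rec, rng, out, false, false, t_fix, 0, 0, dummy, 0, 0);
  mat dec = cpp_decisions(out.Z, dec_thr, t_fix);
  int n_valid = 0, n_correct = 0;
  for (int i = 0; i < n_val; ++i) {
    if (dec(i, 0) == 0) {
      ++n_valid;
      const int truth = freq(i) > f_thr ? 1 : 0;
      if ((int)dec(i, 1) == truth) ++n_correct;
    }
  }
  valid_frac = (double)n_valid / n_val;
  correct_frac = n_valid > 0 ? (double)n_correct / n_valid : 0.0;
}

// BPTT training with SGD + L2 weight decay on {W_rec, b_rec, b_inp, b_out},
// Dale projection after every update, convergence checks every
// validate_every epochs on a fresh validation batch.
// [[Rcpp::export]]
Rcpp::List cpp_train(const arma::mat &Win, arma::mat Wrec, const arma::mat &Wout,
                     arma::vec b_rec, arma::vec b_inp, arma::vec b_out,
                     int n_exc, bool dale, Rcpp::List task, Rcpp::List train,
                     double seed) {
  const int t_fix = task["t_fix"], t_stim = task["t_stim"];
  const int n_channels = task["n_channels"], grace_steps = task["grace_steps"];
  const double alpha = task["alpha"], u0 = task["u0"];
  const double sigma_in = task["sigma_in"], gain = task["gain"];
  const bool cue_on = task["cue_on"];
  const double cue_amp = task["cue_amp"];
  const double f_min = task["f_min"], f_max = task["f_max"];
  const double f_thr = task["f_threshold"];
  const double target_low = task["target_low"], target_high = task["target_high"];
  const double sigma_rec = train["sigma_rec"];
  const double lr = train["lr"], lambda = train["weight_decay"];
  const double gscale = train["loss_scale"];
  const int B = train["batch_size"], max_epochs = train["max_epochs"];
  const int validate_every = train["validate_every"];
  const int n_val = train["validation_size"];
  const double crit_valid = train["valid_criterion"];
  const double crit_correct = train["correct_criterion"];
  const double dec_thr = train["decision_threshold"];

  const uword N = Wrec.n_rows;
  const int T = t_fix + t_stim;
  rng_t rng((uint64_t)seed);

  std::vector<mat> Xs(T), Rs(T);
  ivec modality(B);
  vec freq(B);
  cube U(n_channels, B, T);
  vec mask(T, fill::ones);
  for (int t = t_fix; t < t_fix + grace_steps; ++t) mask(t) = 0.0;

  std::vector<double> h_epoch, h_loss, h_valid, h_correct;
  bool converged = false, diverged = false;
  int epochs_used = max_epochs;
  double loss_acc = 0.0;
  int loss_n = 0;

  ForwardOut out;
  uvec dummy;
  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    sample_conditions(modality, freq, f_min, f_max, rng);
    fill_inputs(U, modality, freq, t_fix, alpha, u0, sigma_in, gain, cue_on,
                cue_amp, f_min, f_max, rng);
    forward_pass(Win, Wrec, Wout, b_rec, b_inp, b_out, n_exc, U, alpha,
                 sigma_rec, rng, out, false, false, t_fix, 0, 0, dummy, 0, 0,
                 &Xs, &Rs);
    // targets: both outputs low during fixation; correct output high during
    // the stimulus epoch
    cube targ(2, B, T);
    targ.fill(target_low);
    for (int i = 0; i < B; ++i) {
      const int hi = freq(i) > f_thr ? 1 : 0;
      for (int t = t_fix; t < T; ++t) targ(hi, i, t) = target_high;
    }
    Grads g;
    bptt_backward(Wrec, Wout, n_exc, Xs, Rs, out.Z, targ, mask, alpha, g);
    if (!std::isfinite(g.loss)) { diverged = true; epochs_used = epoch; break; }
    loss_acc += g.loss; ++loss_n;
    // SGD with coupled L2 weight decay, then Dale projection. loss_scale
    // converts the per-element mean gradient to the reduction convention
    // actually optimized (see train_config()).
    Wrec -= lr * (gscale * g.gWrec + lambda * Wrec);
    b_rec -= lr * (gscale * g.gb_rec + lambda * b_rec);
    b_inp -= lr * (gscale * g.gb_inp + lambda * b_inp);
    b_out -= lr * (gscale * g.gb_out + lambda * b_out);
    for (uword j = 0; dale && j < N; ++j) {
      if ((int)j < n_exc) {
        for (uword i = 0; i < N; ++i) if (Wrec(i, j) < 0) Wrec(i, j) = 0;
      } else {
        for (uword i = 0; i < N; ++i) if (Wrec(i, j) > 0) Wrec(i, j) = 0;
      }
    }
    if (epoch % validate_every == 0) {
      double vf, cf;
      validate_now(Win, Wrec, Wout, b_rec, b_inp, b_out, n_exc, n_val, t_fix,
                   t_stim, n_channels, alpha, u0, sigma_in, gain, cue_on,
                   cue_amp, f_min, f_max, f_thr, sigma_rec, dec_thr, rng, vf, cf);
      h_epoch.push_back(epoch);
      h_loss.push_back(loss_acc / std::max(loss_n, 1));
      h_valid.push_back(vf);
      h_correct.push_back(cf);
      loss_acc = 0.0; loss_n = 0;
      if (vf >= crit_valid && cf >= crit_correct) {
        converged = true; epochs_used = epoch; break;
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("Wrec") = Wrec, Rcpp::Named("b_rec") = b_rec,
      Rcpp::Named("b_inp") = b_inp, Rcpp::Named("b_out") = b_out,
      Rcpp::Named("converged") = converged, Rcpp::Named("diverged") = diverged,
      Rcpp::Named("epochs_used") = epochs_used,
      Rcpp::Named("history") = Rcpp::DataFrame::create(
          Rcpp::Named("epoch") = h_epoch, Rcpp::Named("loss") = h_loss,
          Rcpp::Named("valid_frac") = h_valid,
          Rcpp::Named("correct_frac") = h_correct));
}
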