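// Compiled kernels for the batched rollout (policy + value recurrent
// dynamics interleaved with the task environment) and for
// backpropagation through time.  The R implementations of the same
// computations are kept in R/ as reference paths; tests assert
// bit-level agreement of the forward dynamics and finite-difference
// agreement of the gradients.
//
// RNG discipline: draws come from R's own generator in exactly the
// same order and count as the R reference path (policy noise, action
// uniform, value noise, per step), so seeded runs are identical across
// engines.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat sigmoid(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

static arma::mat rnorm_mat(int nr, int nc) {
  arma::mat m(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) m(i, j) = R::norm_rand();
  return m;
}

// [[Rcpp::export(name = ".cpp_rollout")]]
List cpp_rollout(List pol, List val,
                 arma::mat W_out_pi, arma::vec b_out_pi,
                 arma::rowvec W_out_v, double b_out_v,
                 arma::cube U,                 // k x B x T
                 IntegerVector tgt1, IntegerVector tgt2,
                 IntegerVector period_of,      // length T, 0 = terminal
                 int dec1_last, int dec2_last, // 0-based step indices
                 int p_dec1, int p_dec2,
                 double eta_p, double eta_v, double sd_p, double sd_v,
                 bool noise_on, bool cache, double timeout1_reward,
                 Nullable<IntegerMatrix> scripted, bool critic_prev_action) {
  const arma::mat pW_rec = pol["W_rec"], pW_rphi = pol["W_rec_phi"],
    pW_rpsi = pol["W_rec_psi"], pW_in = pol["W_in"],
    pW_iphi = pol["W_in_phi"], pW_ipsi = pol["W_in_psi"];
  const arma::vec pb = pol["b"], pb_phi = pol["b_phi"], pb_psi = pol["b_psi"];
  const arma::mat vW_rec = val["W_rec"], vW_rphi = val["W_rec_phi"],
    vW_rpsi = val["W_rec_psi"], vW_in = val["W_in"],
    vW_iphi = val["W_in_phi"], vW_ipsi = val["W_in_psi"];
  const arma::vec vb = val["b"], vb_phi = val["b_phi"], vb_psi = val["b_psi"];

  const int k = U.n_rows, B = U.n_cols, T = U.n_slices;
  const int np = pW_rec.n_rows, nv = vW_rec.n_rows, na = W_out_pi.n_rows;
  const bool has_script = scripted.isNotNull();
  IntegerMatrix script = has_script ? IntegerMatrix(scripted) :
    IntegerMatrix(1, 1);

  arma::mat hp(np, B, arma::fill::zeros), hv(nv, B, arma::fill::zeros);
  arma::cube rates(np, B, T);
  arma::cube cp_h, cp_phi, cp_psi, cp_cand, cv_h, cv_phi, cv_psi, cv_cand,
    c_probs;
  if (cache) {
    cp_h.set_size(np, B, T); cp_phi.set_size(np, B, T);
    cp_psi.set_size(np, B, T); cp_cand.set_size(np, B, T);
    cv_h.set_size(nv, B, T); cv_phi.set_size(nv, B, T);
    cv_psi.set_size(nv, B, T); cv_cand.set_size(nv, B, T);
    c_probs.set_size(na, B, T);
  }

  arma::mat rewards(B, T, arma::fill::zeros);
  arma::umat taken(B, T, arma::fill::zeros);
  arma::imat actions(B, T, arma::fill::ones);
  arma::mat logp(B, T, arma::fill::zeros);
  arma::mat values(B, T, arma::fill::zeros);

  std::vector<int> alive(B, 1), first_choice(B, 0), second_choice(B, 0),
    choice1_step(B, NA_INTEGER), choice2_step(B, NA_INTEGER),
    term_step(B, NA_INTEGER);
  std::vector<int> first_correct(B, 0), second_correct(B, 0);
  std::vector<int> prev_a(B, 0);          // 0 = no action yet
  StringVector event_last(B, "trial-end");

  for (int t = 0; t < T; ++t) {
    const arma::mat ut = U.slice(t);
    // ---- policy step ----
    arma::mat x_prev = arma::clamp(hp, 0.0, arma::datum::inf);
    arma::mat phi = pW_rphi * x_prev + pW_iphi * ut;
    phi.each_col() += pb_phi;
    phi = sigmoid(phi);
    arma::mat psi = pW_rpsi * x_prev + pW_ipsi * ut;
    psi.each_col() += pb_psi;
    psi = sigmoid(psi);
    arma::mat cand = pW_rec * (psi % x_prev) + pW_in * ut;
    cand.each_col() += pb;
    if (noise_on) cand += sd_p * rnorm_mat(np, B);
    arma::mat ef = eta_p * phi;
    hp = (1.0 - ef) % hp + ef % cand;
    arma::mat x = arma::clamp(hp, 0.0, arma::datum::inf);

    arma::mat z = W_out_pi * x;
    z.each_col() += b_out_pi;
    z.each_row() -= arma::max(z, 0);
    arma::mat pr = arma::exp(z);
    pr.each_row() /= arma::sum(pr, 0);

    std::vector<int> a(B);
    for (int b = 0; b < B; ++b) {
      double u = R::unif_rand();
      int ai = 1 + (u > pr(0, b)) + (u > pr(0, b) + pr(1, b));
      a[b] = has_script ? script(b, t) : ai;
    }

    // ---- environment ----
    int pid = period_of[t];
    arma::vec r(B, arma::fill::zeros);
    std::vector<int> died(B, 0);
    for (int b = 0; b < B; ++b) {
      if (!alive[b]) continue;
      if (pid == 0) {                    // terminal step
        died[b] = 1; event_last[b] = "trial-end";
      } else if (pid == p_dec1) {
        if (first_choice[b] == 0 && a[b] > 1) {
          first_choice[b] = a[b];
          choice1_step[b] = t + 1;
          if (a[b] == tgt1[b]) {
            r[b] = 1; first_correct[b] = 1;
            event_last[b] = "correct-choice-1";
          } else {
            r[b] = -1; died[b] = 1; event_last[b] = "wrong-choice-1";
          }
        } else if (t == dec1_last && first_choice[b] == 0 && a[b] == 1) {
          r[b] = timeout1_reward; died[b] = 1;
          event_last[b] = "no-choice-1";
        }
      } else if (pid == p_dec2) {
        if (second_choice[b] == 0 && a[b] > 1) {
          second_choice[b] = a[b];
          choice2_step[b] = t + 1;
          if (a[b] == tgt2[b]) {
            r[b] = 1; second_correct[b] = 1;
            event_last[b] = "correct-choice-2";
          } else {
            r[b] = 0; event_last[b] = "wrong-choice-2";
          }
        } else if (t == dec2_last && second_choice[b] == 0 && a[b] == 1) {
          r[b] = -1; died[b] = 1; event_last[b] = "no-choice-2";
        }
      } else if (a[b] > 1) {
        // left/right before the first choice breaks fixation; after
        // the first choice the agent has committed (the policy cannot
        // observe its own past action), so left/right is ignored
        // until the second decision window
        if (first_choice[b] == 0) {
          r[b] = -1; died[b] = 1; event_last[b] = "break-fixation";
        }
      }
    }

    // ---- value step on [x ; one-hot action] ----
    arma::mat uv(np + na, B, arma::fill::zeros);
    uv.rows(0, np - 1) = x;
    for (int b = 0; b < B; ++b) {
      int av = critic_prev_action ? prev_a[b] : a[b];
      if (av > 0) uv(np + av - 1, b) = 1.0;
    }
    arma::mat xv_prev = arma::clamp(hv, 0.0, arma::datum::inf);
    arma::mat phiv = vW_rphi * xv_prev + vW_iphi * uv;
    phiv.each_col() += vb_phi;
    phiv = sigmoid(phiv);
    arma::mat psiv = vW_rpsi * xv_prev + vW_ipsi * uv;
    psiv.each_col() += vb_psi;
    psiv = sigmoid(psiv);
    arma::mat candv = vW_rec * (psiv % xv_prev) + vW_in * uv;
    candv.each_col() += vb;
    if (noise_on) candv += sd_v * rnorm_mat(nv, B);
    arma::mat efv = eta_v * phiv;
    hv = (1.0 - efv) % hv + efv % candv;
    arma::mat xv = arma::clamp(hv, 0.0, arma::datum::inf);
    arma::rowvec v = W_out_v * xv + b_out_v;

    // ---- record ----
    for (int b = 0; b < B; ++b) {
      taken(b, t) = alive[b];
      actions(b, t) = a[b];
      rewards(b, t) = alive[b] ? r[b] : 0.0;
      logp(b, t) = std::log(pr(a[b] - 1, b));
      values(b, t) = v[b];
    }
    rates.slice(t) = x;
    if (cache) {
      cp_h.slice(t) = hp; cp_phi.slice(t) = phi;
      cp_psi.slice(t) = psi; cp_cand.slice(t) = cand;
      cv_h.slice(t) = hv; cv_phi.slice(t) = phiv;
      cv_psi.slice(t) = psiv; cv_cand.slice(t) = candv;
      c_probs.slice(t) = pr;
    }
    for (int b = 0; b < B; ++b) {
      if (died[b] && term_step[b] == NA_INTEGER) term_step[b] = t + 1;
      if (died[b]) alive[b] = 0;
      prev_a[b] = a[b];
    }
  }

  IntegerVector lengths(B);
  for (int b = 0; b < B; ++b)
    lengths[b] = term_step[b] == NA_INTEGER ? T : term_step[b];

  List out = List::create(
    _["rewards"] = rewards, _["taken"] = taken, _["actions"] = actions,
    _["logp"] = logp, _["values"] = values, _["rates"] = rates,
    _["lengths"] = lengths,
    _["first_correct"] = IntegerVector(first_correct.begin(),
                                       first_correct.end()),
    _["second_correct"] = IntegerVector(second_correct.begin(),
                                        second_correct.end()),
    _["first_choice"] = IntegerVector(first_choice.begin(),
                                      first_choice.end()),
    _["second_choice"] = IntegerVector(second_choice.begin(),
                                       second_choice.end()),
    _["choice1_step"] = IntegerVector(choice1_step.begin(),
                                      choice1_step.end()),
    _["choice2_step"] = IntegerVector(choice2_step.begin(),
                                      choice2_step.end()),
    _["event_last"] = event_last);
  if (cache) {
    out["cache"] = List::create(
      _["p.h"] = cp_h, _["p.phi"] = cp_phi, _["p.psi"] = cp_psi,
      _["p.cand"] = cp_cand, _["v.h"] = cv_h, _["v.phi"] = cv_phi,
      _["v.psi"] = cv_psi, _["v.cand"] = cv_cand, _["probs"] = c_probs);
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_gru_backward")]]
List cpp_gru_backward(arma::mat W_rec, arma::mat W_rec_phi,
                      arma::mat W_rec_psi, arma::mat M_rec, arma::mat M_in,
                      arma::cube h, arma::cube phi, arma::cube psi,
                      arma::cube cand, arma::cube U, arma::cube dX_head,
                      double eta) {
  const int n = h.n_rows, B = h.n_cols, T = h.n_slices;
  const int k = U.n_rows;
  arma::mat gW_rec(n, n, arma::fill::zeros),
    gW_rphi(n, n, arma::fill::zeros), gW_rpsi(n, n, arma::fill::zeros),
    gW_in(n, k, arma::fill::zeros), gW_iphi(n, k, arma::fill::zeros),
    gW_ipsi(n, k, arma::fill::zeros);
  arma::vec gb(n, arma::fill::zeros), gb_phi(n, arma::fill::zeros),
    gb_psi(n, arma::fill::zeros);
  arma::mat dXrec(n, B, arma::fill::zeros), dHdir(n, B, arma::fill::zeros);
  const arma::mat tW_rec = W_rec.t(), tW_rphi = W_rec_phi.t(),
    tW_rpsi = W_rec_psi.t();
  for (int t = T - 1; t >= 0; --t) {
    const arma::mat& h_t = h.slice(t);
    arma::mat h_prev = t > 0 ? h.slice(t - 1) :
      arma::mat(n, B, arma::fill::zeros);
    arma::mat x_prev = arma::clamp(h_prev, 0.0, arma::datum::inf);
    const arma::mat& phi_t = phi.slice(t);
    const arma::mat& psi_t = psi.slice(t);

    arma::mat dX = dX_head.slice(t) + dXrec;
    arma::mat dH = dHdir + dX % arma::conv_to<arma::mat>::from(h_t > 0);
    arma::mat ef = eta * phi_t;
    arma::mat dcand = dH % ef;
    arma::mat dphi = dH % (eta * (cand.slice(t) - h_prev));
    dHdir = dH % (1.0 - ef);
    arma::mat dpphi = dphi % phi_t % (1.0 - phi_t);
    arma::mat g = tW_rec * dcand;
    arma::mat dppsi = (g % x_prev) % psi_t % (1.0 - psi_t);
    dXrec = g % psi_t + tW_rphi * dpphi + tW_rpsi * dppsi;

    gW_rec += dcand * (psi_t % x_prev).t();
    gW_rphi += dpphi * x_prev.t();
    gW_rpsi += dppsi * x_prev.t();
    const arma::mat tu = U.slice(t).t();
    gW_in += dcand * tu;
    gW_iphi += dpphi * tu;
    gW_ipsi += dppsi * tu;
    gb += arma::sum(dcand, 1);
    gb_phi += arma::sum(dpphi, 1);
    gb_psi += arma::sum(dppsi, 1);
  }
  return List::create(
    _["W_rec"] = gW_rec % M_rec, _["W_rec_phi"] = gW_rphi % M_rec,
    _["W_rec_psi"] = gW_rpsi % M_rec, _["W_in"] = gW_in % M_in,
    _["W_in_phi"] = gW_iphi % M_in, _["W_in_psi"] = gW_ipsi % M_in,
    _["b"] = gb, _["b_phi"] = gb_phi, _["b_psi"] = gb_psi);
}
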