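// Convolutional-recurrent site classifier: forward pass, backpropagation
// through time, and an Adam training loop with weighted cross-entropy and
// early stopping.  Sites are variable-length L x n feature matrices processed
// one at a time (no cross-site padding); gradients are accumulated over
// mini-batches of sites.
//
// Architecture: 1-D convolution (width w, zero padding, tanh) over the
// residue axis -> unidirectional GRU read out at the final hidden state
// h_L -> linear layer with two output neurons -> softmax.  The bounded
// convolution activation caps the damage any single out-of-domain input
// can inject into the recurrent state.
//
// All randomness (parameter init, epoch shuffling) is supplied from R so the
// training trajectory is reproducible under set.seed().

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Params {
  mat Wc; vec bc;                 // conv: channels x (w * n_in)
  mat Wz, Uz; vec bz;             // GRU update gate
  mat Wr, Ur; vec br;             // GRU reset gate
  mat Wn, Un; vec bn;             // GRU candidate
  mat Wo; vec bo;                 // output layer: 2 x hidden
  int w;                          // conv filter width (odd)
};

Params unpack(const Rcpp::List& p) {
  Params P;
  P.Wc = Rcpp::as<mat>(p["Wc"]); P.bc = Rcpp::as<vec>(p["bc"]);
  P.Wz = Rcpp::as<mat>(p["Wz"]); P.Uz = Rcpp::as<mat>(p["Uz"]); P.bz = Rcpp::as<vec>(p["bz"]);
  P.Wr = Rcpp::as<mat>(p["Wr"]); P.Ur = Rcpp::as<mat>(p["Ur"]); P.br = Rcpp::as<vec>(p["br"]);
  P.Wn = Rcpp::as<mat>(p["Wn"]); P.Un = Rcpp::as<mat>(p["Un"]); P.bn = Rcpp::as<vec>(p["bn"]);
  P.Wo = Rcpp::as<mat>(p["Wo"]); P.bo = Rcpp::as<vec>(p["bo"]);
  P.w  = Rcpp::as<int>(p["filter_width"]);
  return P;
}

Rcpp::List pack(const Params& P) {
  return Rcpp::List::create(
    Rcpp::Named("Wc") = P.Wc, Rcpp::Named("bc") = P.bc,
    Rcpp::Named("Wz") = P.Wz, Rcpp::Named("Uz") = P.Uz, Rcpp::Named("bz") = P.bz,
    Rcpp::Named("Wr") = P.Wr, Rcpp::Named("Ur") = P.Ur, Rcpp::Named("br") = P.br,
    Rcpp::Named("Wn") = P.Wn, Rcpp::Named("Un") = P.Un, Rcpp::Named("bn") = P.bn,
    Rcpp::Named("Wo") = P.Wo, Rcpp::Named("bo") = P.bo,
    Rcpp::Named("filter_width") = P.w);
}

// stacked sliding windows of X' (n_in x L), zero-padded: (w*n_in) x L
mat im2col(const mat& Xt, int w) {
  const int n = Xt.n_rows, L = Xt.n_cols, p = (w - 1) / 2;
  mat M(w * n, L, fill::zeros);
  for (int k = 0; k < w; ++k) {
    const int off = k - p;            // source column offset
    const int lo = std::max(0, -off), hi = std::min(L, L - off);
    if (lo < hi)
      M.rows(k * n, (k + 1) * n - 1).cols(lo, hi - 1) =
        Xt.cols(lo + off, hi - 1 + off);
  }
  return M;
}

struct FwdCache {
  mat M;                // im2col input
  mat Apre;             // conv pre-activation, ch x L
  mat Sp;               // conv activation (ReLU), ch x L
  mat Z, R, N, H;       // GRU per-step quantities, hid x L (H col t = h_t)
  vec probs;            // softmax output, length 2 (phys, adv)
  vec hL;
};

FwdCache forward(const Params& P, const mat& X) {
  FwdCache C;
  mat Xt = X.t();                       // n_in x L
  C.M = im2col(Xt, P.w);
  C.Apre = P.Wc * C.M;
  C.Apre.each_col() += P.bc;
  C.Sp = tanh(C.Apre);
  const int L = Xt.n_cols, hid = P.bz.n_elem;
  C.Z.set_size(hid, L); C.R.set_size(hid, L); C.N.set_size(hid, L); C.H.set_size(hid, L);
  vec h(hid, fill::zeros);
  for (int t = 0; t < L; ++t) {
    vec x = C.Sp.col(t);
    vec z = 1.0 / (1.0 + exp(-(P.Wz * x + P.Uz * h + P.bz)));
    vec r = 1.0 / (1.0 + exp(-(P.Wr * x + P.Ur * h + P.br)));
    vec n = tanh(P.Wn * x + P.Un * (r % h) + P.bn);
    h = (1.0 - z) % n + z % h;
    C.Z.col(t) = z; C.R.col(t) = r; C.N.col(t) = n; C.H.col(t) = h;
  }
  C.hL = h;
  vec logits = P.Wo * h + P.bo;
  double m = logits.max();
  vec e = exp(logits - m);
  C.probs = e / accu(e);
  return C;
}

struct Grads {
  mat Wc; vec bc;
  mat Wz, Uz; vec bz;
  mat Wr, Ur; vec br;
  mat Wn, Un; vec bn;
  mat Wo; vec bo;
  void zero_like(const Params& P) {
    Wc.zeros(size(P.Wc)); bc.zeros(size(P.bc));
    Wz.zeros(size(P.Wz)); Uz.zeros(size(P.Uz)); bz.zeros(size(P.bz));
    Wr.zeros(size(P.Wr)); Ur.zeros(size(P.Ur)); br.zeros(size(P.br));
    Wn.zeros(size(P.Wn)); Un.zeros(size(P.Un)); bn.zeros(size(P.bn));
    Wo.zeros(size(P.Wo)); bo.zeros(size(P.bo));
  }
};

// accumulate gradients for one site; y in {0,1}, wt = sample weight
void backward(const Params& P, const FwdCache& C, int y, double wt, Grads& G) {
  const int L = C.H.n_cols, hid = P.bz.n_elem;
  vec dlog = C.probs * wt;
  dlog(y) -= wt;                                    // wt * (p - onehot)
  G.Wo += dlog * C.hL.t();
  G.bo += dlog;
  vec dh = P.Wo.t() * dlog;
  mat dSp(C.Sp.n_rows, L, fill::zeros);             // grad wrt conv output
  for (int t = L - 1; t >= 0; --t) {
    vec z = C.Z.col(t), r = C.R.col(t), n = C.N.col(t);
    vec hprev = (t == 0) ? vec(hid, fill::zeros) : vec(C.H.col(t - 1));
    vec x = C.Sp.col(t);
    vec dz = dh % (hprev - n) % z % (1.0 - z);
    vec dn = dh % (1.0 - z) % (1.0 - n % n);
    vec rh = r % hprev;
    G.Wn += dn * x.t();  G.Un += dn * rh.t();  G.bn += dn;
    vec drh = P.Un.t() * dn;
    vec dr = drh % hprev % r % (1.0 - r);
    G.Wz += dz * x.t();  G.Uz += dz * hprev.t();  G.bz += dz;
    G.Wr += dr * x.t();  G.Ur += dr * hprev.t();  G.br += dr;
    dSp.col(t) = P.Wz.t() * dz + P.Wr.t() * dr + P.Wn.t() * dn;
    dh = dh % z + drh % r + P.Uz.t() * dz + P.Ur.t() * dr;
  }
  mat dApre = dSp % (1.0 - C.Sp % C.Sp);
  G.Wc += dApre * C.M.t();
  G.bc += sum(dApre, 1);
}

double site_loss(const vec& probs, int y) {
  return -std::log(std::max(probs(y), 1e-12));
}

double eval_loss(const Params& P, const Rcpp::List& X, const Rcpp::IntegerVector& y,
                 double w_pos) {
  double num = 0.0, den = 0.0;
  for (int i = 0; i < X.size(); ++i) {
    FwdCache C = forward(P, Rcpp::as<mat>(X[i]));
    double wt = (y[i] == 0) ? w_pos : 1.0;          // index 0 = physiological
    num += wt * site_loss(C.probs, y[i]);
    den += wt;
  }
  return num / den;
}

struct Adam {
  Grads m, v;
  long t = 0;
  double lr, b1, b2, eps, wd, l1;
  void init(const Params& P, double lr_, double b1_, double b2_, double eps_,
            double wd_, double l1_) {
    m.zero_like(P); v.zero_like(P);
    lr = lr_; b1 = b1_; b2 = b2_; eps = eps_; wd = wd_; l1 = l1_;
  }
  // decoupled (AdamW-style) weight decay on weight matrices, not biases
  template <typename T>
  void step1(T& p, T& mm, T& vv, const T& g, bool decay) {
    mm = b1 * mm + (1.0 - b1) * g;
    vv = b2 * vv + (1.0 - b2) * (g % g);
    T mhat = mm / (1.0 - std::pow(b1, (double)t));
    T vhat = vv / (1.0 - std::pow(b2, (double)t));
    p -= lr * mhat / (sqrt(vhat) + eps);
    if (decay) p -= lr * wd * p;
  }
  void step(Params& P, const Grads& G) {
    ++t;
    step1(P.Wc, m.Wc, v.Wc, G.Wc, true); step1(P.bc, m.bc, v.bc, G.bc, false);
    if (l1 > 0) {
      // proximal soft-threshold on the input layer: weights of inputs that
      // carry no persistent gradient are driven to exact zero
      const double th = lr * l1;
      P.Wc.transform([th](double w) {
        return (w > th) ? w - th : ((w < -th) ? w + th : 0.0);
      });
    }
    step1(P.Wz, m.Wz, v.Wz, G.Wz, true); step1(P.Uz, m.Uz, v.Uz, G.Uz, true); step1(P.bz, m.bz, v.bz, G.bz, false);
    step1(P.Wr, m.Wr, v.Wr, G.Wr, true); step1(P.Ur, m.Ur, v.Ur, G.Ur, true); step1(P.br, m.br, v.br, G.br, false);
    step1(P.Wn, m.Wn, v.Wn, G.Wn, true); step1(P.Un, m.Un, v.Un, G.Un, true); step1(P.bn, m.bn, v.bn, G.bn, false);
    step1(P.Wo, m.Wo, v.Wo, G.Wo, true); step1(P.bo, m.bo, v.bo, G.bo, false);
  }
};

} // namespace

// [[Rcpp::export(name = ".nn_predict")]]
arma::mat nn_predict(Rcpp::List params, Rcpp::List X) {
  Params P = unpack(params);
  mat out(X.size(), 2);
  for (int i = 0; i < X.size(); ++i) {
    FwdCache C = forward(P, Rcpp::as<mat>(X[i]));
    out.row(i) = C.probs.t();
  }
  return out;   // col 1 = p_physiological, col 2 = p_adventitious
}

// [[Rcpp::export(name = ".nn_conv_forward")]]
arma::mat nn_conv_forward(Rcpp::List params, arma::mat X) {
  Params P = unpack(params);
  FwdCache C = forward(P, X);
  return C.Sp.t();    // L x channels
}

// [[Rcpp::export(name = ".nn_hidden_state")]]
arma::vec nn_hidden_state(Rcpp::List params, arma::mat X) {
  Params P = unpack(params);
  return forward(P, X).hL;
}

// [[Rcpp::export(name = ".nn_logits")]]
arma::vec nn_logits(Rcpp::List params, arma::mat X) {
  Params P = unpack(params);
  FwdCache C = forward(P, X);
  return P.Wo * C.hL + P.bo;
}

// GRU pass alone on an already-encoded sequence S' (L x channels)
// [[Rcpp::export(name = ".nn_gru_encoded")]]
arma::vec nn_gru_encoded(Rcpp::List params, arma::mat Sprime) {
  Params P = unpack(params);
  const int L = Sprime.n_rows, hid = P.bz.n_elem;
  vec h(hid, fill::zeros);
  for (int t = 0; t < L; ++t) {
    vec x = Sprime.row(t).t();
    vec z = 1.0 / (1.0 + exp(-(P.Wz * x + P.Uz * h + P.bz)));
    vec r = 1.0 / (1.0 + exp(-(P.Wr * x + P.Ur * h + P.br)));
    vec n = tanh(P.Wn * x + P.Un * (r % h) + P.bn);
    h = (1.0 - z) % n + z % h;
  }
  return h;
}

// order: max_epochs x N matrix of 1-based shuffles generated in R.
// y: 0 = physiological (positive class), 1 = adventitious.
// [[Rcpp::export(name = ".nn_train")]]
Rcpp::List nn_train(Rcpp::List params,
                    Rcpp::List Xtr, Rcpp::IntegerVector ytr,
                    Rcpp::List Xval, Rcpp::IntegerVector yval,
                    Rcpp::IntegerMatrix order,
                    double w_pos, double lr, int max_epochs, int patience,
                    int batch_size, double weight_decay, double l1_input,
                    arma::vec col_noise, int noise_seed) {
  Params P = unpack(params);
  const int N = Xtr.size();
  Adam opt;
  opt.init(P, lr, 0.9, 0.999, 1e-8, weight_decay, l1_input);
  Grads G;
  std::vector<double> tr_loss, va_loss;
  double best = datum::inf;
  Params bestP = P;
  int wait = 0, best_epoch = 0;
  // denoising augmentation: per-presentation Gaussian input noise, drawn
  // from a dedicated deterministic stream so training stays reproducible
  std::mt19937_64 nrng(noise_seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const bool augment = any(col_noise > 0);
  for (int ep = 0; ep < max_epochs; ++ep) {
    double ep_num = 0.0, ep_den = 0.0;
    for (int start = 0; start < N; start += batch_size) {
      int end = std::min(start + batch_size, N);
      G.zero_like(P);
      double bden = 0.0;
      for (int k = start; k < end; ++k) {
        int i = order(ep, k) - 1;
        mat Xi = Rcpp::as<mat>(Xtr[i]);
        if (augment)
          for (uword j = 0; j < Xi.n_cols; ++j) {
            if (col_noise(j) == 0) continue;
            for (uword r = 0; r < Xi.n_rows; ++r)
              Xi(r, j) += col_noise(j) * gauss(nrng);
          }
        FwdCache C = forward(P, Xi);
        double wt = (ytr[i] == 0) ? w_pos : 1.0;
        backward(P, C, ytr[i], wt, G);
        double l = site_loss(C.probs, ytr[i]);
        if (!std::isfinite(l))
          Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
        ep_num += wt * l; ep_den += wt; bden += wt;
      }
      // normalise accumulated gradients to the weighted batch mean
      double s = 1.0 / bden;
      G.Wc *= s; G.bc *= s; G.Wz *= s; G.Uz *= s; G.bz *= s;
      G.Wr *= s; G.Ur *= s; G.br *= s; G.Wn *= s; G.Un *= s; G.bn *= s;
      G.Wo *= s; G.bo *= s;
      opt.step(P, G);
    }
    tr_loss.push_back(ep_num / ep_den);
    double vl = eval_loss(P, Xval, yval, w_pos);
    va_loss.push_back(vl);
    if (vl < best - 1e-7) {
      best = vl; bestP = P; wait = 0; best_epoch = ep + 1;
    } else if (++wait >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = pack(bestP),
    Rcpp::Named("train_loss") = tr_loss,
    Rcpp::Named("val_loss") = va_loss,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("epochs_run") = (int)tr_loss.size());
}
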