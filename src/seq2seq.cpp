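// Dense-connected Bi-GRU encoder / GRU decoder with Luong general attention.
// Forward, autoregressive prediction, and full BPTT gradients for the masked
// multitask objective (masked MSE on values + lambda * CE on classes).
//
// Conventions: sequences are stored feature-by-time (columns = time steps).
// GRU gate orientation follows h_t = (1 - z) * h_prev + z * h_cand.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }
static inline mat elu(mat x) {
  x.transform([](double v) { return v > 0 ? v : std::exp(v) - 1.0; });
  return x;
}
static inline mat elu_deriv(mat x) {
  x.transform([](double v) { return v > 0 ? 1.0 : std::exp(v); });
  return x;
}

struct GruParams {
  mat Wz, Uz, Wr, Ur, Wh, Uh;
  vec bz, br, bh;
};

struct GruGrads {
  mat Wz, Uz, Wr, Ur, Wh, Uh;
  vec bz, br, bh;
  void init(const GruParams& p) {
    Wz.zeros(arma::size(p.Wz)); Uz.zeros(arma::size(p.Uz));
    Wr.zeros(arma::size(p.Wr)); Ur.zeros(arma::size(p.Ur));
    Wh.zeros(arma::size(p.Wh)); Uh.zeros(arma::size(p.Uh));
    bz.zeros(p.bz.n_elem); br.zeros(p.br.n_elem); bh.zeros(p.bh.n_elem);
  }
};

struct GruCache {
  mat X, H, Z, R, Hc;
  vec h0;
};

static GruParams get_gru(const List& pl, const std::string& pre) {
  GruParams g;
  g.Wz = as<mat>(pl[pre + "_Wz"]); g.Uz = as<mat>(pl[pre + "_Uz"]);
  g.Wr = as<mat>(pl[pre + "_Wr"]); g.Ur = as<mat>(pl[pre + "_Ur"]);
  g.Wh = as<mat>(pl[pre + "_Wh"]); g.Uh = as<mat>(pl[pre + "_Uh"]);
  g.bz = as<vec>(pl[pre + "_bz"]); g.br = as<vec>(pl[pre + "_br"]);
  g.bh = as<vec>(pl[pre + "_bh"]);
  return g;
}

static void put_gru(List& out, const std::string& pre, const GruGrads& g) {
  out[pre + "_Wz"] = g.Wz; out[pre + "_Uz"] = g.Uz; out[pre + "_bz"] = g.bz;
  out[pre + "_Wr"] = g.Wr; out[pre + "_Ur"] = g.Ur; out[pre + "_br"] = g.br;
  out[pre + "_Wh"] = g.Wh; out[pre + "_Uh"] = g.Uh; out[pre + "_bh"] = g.bh;
}

// One GRU step; also used standalone through gru_step_cpp for oracle tests.
static vec gru_cell(const GruParams& p, const vec& hprev, const vec& x,
                    vec& z_out, vec& r_out, vec& hc_out) {
  z_out  = sigm(p.Wz * x + p.Uz * hprev + p.bz);
  r_out  = sigm(p.Wr * x + p.Ur * hprev + p.br);
  hc_out = arma::tanh(p.Wh * x + p.Uh * (r_out % hprev) + p.bh);
  return (1.0 - z_out) % hprev + z_out % hc_out;
}

static GruCache gru_forward(const GruParams& p, const mat& X, const vec& h0) {
  const uword L = X.n_cols, m = p.Uz.n_rows;
  GruCache c;
  c.X = X; c.h0 = h0;
  c.H.set_size(m, L); c.Z.set_size(m, L); c.R.set_size(m, L); c.Hc.set_size(m, L);
  vec h = h0, z(m), r(m), hc(m);
  for (uword t = 0; t < L; ++t) {
    h = gru_cell(p, h, X.col(t), z, r, hc);
    c.H.col(t) = h; c.Z.col(t) = z; c.R.col(t) = r; c.Hc.col(t) = hc;
  }
  return c;
}

// BPTT. dH holds dLoss/dH_t for every step (final-state gradients must be
// folded into dH's last column by the caller). Returns dX; writes dh0.
static mat gru_backward(const GruParams& p, GruGrads& g, const GruCache& c,
                        const mat& dH, vec& dh0) {
  const uword L = c.X.n_cols;
  mat dX(arma::size(c.X), arma::fill::zeros);
  vec dh(p.Uz.n_rows, arma::fill::zeros);
  for (uword tt = L; tt-- > 0;) {
    dh += dH.col(tt);
    const vec hprev = (tt == 0) ? c.h0 : vec(c.H.col(tt - 1));
    const vec z = c.Z.col(tt), r = c.R.col(tt), hc = c.Hc.col(tt);
    const vec x = c.X.col(tt);
    vec dhc = dh % z;
    vec dz  = dh % (hc - hprev);
    vec dhprev = dh % (1.0 - z);
    vec dah = dhc % (1.0 - hc % hc);
    g.Wh += dah * x.t(); g.Uh += dah * (r % hprev).t(); g.bh += dah;
    vec drh = p.Uh.t() * dah;
    vec dr = drh % hprev;
    dhprev += drh % r;
    vec daz = dz % z % (1.0 - z);
    g.Wz += daz * x.t(); g.Uz += daz * hprev.t(); g.bz += daz;
    dhprev += p.Uz.t() * daz;
    vec dar = dr % r % (1.0 - r);
    g.Wr += dar * x.t(); g.Ur += dar * hprev.t(); g.br += dar;
    dhprev += p.Ur.t() * dar;
    dX.col(tt) = p.Wz.t() * daz + p.Wr.t() * dar + p.Wh.t() * dah;
    dh = dhprev;
  }
  dh0 = dh;
  return dX;
}

static mat softmax_cols(const mat& S) {
  mat A = S;
  A.each_row() -= arma::max(S, 0);
  A = arma::exp(A);
  A.each_row() /= arma::sum(A, 0);
  return A;
}

struct ModelDims {
  arma::ivec enc_units, dec_units;
  int in_dim, di_dim, out_dim, n_class, n_layers;
  int enc_out, dec_top;
};

static ModelDims get_dims(const List& cfg) {
  ModelDims d;
  d.enc_units = as<arma::ivec>(cfg["enc_units"]);
  d.dec_units = as<arma::ivec>(cfg["dec_units"]);
  d.in_dim  = as<int>(cfg["in_dim"]);
  d.di_dim  = as<int>(cfg["di_dim"]);
  d.out_dim = as<int>(cfg["out_dim"]);
  d.n_class = as<int>(cfg["n_class"]);
  d.n_layers = d.enc_units.n_elem;
  d.enc_out = 2 * d.enc_units(d.n_layers - 1);
  d.dec_top = d.dec_units(d.n_layers - 1);
  return d;
}

struct EncState {
  std::vector<GruCache> fw, bw;     // bw caches are in reversed time
  std::vector<mat> outs;            // aligned to original time, 2m x L
  mat Henc;                         // top-layer outputs, enc_out x L
  std::vector<vec> h0_dec;          // decoder initial states per layer
};

static EncState encoder_forward(const List& pl, const ModelDims& d, const mat& X) {
  EncState st;
  const uword L = X.n_cols;
  mat stacked = X;                  // dense input: source then previous outputs
  for (int l = 0; l < d.n_layers; ++l) {
    const std::string fp = "e" + std::to_string(l + 1) + "f";
    const std::string bp = "e" + std::to_string(l + 1) + "b";
    GruParams pf = get_gru(pl, fp), pb = get_gru(pl, bp);
    const int m = d.enc_units(l);
    vec h0(m, arma::fill::zeros);
    GruCache cf = gru_forward(pf, stacked, h0);
    GruCache cb = gru_forward(pb, arma::fliplr(stacked), h0);
    mat out(2 * m, L);
    out.rows(0, m - 1) = cf.H;
    out.rows(m, 2 * m - 1) = arma::fliplr(cb.H);   // align to original time
    st.fw.push_back(std::move(cf));
    st.bw.push_back(std::move(cb));
    st.outs.push_back(out);
    vec h0d(2 * m);
    h0d.subvec(0, m - 1) = st.fw[l].H.col(L - 1);          // forward final
    h0d.subvec(m, 2 * m - 1) = st.bw[l].H.col(L - 1);      // backward final
    st.h0_dec.push_back(h0d);
    stacked = arma::join_cols(stacked, out);
  }
  st.Henc = st.outs.back();
  return st;
}

struct DecState {
  std::vector<GruCache> layers;
  mat Htop;
};

static DecState decoder_forward(const List& pl, const ModelDims& d,
                                const mat& Yin, const std::vector<vec>& h0s) {
  DecState st;
  mat stacked = Yin;
  for (int l = 0; l < d.n_layers; ++l) {
    GruParams p = get_gru(pl, "d" + std::to_string(l + 1));
    GruCache c = gru_forward(p, stacked, h0s[l]);
    stacked = arma::join_cols(stacked, c.H);
    st.layers.push_back(std::move(c));
  }
  st.Htop = st.layers.back().H;
  return st;
}

// [[Rcpp::export]]
NumericVector gru_step_cpp(const arma::mat& Wz, const arma::mat& Uz, const arma::vec& bz,
                           const arma::mat& Wr, const arma::mat& Ur, const arma::vec& br,
                           const arma::mat& Wh, const arma::mat& Uh, const arma::vec& bh,
                           const arma::vec& h_prev, const arma::vec& x) {
  GruParams p; p.Wz = Wz; p.Uz = Uz; p.bz = bz; p.Wr = Wr; p.Ur = Ur; p.br = br;
  p.Wh = Wh; p.Uh = Uh; p.bh = bh;
  vec z, r, hc;
  return wrap(gru_cell(p, h_prev, x, z, r, hc));
}

// Teacher-forced loss (+ optional gradients) for one sample.
// X: in_dim x L; Yin: (out_dim + di_dim) x T (decoder inputs, column 1 is the
// all-ones start token with DI appended); target_v, mask: length T;
// target_c: length T with classes in 0..n_class-1.
static List s2s_sample(const List& pl, const ModelDims& d,
                       const mat& X, const mat& Yin,
                       const vec& target_v, const arma::ivec& target_c,
                       const vec& mask, double lambda, bool want_grad,
                       std::map<std::string, mat>* acc_m,
                       std::map<std::string, vec>* acc_v) {
  const uword L = X.n_cols, T = Yin.n_cols;
  EncState enc = encoder_forward(pl, d, X);
  DecState dec = decoder_forward(pl, d, Yin, enc.h0_dec);

  const mat att_W = as<mat>(pl["att_W"]);
  const mat v_W = as<mat>(pl["v_W"]); const vec v_b = as<vec>(pl["v_b"]);
  const mat c_W = as<mat>(pl["c_W"]); const vec c_b = as<vec>(pl["c_b"]);

  mat Umat = att_W.t() * dec.Htop;            // enc_out x T
  mat S = enc.Henc.t() * Umat;                // L x T scores
  mat A = softmax_cols(S);                    // attention weights
  mat C = enc.Henc * A;                       // enc_out x T contexts
  mat Vin = arma::join_cols(C, dec.Htop);     // (enc_out + dec_top) x T
  mat vpre = v_W * Vin; vpre.each_col() += v_b;
  mat vout = elu(vpre);                       // 1 x T
  mat cpre = c_W * dec.Htop; cpre.each_col() += c_b;
  mat E = elu(cpre);
  mat P = softmax_cols(E);                    // n_class x T

  const double M = arma::accu(mask);
  vec verr = vout.row(0).t() - target_v;
  double mse = arma::accu(mask % arma::square(verr)) / M;
  double ce = 0.0;
  for (uword t = 0; t < T; ++t)
    ce += -std::log(std::max(P(target_c(t), t), 1e-12));
  ce /= (double)T;
  double loss = mse + lambda * ce;

  if (want_grad) {
    // heads
    mat dvout = (2.0 / M) * (mask % verr).t();          // 1 x T
    mat dvpre = dvout % elu_deriv(vpre);
    (*acc_m)["v_W"] += dvpre * Vin.t();
    (*acc_v)["v_b"] += arma::sum(dvpre, 1);
    mat dVin = v_W.t() * dvpre;
    mat dC = dVin.rows(0, d.enc_out - 1);
    mat dHtop = dVin.rows(d.enc_out, d.enc_out + d.dec_top - 1);

    mat dE = P;                                          // softmax + NLL
    for (uword t = 0; t < T; ++t) dE(target_c(t), t) -= 1.0;
    dE *= lambda / (double)T;
    mat dcpre = dE % elu_deriv(cpre);
    (*acc_m)["c_W"] += dcpre * dec.Htop.t();
    (*acc_v)["c_b"] += arma::sum(dcpre, 1);
    dHtop += c_W.t() * dcpre;

    // attention
    mat dA = enc.Henc.t() * dC;                          // L x T
    mat dHenc = dC * A.t();                              // enc_out x L
    mat dS(arma::size(dA));
    for (uword t = 0; t < T; ++t) {
      vec a = A.col(t), da = dA.col(t);
      dS.col(t) = a % (da - arma::dot(da, a));
    }
    mat dU = enc.Henc * dS;                              // enc_out x T
    dHenc += Umat * dS.t();
    (*acc_m)["att_W"] += dec.Htop * dU.t();
    dHtop += att_W * dU;

    // decoder BPTT (top to bottom; dense connections route dX rows down)
    std::vector<mat> dDecH(d.n_layers);
    for (int l = 0; l < d.n_layers; ++l)
      dDecH[l].zeros(d.dec_units(l), T);
    dDecH[d.n_layers - 1] = dHtop;
    std::vector<vec> dh0_dec(d.n_layers);
    const int yin_rows = d.out_dim + d.di_dim;
    for (int l = d.n_layers - 1; l >= 0; --l) {
      const std::string pre = "d" + std::to_string(l + 1);
      GruParams p = get_gru(pl, pre);
      GruGrads g; g.init(p);
      vec dh0;
      mat dX = gru_backward(p, g, dec.layers[l], dDecH[l], dh0);
      dh0_dec[l] = dh0;
      int row = yin_rows;                               // skip teacher inputs
      for (int k = 0; k < l; ++k) {
        dDecH[k] += dX.rows(row, row + d.dec_units(k) - 1);
        row += d.dec_units(k);
      }
      (*acc_m)[pre + "_Wz"] += g.Wz; (*acc_m)[pre + "_Uz"] += g.Uz; (*acc_v)[pre + "_bz"] += g.bz;
      (*acc_m)[pre + "_Wr"] += g.Wr; (*acc_m)[pre + "_Ur"] += g.Ur; (*acc_v)[pre + "_br"] += g.br;
      (*acc_m)[pre + "_Wh"] += g.Wh; (*acc_m)[pre + "_Uh"] += g.Uh; (*acc_v)[pre + "_bh"] += g.bh;
    }

    // encoder BPTT
    std::vector<mat> dEncOut(d.n_layers);
    for (int l = 0; l < d.n_layers; ++l)
      dEncOut[l].zeros(2 * d.enc_units(l), L);
    dEncOut[d.n_layers - 1] = dHenc;
    for (int l = d.n_layers - 1; l >= 0; --l) {
      const int m = d.enc_units(l);
      mat dHf = dEncOut[l].rows(0, m - 1);
      mat dHb_orig = dEncOut[l].rows(m, 2 * m - 1);
      // decoder initial-state gradients: [fw final; bw final]
      dHf.col(L - 1) += dh0_dec[l].subvec(0, m - 1);
      mat dHb = arma::fliplr(dHb_orig);                 // to reversed time
      dHb.col(L - 1) += dh0_dec[l].subvec(m, 2 * m - 1);
      const std::string fp = "e" + std::to_string(l + 1) + "f";
      const std::string bp = "e" + std::to_string(l + 1) + "b";
      GruParams pf = get_gru(pl, fp), pb = get_gru(pl, bp);
      GruGrads gf, gb; gf.init(pf); gb.init(pb);
      vec dh0f, dh0b;
      mat dXf = gru_backward(pf, gf, enc.fw[l], dHf, dh0f);
      mat dXb_rev = gru_backward(pb, gb, enc.bw[l], dHb, dh0b);
      mat dX = dXf + arma::fliplr(dXb_rev);
      int row = d.in_dim;                               // skip the source rows
      for (int k = 0; k < l; ++k) {
        dEncOut[k] += dX.rows(row, row + 2 * d.enc_units(k) - 1);
        row += 2 * d.enc_units(k);
      }
      (*acc_m)[fp + "_Wz"] += gf.Wz; (*acc_m)[fp + "_Uz"] += gf.Uz; (*acc_v)[fp + "_bz"] += gf.bz;
      (*acc_m)[fp + "_Wr"] += gf.Wr; (*acc_m)[fp + "_Ur"] += gf.Ur; (*acc_v)[fp + "_br"] += gf.br;
      (*acc_m)[fp + "_Wh"] += gf.Wh; (*acc_m)[fp + "_Uh"] += gf.Uh; (*acc_v)[fp + "_bh"] += gf.bh;
      (*acc_m)[bp + "_Wz"] += gb.Wz; (*acc_m)[bp + "_Uz"] += gb.Uz; (*acc_v)[bp + "_bz"] += gb.bz;
      (*acc_m)[bp + "_Wr"] += gb.Wr; (*acc_m)[bp + "_Ur"] += gb.Ur; (*acc_v)[bp + "_br"] += gb.br;
      (*acc_m)[bp + "_Wh"] += gb.Wh; (*acc_m)[bp + "_Uh"] += gb.Uh; (*acc_v)[bp + "_bh"] += gb.bh;
    }
  }

  return List::create(_["loss"] = loss, _["mse"] = mse, _["ce"] = ce,
                      _["values"] = vout.row(0).t(), _["probs"] = P.t());
}

// [[Rcpp::export]]
List s2s_batch_cpp(List params, List cfg, List samples, double lambda,
                   bool want_grad) {
  ModelDims d = get_dims(cfg);
  const int N = samples.size();
  std::map<std::string, mat> acc_m;
  std::map<std::string, vec> acc_v;
  // biases are identified by name (suffix "_b?") so classification cannot
  // drift when R turns a length-1 vector into a 1x1 matrix or back
  auto is_bias = [](const std::string& n) {
    size_t p = n.rfind("_b");
    return p != std::string::npos && p + 3 >= n.size();
  };
  if (want_grad) {
    CharacterVector nm = params.names();
    for (int i = 0; i < nm.size(); ++i) {
      std::string n = as<std::string>(nm[i]);
      if (is_bias(n)) acc_v[n] = vec(as<vec>(params[n]).n_elem, arma::fill::zeros);
      else acc_m[n] = mat(arma::size(as<mat>(params[n])), arma::fill::zeros);
    }
  }
  double loss = 0, mse = 0, ce = 0;
  for (int j = 0; j < N; ++j) {
    List s = samples[j];
    List r = s2s_sample(params, d,
                        as<mat>(s["X"]), as<mat>(s["Yin"]),
                        as<vec>(s["target_v"]), as<arma::ivec>(s["target_c"]),
                        as<vec>(s["mask"]), lambda, want_grad,
                        want_grad ? &acc_m : nullptr,
                        want_grad ? &acc_v : nullptr);
    loss += as<double>(r["loss"]); mse += as<double>(r["mse"]); ce += as<double>(r["ce"]);
  }
  loss /= N; mse /= N; ce /= N;
  List out = List::create(_["loss"] = loss, _["mse"] = mse, _["ce"] = ce);
  if (want_grad) {
    List g;
    CharacterVector nm = params.names();
    for (int i = 0; i < nm.size(); ++i) {
      std::string n = as<std::string>(nm[i]);
      if (acc_m.count(n)) {
        g[n] = mat(acc_m[n] / (double)N);
      } else {
        vec v = acc_v[n] / (double)N;
        g[n] = NumericVector(v.begin(), v.end());
      }
    }
    out["grads"] = g;
  }
  return out;
}

// Teacher-forced forward pass for one sample (no gradients).
// [[Rcpp::export]]
List s2s_forward_cpp(List params, List cfg, const arma::mat& X,
                     const arma::mat& Yin, const arma::vec& target_v,
                     const arma::ivec& target_c, const arma::vec& mask,
                     double lambda) {
  ModelDims d = get_dims(cfg);
  return s2s_sample(params, d, X, Yin, target_v, target_c, mask, lambda,
                    false, nullptr, nullptr);
}

// Autoregressive decoding: exactly T steps, feeding back [value; class probs].
// Returns values (T), class probabilities (T x n_class), attention map (T x L).
// [[Rcpp::export]]
List s2s_predict_cpp(List params, List cfg, const arma::mat& X,
                     const arma::vec& xdi, int T) {
  ModelDims d = get_dims(cfg);
  const uword L = X.n_cols;
  EncState enc = encoder_forward(params, d, X);

  std::vector<GruParams> dp;
  for (int l = 0; l < d.n_layers; ++l)
    dp.push_back(get_gru(params, "d" + std::to_string(l + 1)));
  const mat att_W = as<mat>(params["att_W"]);
  const mat v_W = as<mat>(params["v_W"]); const vec v_b = as<vec>(params["v_b"]);
  const mat c_W = as<mat>(params["c_W"]); const vec c_b = as<vec>(params["c_b"]);

  std::vector<vec> h = enc.h0_dec;
  vec y_prev(d.out_dim, arma::fill::ones);              // start token
  vec values(T);
  mat probs(T, d.n_class), amap(T, L);
  vec z, r, hc;
  for (int t = 0; t < T; ++t) {
    vec x = (d.di_dim > 0) ? arma::join_cols(y_prev, xdi) : y_prev;
    for (int l = 0; l < d.n_layers; ++l) {
      h[l] = gru_cell(dp[l], h[l], x, z, r, hc);
      x = arma::join_cols(x, h[l]);
    }
    const vec& ht = h[d.n_layers - 1];
    vec u = att_W.t() * ht;
    vec s = enc.Henc.t() * u;
    s -= s.max();
    vec a = arma::exp(s); a /= arma::accu(a);
    vec ctx = enc.Henc * a;
    vec vin = arma::join_cols(ctx, ht);
    double vpre = arma::as_scalar(v_W * vin) + v_b(0);
    double vout = vpre > 0 ? vpre : std::exp(vpre) - 1.0;
    vec e = elu(mat(c_W * ht + c_b));
    e -= e.max();
    vec p = arma::exp(e); p /= arma::accu(p);
    values(t) = vout;
    probs.row(t) = p.t();
    amap.row(t) = a.t();
    y_prev = arma::join_cols(vec{vout}, p);
  }
  return List::create(_["values"] = values, _["probs"] = probs,
                      _["attention"] = amap);
}
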