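#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Inner training loop for one cluster of per-gene networks. The math is
// identical to the R reference engine (see train_once_r): per-task forward
// and backward passes for the batch-mean (or batch-sum) squared error, L1
// subgradients on the layer weights, the trace-norm subgradient U V^T of
// each shared-layer stack recomputed by thin SVD at every step, and Adam
// updates. Batch index streams are pre-sampled in R so the two engines are
// bit-comparable and fully seeded.

using namespace arma;

namespace {

struct Task {
  mat w_agg;            // 3 x n
  mat W1, W2, W3, W4;   // n x 64, 64 x 32, 32 x 16, 16 x 1
  vec b1, b2, b3, b4;
};

struct AdamSlot {
  mat m, v;
};

inline mat act_f(const mat &z, int code) {
  switch (code) {
    case 0: return clamp(z, 0.0, datum::inf) + 0.01 * clamp(z, -datum::inf, 0.0);
    case 1: return clamp(z, 0.0, datum::inf);
    case 2: return tanh(z);
    default: return z;
  }
}

inline mat act_df(const mat &z, int code) {
  switch (code) {
    case 0: return conv_to<mat>::from(z > 0) + 0.01 * conv_to<mat>::from(z <= 0);
    case 1: return conv_to<mat>::from(z > 0);
    case 2: return 1.0 - square(tanh(z));
    default: return ones<mat>(z.n_rows, z.n_cols);
  }
}

void adam_step(mat &p, const mat &g, AdamSlot &s, double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  s.m = b1 * s.m + (1 - b1) * g;
  s.v = b2 * s.v + (1 - b2) * (g % g);
  mat mhat = s.m / (1 - std::pow(b1, t));
  mat vhat = s.v / (1 - std::pow(b2, t));
  p -= lr * mhat / (sqrt(vhat) + eps);
}

}  // namespace

// [[Rcpp::export(name = ".train_cluster_cpp")]]
Rcpp::List train_cluster_cpp(Rcpp::List features, Rcpp::List targets,
                             Rcpp::List init_params, Rcpp::List index_streams,
                             double lambda_l1, double gamma_trace,
                             double learning_rate, int activation_code,
                             bool mse_batch_mean, bool share_fc1, bool share_fc2,
                             bool penalize_biases) {
  const int T = features.size();
  std::vector<mat> X(T);
  std::vector<vec> y(T);
  std::vector<umat> idx(T);
  std::vector<Task> tasks(T);
  for (int i = 0; i < T; ++i) {
    X[i] = Rcpp::as<mat>(features[i]);
    y[i] = Rcpp::as<vec>(targets[i]);
    idx[i] = Rcpp::as<umat>(index_streams[i]);  // steps x b, 0-based
    Rcpp::List p = init_params[i];
    tasks[i].w_agg = Rcpp::as<mat>(p["w_agg"]);
    tasks[i].W1 = Rcpp::as<mat>(p["W1"]); tasks[i].b1 = Rcpp::as<vec>(p["b1"]);
    tasks[i].W2 = Rcpp::as<mat>(p["W2"]); tasks[i].b2 = Rcpp::as<vec>(p["b2"]);
    tasks[i].W3 = Rcpp::as<mat>(p["W3"]); tasks[i].b3 = Rcpp::as<vec>(p["b3"]);
    tasks[i].W4 = Rcpp::as<mat>(p["W4"]); tasks[i].b4 = Rcpp::as<vec>(p["b4"]);
  }
  const int n = tasks[0].w_agg.n_cols;
  const int steps = idx[0].n_rows;

  // Adam state: 9 slots per task in a fixed order
  std::vector<std::vector<AdamSlot> > st(T, std::vector<AdamSlot>(9));
  for (int i = 0; i < T; ++i) {
    mat zagg = zeros<mat>(3, n);
    st[i][0] = {zagg, zagg};
    st[i][1] = {zeros<mat>(size(tasks[i].W1)), zeros<mat>(size(tasks[i].W1))};
    st[i][2] = {zeros<mat>(tasks[i].b1.n_elem, 1), zeros<mat>(tasks[i].b1.n_elem, 1)};
    st[i][3] = {zeros<mat>(size(tasks[i].W2)), zeros<mat>(size(tasks[i].W2))};
    st[i][4] = {zeros<mat>(tasks[i].b2.n_elem, 1), zeros<mat>(tasks[i].b2.n_elem, 1)};
    st[i][5] = {zeros<mat>(size(tasks[i].W3)), zeros<mat>(size(tasks[i].W3))};
    st[i][6] = {zeros<mat>(tasks[i].b3.n_elem, 1), zeros<mat>(tasks[i].b3.n_elem, 1)};
    st[i][7] = {zeros<mat>(size(tasks[i].W4)), zeros<mat>(size(tasks[i].W4))};
    st[i][8] = {zeros<mat>(1, 1), zeros<mat>(1, 1)};
  }

  std::vector<Task> grads(T);
  for (int t = 0; t < steps; ++t) {
    for (int i = 0; i < T; ++i) {
      Task &p = tasks[i];
      const urowvec rows = idx[i].row(t);
      const uvec rows_v = conv_to<uvec>::from(rows);
      mat Xb = X[i].rows(rows_v);
      vec yb = y[i].elem(rows_v);
      const int b = Xb.n_rows;
      mat Xa = Xb.cols(0, n - 1), Xm = Xb.cols(n, 2 * n - 1), Xx = Xb.cols(2 * n, 3 * n - 1);
      mat Z0 = Xa.each_row() % p.w_agg.row(0) + Xm.each_row() % p.w_agg.row(1) +
               Xx.each_row() % p.w_agg.row(2);
      mat H0 = act_f(Z0, activation_code);
      mat Z1 = H0 * p.W1; Z1.each_row() += p.b1.t(); mat H1 = act_f(Z1, activation_code);
      mat Z2 = H1 * p.W2; Z2.each_row() += p.b2.t(); mat H2 = act_f(Z2, activation_code);
      mat Z3 = H2 * p.W3; Z3.each_row() += p.b3.t(); mat H3 = act_f(Z3, activation_code);
      vec pred = H3 * p.W4 + p.b4(0);
      if (!pred.is_finite())
        Rcpp::stop("non-finite predictions during training; lower the learning rate");

      vec dpred = 2.0 * (pred - yb);
      if (mse_batch_mean) dpred /= (double)b;
      mat dp(dpred);
      Task &g = grads[i];
      g.W4 = H3.t() * dp; g.b4 = vec(1); g.b4(0) = accu(dp);
      mat dH3 = dp * p.W4.t();
      mat dZ3 = dH3 % act_df(Z3, activation_code);
      g.W3 = H2.t() * dZ3; g.b3 = sum(dZ3, 0).t();
      mat dH2 = dZ3 * p.W3.t();
      mat dZ2 = dH2 % act_df(Z2, activation_code);
      g.W2 = H1.t() * dZ2; g.b2 = sum(dZ2, 0).t();
      mat dH1 = dZ2 * p.W2.t();
      mat dZ1 = dH1 % act_df(Z1, activation_code);
      g.W1 = H0.t() * dZ1; g.b1 = sum(dZ1, 0).t();
      mat dH0 = dZ1 * p.W1.t();
      mat dZ0 = dH0 % act_df(Z0, activation_code);
      g.w_agg = join_vert(sum(dZ0 % Xa, 0), sum(dZ0 % Xm, 0), sum(dZ0 % Xx, 0));

      if (lambda_l1 > 0) {
        g.w_agg += lambda_l1 * sign(p.w_agg);
        g.W1 += lambda_l1 * sign(p.W1);
        g.W2 += lambda_l1 * sign(p.W2);
        g.W3 += lambda_l1 * sign(p.W3);
        g.W4 += lambda_l1 * sign(p.W4);
        if (penalize_biases) {
          g.b1 += lambda_l1 * sign(p.b1);
          g.b2 += lambda_l1 * sign(p.b2);
          g.b3 += lambda_l1 * sign(p.b3);
          g.b4 += lambda_l1 * sign(p.b4);
        }
      }
    }

    if (gamma_trace > 0) {
      for (int layer = 0; layer < 2; ++layer) {
        if ((layer == 0 && !share_fc1) || (layer == 1 && !share_fc2)) continue;
        const int wrows = (layer == 0) ? tasks[0].W1.n_rows : tasks[0].W2.n_rows;
        const int wcols = (layer == 0) ? tasks[0].W1.n_cols : tasks[0].W2.n_cols;
        const int wlen = wrows * wcols;
        const int blen = penalize_biases ? wcols : 0;
        mat stack(wlen + blen, T);
        for (int i = 0; i < T; ++i) {
          const mat &W = (layer == 0) ? tasks[i].W1 : tasks[i].W2;
          stack.submat(0, i, wlen - 1, i) = vectorise(W);
          if (blen) {
            const vec &bb = (layer == 0) ? tasks[i].b1 : tasks[i].b2;
            stack.submat(wlen, i, wlen + blen - 1, i) = bb;
          }
        }
        mat U, V; vec s;
        if (!svd_econ(U, s, V, stack))
          Rcpp::stop("SVD of the shared-layer stack failed");
        mat G = U * V.t();
        for (int i = 0; i < T; ++i) {
          mat gi = reshape(G.submat(0, i, wlen - 1, i), wrows, wcols);
          if (layer == 0) grads[i].W1 += gamma_trace * gi;
          else grads[i].W2 += gamma_trace * gi;
          if (blen) {
            vec gb = G.submat(wlen, i, wlen + blen - 1, i);
            if (layer == 0) grads[i].b1 += gamma_trace * gb;
            else grads[i].b2 += gamma_trace * gb;
          }
        }
      }
    }

    const double tt = t + 1;
    for (int i = 0; i < T; ++i) {
      Task &p = tasks[i];
      Task &g = grads[i];
      adam_step(p.w_agg, g.w_agg, st[i][0], learning_rate, tt);
      adam_step(p.W1, g.W1, st[i][1], learning_rate, tt);
      { mat bm(p.b1), gm(g.b1); adam_step(bm, gm, st[i][2], learning_rate, tt); p.b1 = bm.col(0); }
      adam_step(p.W2, g.W2, st[i][3], learning_rate, tt);
      { mat bm(p.b2), gm(g.b2); adam_step(bm, gm, st[i][4], learning_rate, tt); p.b2 = bm.col(0); }
      adam_step(p.W3, g.W3, st[i][5], learning_rate, tt);
      { mat bm(p.b3), gm(g.b3); adam_step(bm, gm, st[i][6], learning_rate, tt); p.b3 = bm.col(0); }
      adam_step(p.W4, g.W4, st[i][7], learning_rate, tt);
      { mat bm(p.b4), gm(g.b4); adam_step(bm, gm, st[i][8], learning_rate, tt); p.b4 = bm.col(0); }
    }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::List out(T);
  for (int i = 0; i < T; ++i) {
    out[i] = Rcpp::List::create(
        Rcpp::Named("w_agg") = tasks[i].w_agg,
        Rcpp::Named("W1") = tasks[i].W1, Rcpp::Named("b1") = tasks[i].b1,
        Rcpp::Named("W2") = tasks[i].W2, Rcpp::Named("b2") = tasks[i].b2,
        Rcpp::Named("W3") = tasks[i].W3, Rcpp::Named("b3") = tasks[i].b3,
        Rcpp::Named("W4") = tasks[i].W4, Rcpp::Named("b4") = tasks[i].b4);
  }
  return out;
}
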