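// Siamese edge-convolution encoder for streamlines, with hand-written
// backpropagation and Adam, plus the Student's-t / KL self-training
// gradients of the clustering stage.
//
// Layout conventions (performance: Armadillo is column-major):
//   * a batch of B fibers with np points is a feature matrix F of size
//     C x (B*np); point t of fiber f sits in column f*np + t;
//   * edge-conv weights We[l] are C_out x (2*C_in), biases C_out x 1;
//     per edge the input column is [x_center; x_neighbor - x_center];
//   * embeddings are ne x B internally, transposed at the R boundary.
//
// The along-fiber graph `nb` (np x k, 0-based) is fixed and shared by all
// fibers: neighbors are the k sequence-nearest point indices.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct NetCfg {
  int np, k, L, cg, f1, f2, ne;
  std::vector<int> widths;
  double slope;
};

static NetCfg parse_cfg(const Rcpp::List& cfgl) {
  NetCfg c;
  c.np = Rcpp::as<int>(cfgl["np"]);
  c.k = Rcpp::as<int>(cfgl["k"]);
  Rcpp::IntegerVector w = cfgl["widths"];
  c.widths = std::vector<int>(w.begin(), w.end());
  c.L = static_cast<int>(c.widths.size());
  c.cg = Rcpp::as<int>(cfgl["cg"]);
  Rcpp::IntegerVector fc = cfgl["fc"];
  c.f1 = fc[0];
  c.f2 = fc[1];
  c.ne = fc[2];
  c.slope = Rcpp::as<double>(cfgl["slope"]);
  return c;
}

static std::vector<mat> parse_params(const Rcpp::List& pl) {
  std::vector<mat> P;
  P.reserve(pl.size());
  for (int i = 0; i < pl.size(); ++i) P.push_back(Rcpp::as<mat>(pl[i]));
  return P;
}

static Rcpp::List wrap_params(const std::vector<mat>& P, const Rcpp::List& proto) {
  Rcpp::List out(P.size());
  for (size_t i = 0; i < P.size(); ++i) out[i] = P[i];
  out.attr("names") = proto.attr("names");
  return out;
}

// param order: We1,be1,...,WeL,beL, Wg,bg, Wf1,bf1, Wf2,bf2, Wf3,bf3
static inline int n_params(const NetCfg& c) { return 2 * c.L + 8; }

struct Cache {
  std::vector<mat> F;           // F[0] = input (3 x N); F[l] = output of layer l
  std::vector<mat> Ein;         // cached edge inputs per layer, 2C x N*k
  std::vector<Mat<int> > amax;  // argmax edge slot, C_out x N
  std::vector<mat> dact;        // activation derivative at the max edge
  std::vector<int> cidx, nidx;  // per-edge center / neighbor point columns
  mat Gcat;                     // concat of layer outputs, sumC x N
  mat dactg;                    // cg x N
  Mat<int> gmax;                // argmax point per fiber, cg x B
  mat g, h1, h2, d1, d2, z;
};

// per-edge center/neighbor column indices for a batch of B fibers
static void edge_indices(const imat& nb, int np, int B, std::vector<int>& cidx,
                         std::vector<int>& nidx) {
  const int k = static_cast<int>(nb.n_cols);
  cidx.resize(static_cast<size_t>(B) * np * k);
  nidx.resize(cidx.size());
  size_t e = 0;
  for (int f = 0; f < B; ++f)
    for (int t = 0; t < np; ++t)
      for (int s = 0; s < k; ++s, ++e) {
        cidx[e] = f * np + t;
        nidx[e] = f * np + nb(t, s);
      }
}

static mat build_ein(const mat& F, const std::vector<int>& cidx,
                     const std::vector<int>& nidx) {
  const int C = static_cast<int>(F.n_rows);
  const size_t E = cidx.size();
  mat Ein(2 * C, E);
  const double* fp = F.memptr();
  double* ep = Ein.memptr();
  for (size_t e = 0; e < E; ++e) {
    const double* fc = fp + static_cast<size_t>(cidx[e]) * C;
    const double* fn = fp + static_cast<size_t>(nidx[e]) * C;
    double* out = ep + e * 2 * C;
    for (int c = 0; c < C; ++c) {
      out[c] = fc[c];
      out[C + c] = fn[c] - fc[c];
    }
  }
  return Ein;
}

// forward pass; fills cache (always: cost is dominated by the GEMMs)
static void forward(const std::vector<mat>& P, const NetCfg& cfg, const imat& nb,
                    const mat& X, int B, Cache& c) {
  const int np = cfg.np, k = cfg.k, N = B * np;
  c.F.assign(cfg.L + 1, mat());
  c.Ein.assign(cfg.L, mat());
  c.amax.assign(cfg.L, Mat<int>());
  c.dact.assign(cfg.L, mat());
  edge_indices(nb, np, B, c.cidx, c.nidx);
  c.F[0] = X;
  for (int l = 0; l < cfg.L; ++l) {
    const mat& We = P[2 * l];
    const mat& be = P[2 * l + 1];
    const int Co = static_cast<int>(We.n_rows);
    c.Ein[l] = build_ein(c.F[l], c.cidx, c.nidx);
    mat H = We * c.Ein[l];
    H.each_col() += be.col(0);
    mat O(Co, N);
    Mat<int> am(Co, N);
    mat da(Co, N);
    const double* h = H.memptr();
    double* op = O.memptr();
    int* ap = am.memptr();
    double* dp = da.memptr();
    for (int r = 0; r < N; ++r)
      for (int ch = 0; ch < Co; ++ch) {
        double best = -datum::inf;
        int bs = 0;
        for (int s = 0; s < k; ++s) {
          const double v = h[(static_cast<size_t>(r) * k + s) * Co + ch];
          if (v > best) { best = v; bs = s; }
        }
        // leaky ReLU is monotone: max-then-activate == activate-then-max
        const size_t o = static_cast<size_t>(r) * Co + ch;
        op[o] = best > 0 ? best : cfg.slope * best;
        ap[o] = bs;
        dp[o] = best > 0 ? 1.0 : cfg.slope;
      }
    c.F[l + 1] = std::move(O);
    c.amax[l] = std::move(am);
    c.dact[l] = std::move(da);
  }
  // global point descriptor on the concatenated edge-conv outputs
  int sumC = 0;
  for (int l = 0; l < cfg.L; ++l) sumC += cfg.widths[l];
  c.Gcat.set_size(sumC, N);
  int off = 0;
  for (int l = 0; l < cfg.L; ++l) {
    c.Gcat.rows(off, off + cfg.widths[l] - 1) = c.F[l + 1];
    off += cfg.widths[l];
  }
  const mat& Wg = P[2 * cfg.L];
  const mat& bg = P[2 * cfg.L + 1];
  mat Pre = Wg * c.Gcat;
  Pre.each_col() += bg.col(0);
  c.dactg = conv_to<mat>::from(Pre > 0) * (1.0 - cfg.slope) + cfg.slope;
  mat Pfeat = Pre;
  Pfeat.transform([&](double v) { return v > 0 ? v : cfg.slope * v; });
  // global max-pool over points -> per-fiber descriptor
  c.g.set_size(cfg.cg, B);
  c.gmax.set_size(cfg.cg, B);
  for (int f = 0; f < B; ++f)
    for (int ch = 0; ch < cfg.cg; ++ch) {
      double best = -datum::inf;
      int bt = 0;
      for (int t = 0; t < np; ++t) {
        const double v = Pfeat(ch, f * np + t);
        if (v > best) { best = v; bt = t; }
      }
      c.g(ch, f) = best;
      c.gmax(ch, f) = bt;
    }
  const mat &Wf1 = P[2 * cfg.L + 2], &bf1 = P[2 * cfg.L + 3];
  const mat &Wf2 = P[2 * cfg.L + 4], &bf2 = P[2 * cfg.L + 5];
  const mat &Wf3 = P[2 * cfg.L + 6], &bf3 = P[2 * cfg.L + 7];
  mat a1 = Wf1 * c.g;
  a1.each_col() += bf1.col(0);
  c.d1 = conv_to<mat>::from(a1 > 0) * (1.0 - cfg.slope) + cfg.slope;
  c.h1 = a1;
  c.h1.transform([&](double v) { return v > 0 ? v : cfg.slope * v; });
  mat a2 = Wf2 * c.h1;
  a2.each_col() += bf2.col(0);
  c.d2 = conv_to<mat>::from(a2 > 0) * (1.0 - cfg.slope) + cfg.slope;
  c.h2 = a2;
  c.h2.transform([&](double v) { return v > 0 ? v : cfg.slope * v; });
  c.z = Wf3 * c.h2;
  c.z.each_col() += bf3.col(0);
}

// backward pass: dz (ne x B) -> gradients G (same shapes as P)
static void backward(const std::vector<mat>& P, const NetCfg& cfg, const imat& nb,
                     const Cache& c, const mat& dz, std::vector<mat>& G) {
  const int np = cfg.np, k = cfg.k;
  const int B = static_cast<int>(c.g.n_cols), N = B * np;
  G.assign(n_params(cfg), mat());
  const mat &Wf1 = P[2 * cfg.L + 2], &Wf2 = P[2 * cfg.L + 4], &Wf3 = P[2 * cfg.L + 6];
  G[2 * cfg.L + 6] = dz * c.h2.t();
  G[2 * cfg.L + 7] = sum(dz, 1);
  mat dh2 = (Wf3.t() * dz) % c.d2;
  G[2 * cfg.L + 4] = dh2 * c.h1.t();
  G[2 * cfg.L + 5] = sum(dh2, 1);
  mat dh1 = (Wf2.t() * dh2) % c.d1;
  G[2 * cfg.L + 2] = dh1 * c.g.t();
  G[2 * cfg.L + 3] = sum(dh1, 1);
  mat dg = Wf1.t() * dh1;  // cg x B
  mat dPfeat(cfg.cg, N, fill::zeros);
  for (int f = 0; f < B; ++f)
    for (int ch = 0; ch < cfg.cg; ++ch)
      dPfeat(ch, f * np + c.gmax(ch, f)) += dg(ch, f);
  mat dPre = dPfeat % c.dactg;
  const mat& Wg = P[2 * cfg.L];
  G[2 * cfg.L] = dPre * c.Gcat.t();
  G[2 * cfg.L + 1] = sum(dPre, 1);
  mat dGcat = Wg.t() * dPre;  // sumC x N
  // walk the edge-conv stack backwards; each layer's output feeds both the
  // next layer and the concatenated descriptor
  std::vector<int> offs(cfg.L);
  int off = 0;
  for (int l = 0; l < cfg.L; ++l) { offs[l] = off; off += cfg.widths[l]; }
  mat dF_up;  // gradient w.r.t. layer l's output coming from layer l+1
  for (int l = cfg.L - 1; l >= 0; --l) {
    const int Co = cfg.widths[l];
    mat dO = dGcat.rows(offs[l], offs[l] + Co - 1);
    if (l < cfg.L - 1) dO += dF_up;
    const mat& We = P[2 * l];
    const int Ci = static_cast<int>(c.F[l].n_rows);
    mat dHe(Co, static_cast<uword>(N) * k, fill::zeros);
    {
      double* hp = dHe.memptr();
      const double* dop = dO.memptr();
      const int* ap = c.amax[l].memptr();
      const double* dp = c.dact[l].memptr();
      for (int r = 0; r < N; ++r)
        for (int ch = 0; ch < Co; ++ch) {
          const size_t o = static_cast<size_t>(r) * Co + ch;
          hp[(static_cast<size_t>(r) * k + ap[o]) * Co + ch] = dop[o] * dp[o];
        }
    }
    G[2 * l] = dHe * c.Ein[l].t();
    G[2 * l + 1] = sum(dHe, 1);
    mat dEin = We.t() * dHe;  // 2Ci x N*k
    mat dF(Ci, N, fill::zeros);
    {
      const double* de = dEin.memptr();
      double* dfp = dF.memptr();
      const size_t E = c.cidx.size();
      for (size_t e = 0; e < E; ++e) {
        const double* col = de + e * 2 * Ci;
        double* fc = dfp + static_cast<size_t>(c.cidx[e]) * Ci;
        double* fn = dfp + static_cast<size_t>(c.nidx[e]) * Ci;
        for (int ch = 0; ch < Ci; ++ch) {
          fc[ch] += col[ch] - col[Ci + ch];
          fn[ch] += col[Ci + ch];
        }
      }
    }
    dF_up = std::move(dF);
  }
}

// stack batch fibers (np x 3 slices) into a 3 x (B*np) feature matrix
static mat stack_batch(const cube& fibers, const std::vector<int>& idx, int np) {
  const int B = static_cast<int>(idx.size());
  mat X(3, static_cast<uword>(B) * np);
  for (int f = 0; f < B; ++f) {
    const mat& S = fibers.slice(idx[f]);  // np x 3
    for (int t = 0; t < np; ++t) X.col(f * np + t) = S.row(t).t();
  }
  return X;
}

// reversal-symmetric accumulation: pair the i-th and (n-1-i)-th terms
// first so the sum is bit-identical under point-order reversal of either
// fiber (addition is commutative in IEEE floating point)
static double sym_mean_np(const std::vector<double>& t) {
  const size_t n = t.size();
  double s = 0.0;
  for (size_t i = 0; i < n / 2; ++i) s += t[i] + t[n - 1 - i];
  if (n % 2) s += t[n / 2];
  return s / static_cast<double>(n);
}

static double mdf_np(const mat& A, const mat& Bm) {
  const uword np = A.n_rows;
  std::vector<double> td(np), tf(np);
  for (uword t = 0; t < np; ++t) {
    td[t] = norm(A.row(t) - Bm.row(t), 2);
    tf[t] = norm(A.row(t) - Bm.row(np - 1 - t), 2);
  }
  return std::min(sym_mean_np(td), sym_mean_np(tf));
}

// pretext MSE between embedding distance and the MDF pseudo-label;
// batch is [a_1..a_m, b_1..b_m]; returns loss, accumulates dz
static double pretext_loss_grad(const mat& z, const vec& y, mat& dz) {
  const int m = static_cast<int>(y.n_elem);
  dz.zeros(z.n_rows, z.n_cols);
  double L = 0;
  for (int i = 0; i < m; ++i) {
    vec u = z.col(i) - z.col(m + i);
    const double d = norm(u, 2);
    const double r = d - y(i);
    L += r * r;
    if (d > 1e-12) {
      vec grd = (2.0 * r / m) * (u / d);
      dz.col(i) += grd;
      dz.col(m + i) -= grd;
    }
  }
  return L / m;
}

// KL(P||Q) self-training loss with Student's-t kernel (one degree of
// freedom); adds lambda-scaled gradients into dz and dmu
static double kl_loss_grad(const mat& z, const mat& mu, const mat& Pt, double lambda,
                           mat& dz, mat& dmu) {
  const int B = static_cast<int>(z.n_cols), nc = static_cast<int>(mu.n_cols);
  double L = 0;
  for (int i = 0; i < B; ++i) {
    vec w(nc);
    for (int j = 0; j < nc; ++j) {
      const double d2 = accu(square(z.col(i) - mu.col(j)));
      w(j) = 1.0 / (1.0 + d2);
    }
    const double S = accu(w);
    vec q = w / S;
    for (int j = 0; j < nc; ++j) {
      const double p = Pt(j, i);
      if (p > 0) L += p * std::log(p / std::max(q(j), 1e-12));
      const double coef = 2.0 * w(j) * (p - q(j)) * lambda / B;
      vec diff = z.col(i) - mu.col(j);
      dz.col(i) += coef * diff;
      dmu.col(j) -= coef * diff;
    }
  }
  return L / B;
}

struct Adam {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  void init_like(const std::vector<mat>& P) {
    m.clear();
    v.clear();
    for (const mat& p : P) {
      m.push_back(mat(p.n_rows, p.n_cols, fill::zeros));
      v.push_back(mat(p.n_rows, p.n_cols, fill::zeros));
    }
  }
  void step(std::vector<mat>& P, const std::vector<mat>& G, double lr, long t) {
    const double c1 = 1.0 - std::pow(b1, static_cast<double>(t));
    const double c2 = 1.0 - std::pow(b2, static_cast<double>(t));
    for (size_t i = 0; i < P.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * G[i];
      v[i] = b2 * v[i] + (1 - b2) * square(G[i]);
      P[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

// [[Rcpp::export]]
arma::mat cpp_encode(const arma::cube& fibers, Rcpp::List params, Rcpp::List cfgl,
                     const arma::imat& nb, int chunk = 512) {
  NetCfg cfg = parse_cfg(cfgl);
  std::vector<mat> P = parse_params(params);
  const int n = static_cast<int>(fibers.n_slices);
  mat Z(n, cfg.ne);
  Cache c;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(n, s + chunk);
    std::vector<int> idx(e - s);
    for (int i = s; i < e; ++i) idx[i - s] = i;
    mat X = stack_batch(fibers, idx, cfg.np);
    forward(P, cfg, nb, X, e - s, c);
    Z.rows(s, e - 1) = c.z.t();
  }
  return Z;
}

// single-batch loss and analytic gradients (used by tests against finite
// differences, and by pretrain_loss)
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(const arma::cube& batch, const arma::vec& y, Rcpp::List params,
                         Rcpp::List cfgl, const arma::imat& nb, bool clustering,
                         const arma::mat& centroids, const arma::mat& Ptarget,
                         double lambda) {
  NetCfg cfg = parse_cfg(cfgl);
  std::vector<mat> P = parse_params(params);
  const int B = static_cast<int>(batch.n_slices);
  std::vector<int> idx(B);
  for (int i = 0; i < B; ++i) idx[i] = i;
  mat X = stack_batch(batch, idx, cfg.np);
  Cache c;
  forward(P, cfg, nb, X, B, c);
  mat dz;
  const double lp = pretext_loss_grad(c.z, y, dz);
  double lc = 0;
  mat mu = centroids.t();  // stored nc x ne on the R side -> ne x nc here
  mat dmu(mu.n_rows, mu.n_cols, fill::zeros);
  if (clustering) lc = kl_loss_grad(c.z, mu, Ptarget, lambda, dz, dmu);
  std::vector<mat> G;
  backward(P, cfg, nb, c, dz, G);
  Rcpp::List gl(G.size());
  for (size_t i = 0; i < G.size(); ++i) gl[i] = G[i];
  gl.attr("names") = params.attr("names");
  return Rcpp::List::create(
      Rcpp::Named("lp") = lp, Rcpp::Named("lc") = lc,
      Rcpp::Named("loss") = lp + lambda * lc, Rcpp::Named("grads") = gl,
      Rcpp::Named("grad_centroids") = dmu.t(), Rcpp::Named("z") = c.z.t());
}

// training loop shared by the pretraining stage (clustering = false) and
// the clustering stage (clustering = true, centroids trained jointly).
// Ptarget: nc x n target distribution columns for all fibers (clustering
// stage only). Adam state is passed in/out so stages can be chunked.
// [[Rcpp::export]]
Rcpp::List cpp_train(const arma::cube& fibers, Rcpp::List params, Rcpp::List cfgl,
                     const arma::imat& nb, int iters, double lr, int batch_pairs,
                     int seed, bool clustering, const arma::mat& centroids,
                     const arma::mat& Ptarget, double lambda,
                     Rcpp::Nullable<Rcpp::List> adam_state, int t0, int log_every) {
  NetCfg cfg = parse_cfg(cfgl);
  std::vector<mat> P = parse_params(params);
  const int n = static_cast<int>(fibers.n_slices);
  if (n < 2) Rcpp::stop("need at least 2 fibers to train");
  mat mu = centroids.n_elem ? centroids.t() : mat();
  if (clustering) P.push_back(mu);  // joint optimizer over encoder + centroids
  Adam opt;
  if (adam_state.isNotNull()) {
    Rcpp::List st(adam_state);
    Rcpp::List lm = st["m"], lv = st["v"];
    for (int i = 0; i < lm.size(); ++i) {
      opt.m.push_back(Rcpp::as<mat>(lm[i]));
      opt.v.push_back(Rcpp::as<mat>(lv[i]));
    }
  } else {
    opt.init_like(P);
  }
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_int_distribution<int> U(0, n - 1);
  const int nlog = log_every > 0 ? (iters + log_every - 1) / log_every : 0;
  mat trace(nlog, 4);
  int logrow = 0;
  Cache c;
  std::vector<mat> G;
  for (int it = 1; it <= iters; ++it) {
    std::vector<int> idx(2 * batch_pairs);
    vec y(batch_pairs);
    for (int i = 0; i < batch_pairs; ++i) {
      const int a = U(rng);
      int b = U(rng);
      while (b == a) b = U(rng);
      idx[i] = a;
      idx[batch_pairs + i] = b;
      y(i) = mdf_np(fibers.slice(a), fibers.slice(b));
    }
    mat X = stack_batch(fibers, idx, cfg.np);
    const int B = 2 * batch_pairs;
    std::vector<mat> Penc(P.begin(), P.begin() + n_params(cfg));
    forward(Penc, cfg, nb, X, B, c);
    mat dz;
    const double lp = pretext_loss_grad(c.z, y, dz);
    double lc = 0;
    mat dmu;
    if (clustering) {
      mat& mur = P.back();
      dmu.zeros(mur.n_rows, mur.n_cols);
      mat Pt(mur.n_cols, B);
      for (int i = 0; i < B; ++i) Pt.col(i) = Ptarget.col(idx[i]);
      lc = kl_loss_grad(c.z, mur, Pt, lambda, dz, dmu);
    }
    backward(Penc, cfg, nb, c, dz, G);
    if (clustering) G.push_back(dmu);
    opt.step(P, G, lr, static_cast<long>(t0) + it);
    if (log_every > 0 && (it % log_every == 0 || it == iters) && logrow < nlog) {
      trace(logrow, 0) = t0 + it;
      trace(logrow, 1) = lp;
      trace(logrow, 2) = lc;
      trace(logrow, 3) = lp + lambda * lc;
      ++logrow;
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }
  mat mu_out;
  if (clustering) {
    mu_out = P.back().t();
    P.pop_back();
  }
  Rcpp::List lm(opt.m.size()), lv(opt.v.size());
  for (size_t i = 0; i < opt.m.size(); ++i) {
    lm[i] = opt.m[i];
    lv[i] = opt.v[i];
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = wrap_params(P, params),
      Rcpp::Named("centroids") = mu_out,
      Rcpp::Named("adam") = Rcpp::List::create(Rcpp::Named("m") = lm, Rcpp::Named("v") = lv),
      Rcpp::Named("t") = t0 + iters,
      Rcpp::Named("log") = (logrow > 0 ? trace.rows(0, logrow - 1) : mat(0, 4)));
}
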