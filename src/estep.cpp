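#include <Rcpp.h>
using namespace Rcpp;

// Collapse one testlet block over the (theta, z) product grid.
//
// Ysub: N x Jd integer codes (NA = not administered)
// logP: list of K matrices (Jd x Q*V) of log category probabilities
// lwvk: log standardized-normal weights, replicated over theta nodes (Q*V)
// Returns Bd (N x Q*V): exp of weighted conditional log-likelihood per
// grid cell, and Ad (N x Q): Bd summed over the z nodes of each theta node
// (the inner quadrature of the bifactor dimension reduction).
// Loops run node-outer / person-inner so every matrix access is
// sequential in the column-major layout.
// [[Rcpp::export]]
List testlet_collapse(IntegerMatrix Ysub, List logP, NumericVector lwvk,
                      int Q, int V) {
  const int N = Ysub.nrow(), Jd = Ysub.ncol(), K = logP.size();
  const int QV = Q * V;
  std::vector<NumericMatrix> mats(K);
  std::vector<const double*> lp(K);
  for (int x = 0; x < K; ++x) {
    mats[x] = as<NumericMatrix>(logP[x]);
    lp[x] = mats[x].begin();
  }
  const int* y0 = Ysub.begin();
  NumericMatrix Bd(N, QV), Ad(N, Q);
  double* bd = Bd.begin();
  double* ad = Ad.begin();
  for (int k = 0; k < QV; ++k) {
    const double lw = lwvk[k];
    const int off = k * Jd;
    double* bcol = bd + (R_xlen_t)k * N;
    for (int i = 0; i < N; ++i) bcol[i] = lw;
    for (int j = 0; j < Jd; ++j) {
      const int* ycol = y0 + (R_xlen_t)j * N;
      // add log prob of the observed category; NA rows untouched
      for (int i = 0; i < N; ++i) {
        const int y = ycol[i];
        if (y != NA_INTEGER) bcol[i] += lp[y][off + j];
      }
    }
    for (int i = 0; i < N; ++i) bcol[i] = std::exp(bcol[i]);
  }
  for (int q = 0; q < Q; ++q) {
    double* acol = ad + (R_xlen_t)q * N;
    for (int v = 0; v < V; ++v) {
      const double* bcol = bd + (R_xlen_t)(q * V + v) * N;
      for (int i = 0; i < N; ++i) acol[i] += bcol[i];
    }
  }
  return List::create(_["Bd"] = Bd, _["Ad"] = Ad);
}

// Expected count accumulation for the M-step of one testlet block.
//
// Joint posterior mass of person i on grid cell (q, v) is
// Ptheta(i, q) * Bd(i, k) / Ad(i, q) with k = q*V + v. Accumulates, per
// item and grid cell, the expected number of responders (Nn) and the
// expected count per response category (Rx).
// [[Rcpp::export]]
List testlet_counts(IntegerMatrix Ysub, NumericMatrix Bd, NumericMatrix Ad,
                    NumericMatrix Ptheta, int V, int K) {
  const int N = Ysub.nrow(), Jd = Ysub.ncol();
  const int QV = Bd.ncol();
  List Rx(K);
  std::vector<double*> rx(K);
  for (int x = 0; x < K; ++x) {
    NumericMatrix m(Jd, QV);
    Rx[x] = m;
    rx[x] = m.begin();
  }
  NumericMatrix Nn(Jd, QV);
  const int* y0 = Ysub.begin();
  std::vector<double> post(N);
  for (int k = 0; k < QV; ++k) {
    const int q = k / V;
    const double* bcol = Bd.begin() + (R_xlen_t)k * N;
    const double* acol = Ad.begin() + (R_xlen_t)q * N;
    const double* pcol = Ptheta.begin() + (R_xlen_t)q * N;
    for (int i = 0; i < N; ++i) {
      post[i] = acol[i] > 0.0 ? bcol[i] * pcol[i] / acol[i] : 0.0;
    }
    const int off = k * Jd;
    for (int j = 0; j < Jd; ++j) {
      const int* ycol = y0 + (R_xlen_t)j * N;
      double nsum = 0.0;
      for (int x = 0; x < K; ++x) rx[x][off + j] = 0.0;
      for (int i = 0; i < N; ++i) {
        const int y = ycol[i];
        if (y != NA_INTEGER) {
          nsum += post[i];
          rx[y][off + j] += post[i];
        }
      }
      Nn[off + j] = nsum;
    }
  }
  return List::create(_["Rx"] = Rx, _["Nn"] = Nn);
}

// Safeguarded Fisher-scoring refinement of item parameters for a block of
// graded (or, with K = 2, two-parameter logistic) items sharing one set of
// effective trait nodes u. Counts come from the E-step: Rx is a list of K
// matrices (J x nodes) of expected per-category counts. Each item takes
// `steps` scoring iterations; every step is accepted only if it increases
// the item's expected complete-data log-likelihood (with up to four step
// halvings), so the EM ascent property is preserved.
static double grm_item_qval(double a, const std::vector<double>& b,
                            const std::vector<double>& u,
                            const std::vector<const double*>& rx,
                            int j, int J, int nodes) {
  const int m = (int)b.size(), K = m + 1;
  double q = 0.0;
  for (int k = 0; k < nodes; ++k) {
    double prev = 1.0;
    for (int c = 0; c < K; ++c) {
      const double lo = (c < m) ? 1.0 / (1.0 + std::exp(-a * (u[k] - b[c])))
                                : 0.0;
      double pc = prev - lo;
      if (pc < 1e-12) pc = 1e-12;
      q += rx[c][(R_xlen_t)k * J + j] * std::log(pc);
      prev = lo;
    }
  }
  return q;
}

// [[Rcpp::export]]
List grm_fisher_block(NumericVector a, NumericMatrix B, NumericVector u,
                      List Rx, int steps, double amin, double amax,
                      double bmax) {
  const int J = a.size(), m = B.ncol(), K = m + 1;
  const int nodes = u.size(), dim = m + 1;
  std::vector<const double*> rx(K);
  std::vector<NumericMatrix> mats(K);
  for (int x = 0; x < K; ++x) {
    mats[x] = as<NumericMatrix>(Rx[x]);
    rx[x] = mats[x].begin();
  }
  std::vector<double> uu(u.begin(), u.end());
  NumericVector a_out = clone(a);
  NumericMatrix B_out = clone(B);

  std::vector<double> b(m), pstar(m), W(m), g(dim), I(dim * dim), delta(dim);
  for (int j = 0; j < J; ++j) {
    double aj = a_out[j];
    for (int y = 0; y < m; ++y) b[y] = B_out(j, y);
    double q0 = grm_item_qval(aj, b, uu, rx, j, J, nodes);
    for (int it = 0; it < steps; ++it) {
      std::fill(g.begin(), g.end(), 0.0);
      std::fill(I.begin(), I.end(), 0.0);
      for (int k = 0; k < nodes; ++k) {
        double Nk = 0.0;
        for (int y = 0; y < m; ++y) {
          pstar[y] = 1.0 / (1.0 + std::exp(-aj * (uu[k] - b[y])));
          W[y] = pstar[y] * (1.0 - pstar[y]);
        }
        for (int c = 0; c < K; ++c) Nk += rx[c][(R_xlen_t)k * J + j];
        if (Nk <= 0.0) continue;
        for (int c = 0; c < K; ++c) {
          const double hi = (c == 0) ? 1.0 : pstar[c - 1];
          const double lo = (c == m) ? 0.0 : pstar[c];
          double pc = hi - lo;
          if (pc < 1e-10) pc = 1e-10;
          // sparse derivative of P_c: at most three nonzero entries
          int idx[3]; double val[3]; int nz = 0;
          double da = 0.0;
          if (c >= 1) da += W[c - 1] * (uu[k] - b[c - 1]);
          if (c < m) da -= W[c] * (uu[k] - b[c]);
          idx[nz] = 0; val[nz++] = da;
          if (c >= 1) { idx[nz] = c; val[nz++] = -aj * W[c - 1]; }
          if (c < m) { idx[nz] = c + 1; val[nz++] = aj * W[c]; }
          const double nkc = rx[c][(R_xlen_t)k * J + j];
          const double wI = Nk / pc;
          for (int s = 0; s < nz; ++s) {
            g[idx[s]] += nkc / pc * val[s];
            for (int t = 0; t < nz; ++t) {
              I[idx[s] * dim + idx[t]] += wI * val[s] * val[t];
            }
          }
        }
      }
      // ridge for numerical safety, then solve I * delta = g
      double tr = 0.0;
      for (int s = 0; s < dim; ++s) tr += I[s * dim + s];
      for (int s = 0; s < dim; ++s) I[s * dim + s] += 1e-8 * (tr + 1.0);
      std::vector<double> A(I);
      std::copy(g.begin(), g.end(), delta.begin());
      bool ok = true;
      for (int col = 0; col < dim && ok; ++col) {  // partial-pivot elimination
        int piv = col;
        for (int r = col + 1; r < dim; ++r) {
          if (std::fabs(A[r * dim + col]) > std::fabs(A[piv * dim + col])) piv = r;
        }
        if (std::fabs(A[piv * dim + col]) < 1e-12) { ok = false; break; }
        if (piv != col) {
          for (int cc = 0; cc < dim; ++cc) std::swap(A[col * dim + cc], A[piv * dim + cc]);
          std::swap(delta[col], delta[piv]);
        }
        for (int r = col + 1; r < dim; ++r) {
          const double f = A[r * dim + col] / A[col * dim + col];
          for (int cc = col; cc < dim; ++cc) A[r * dim + cc] -= f * A[col * dim + cc];
          delta[r] -= f * delta[col];
        }
      }
      if (!ok) break;
      for (int col = dim - 1; col >= 0; --col) {
        double s = delta[col];
        for (int cc = col + 1; cc < dim; ++cc) s -= A[col * dim + cc] * delta[cc];
        delta[col] = s / A[col * dim + col];
      }
      // damped, ascent-guarded update with ordering preserved
      double scale = 1.0;
      double mx = 0.0;
      for (int s = 0; s < dim; ++s) mx = std::max(mx, std::fabs(delta[s]));
      if (mx > 1.0) scale = 1.0 / mx;
      bool accepted = false;
      for (int h = 0; h < 4 && !accepted; ++h) {
        double at = aj + scale * delta[0];
        if (at < amin) at = amin;
        if (at > amax) at = amax;
        std::vector<double> bt(m);
        bool ord = true;
        for (int y = 0; y < m; ++y) {
          bt[y] = b[y] + scale * delta[y + 1];
          if (bt[y] > bmax) bt[y] = bmax;
          if (bt[y] < -bmax) bt[y] = -bmax;
          if (y > 0 && bt[y] < bt[y - 1]) ord = false;
        }
        if (ord) {
          const double q1 = grm_item_qval(at, bt, uu, rx, j, J, nodes);
          if (q1 >= q0) {
            aj = at; b = bt; q0 = q1; accepted = true;
          }
        }
        scale *= 0.5;
      }
      if (!accepted) break;
    }
    a_out[j] = aj;
    for (int y = 0; y < m; ++y) B_out(j, y) = b[y];
  }
  return List::create(_["a"] = a_out, _["B"] = B_out);
}
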