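// Pseudo-polar FFT core and EST iteration.
//
// Conventions (fixed package-wide):
//   slice x[i, j]: i -> u = i-1-N/2 (x axis), j -> v = j-1-N/2 (z, beam at 0 deg)
//   BH sector: F(k, l) = sum_{u,v} x(u,v) exp(-2i pi k (u + s v) / (2N)),  s = 2 l / N
//   BV sector: same with u and v exchanged
//   k = -N..N-1 (2N radial samples, rows), l = -N/2..N/2 (N+1 lines, cols)
// The slope-dependent resampling along v is a Bluestein (chirp-z) transform,
// batched over k and over slices so the whole volume moves through a handful
// of column-wise FFTs.

#include <RcppArmadillo.h>
#include <fftw3.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// In-place batched FFT over matrix columns (FFTW, column-major contiguous).
static void fft_cols(cx_mat& X, int sign) {
  int n = X.n_rows, m = X.n_cols;
  if (n == 0 || m == 0) return;
  fftw_plan pl = fftw_plan_many_dft(
      1, &n, m,
      reinterpret_cast<fftw_complex*>(X.memptr()), NULL, 1, n,
      reinterpret_cast<fftw_complex*>(X.memptr()), NULL, 1, n,
      sign, FFTW_ESTIMATE);
  fftw_execute(pl);
  fftw_destroy_plan(pl);
  if (sign == FFTW_BACKWARD) X /= (double)n;
}

static int good_fft_size(int n) {
  for (;; ++n) {
    int m = n;
    while (m % 2 == 0) m /= 2;
    while (m % 3 == 0) m /= 3;
    while (m % 5 == 0) m /= 5;
    if (m == 1) return n;
  }
}

struct PPPlan {
  int N, twoN, M;
  cx_vec phase_u;               // e^{+i pi k / 2}, per centred k row
  cx_mat chirp_in_f;            // (N   x 2N) e^{-i pi a_k v^2}
  cx_mat chirp_out_f;           // (N+1 x 2N) e^{-i pi a_k l^2}
  cx_mat Bf;                    // (M x 2N) fft of b_k(m) = e^{+i pi a_k m^2}, m = -(N-1)..N
  cx_mat chirp_in_a;            // (N+1 x 2N) e^{+i pi a_k l^2}
  cx_mat chirp_out_a;           // (N   x 2N) e^{+i pi a_k v^2}
  cx_mat Ba;                    // (M x 2N) fft of b2_k(m) = e^{-i pi a_k m^2}, m = -N..N-1
  vec w;                        // radial weights |k| (DC -> 1/2), per k row
};

static PPPlan make_plan(int N) {
  PPPlan P;
  P.N = N; P.twoN = 2 * N;
  P.M = good_fft_size(3 * N);
  P.phase_u.set_size(P.twoN);
  P.chirp_in_f.set_size(N, P.twoN);
  P.chirp_out_f.set_size(N + 1, P.twoN);
  P.chirp_in_a.set_size(N + 1, P.twoN);
  P.chirp_out_a.set_size(N, P.twoN);
  cx_mat bf(P.M, P.twoN, fill::zeros), ba(P.M, P.twoN, fill::zeros);
  P.w.set_size(P.twoN);
  for (int r = 0; r < P.twoN; ++r) {
    double k = r - N;
    double a = k / ((double)N * N);
    P.phase_u(r) = std::polar(1.0, M_PI * k / 2.0);
    P.w(r) = (k == 0.0) ? 0.5 : std::abs(k);
    for (int vi = 0; vi < N; ++vi) {
      double v = vi - N / 2;
      P.chirp_in_f(vi, r) = std::polar(1.0, -M_PI * a * v * v);
      P.chirp_out_a(vi, r) = std::polar(1.0, M_PI * a * v * v);
    }
    for (int li = 0; li <= N; ++li) {
      double l = li - N / 2;
      P.chirp_out_f(li, r) = std::polar(1.0, -M_PI * a * l * l);
      P.chirp_in_a(li, r) = std::polar(1.0, M_PI * a * l * l);
    }
    for (int mi = 0; mi < P.twoN; ++mi) {
      double mf = mi - (N - 1);          // forward kernel support -(N-1)..N
      double mA = mi - N;                // adjoint kernel support -N..N-1
      bf(mi, r) = std::polar(1.0, M_PI * a * mf * mf);
      ba(mi, r) = std::polar(1.0, -M_PI * a * mA * mA);
    }
  }
  fft_cols(bf, FFTW_FORWARD); P.Bf = bf;
  fft_cols(ba, FFTW_FORWARD); P.Ba = ba;
  return P;
}

// Column FFT over u with zero padding to 2N, centred in k and u.
// xs: (N x N x S) real; out: (2N x N*S) complex, row r -> k = r - N, col = v + s*N
static cx_mat col_fft_centred(const PPPlan& P, const cube& xs) {
  int N = P.N, S = xs.n_slices;
  cx_mat Xpad(P.twoN, N * S, fill::zeros);
  for (int s = 0; s < S; ++s)
    Xpad.submat(0, s * N, N - 1, s * N + N - 1) =
      conv_to<cx_mat>::from(xs.slice(s));
  fft_cols(Xpad, FFTW_FORWARD);
  const cx_mat& Xf = Xpad;
  cx_mat X(P.twoN, N * S);
  for (int r = 0; r < P.twoN; ++r) {
    int old = (r + N) % P.twoN;
    X.row(r) = Xf.row(old) * P.phase_u(r);
  }
  return X;
}

// Forward, one sector. xs (N x N x S) real -> G (2N x (N+1) x S).
// Only rows k = -N..0 are computed; rows k = 1..N-1 follow from conjugate
// symmetry of the spectrum of a real slice, G(k, l) = conj(G(-k, l)).
static void sector_forward(const PPPlan& P, const cube& xs, cx_cube& G) {
  int N = P.N, twoN = P.twoN, S = xs.n_slices;
  int H = N + 1;                      // rows r = 0..N, i.e. k = -N..0
  cx_mat X = col_fft_centred(P, xs);
  cx_mat A(P.M, H * S, fill::zeros);
  for (int s = 0; s < S; ++s)
    for (int r = 0; r < H; ++r) {
      int c = s * H + r;
      for (int vi = 0; vi < N; ++vi)
        A(vi, c) = X(r, s * N + vi) * P.chirp_in_f(vi, r);
    }
  fft_cols(A, FFTW_FORWARD);
  for (int s = 0; s < S; ++s)
    A.cols(s * H, s * H + H - 1) %= P.Bf.cols(0, H - 1);
  fft_cols(A, FFTW_BACKWARD);
  const cx_mat& C = A;
  G.set_size(twoN, N + 1, S);
  for (int s = 0; s < S; ++s) {
    for (int r = 0; r < H; ++r) {
      int c = s * H + r;
      for (int li = 0; li <= N; ++li)
        G(r, li, s) = C(li + N - 1, c) * P.chirp_out_f(li, r);
    }
    for (int r = H; r < twoN; ++r)          // k = r - N in 1..N-1
      for (int li = 0; li <= N; ++li)
        G(r, li, s) = std::conj(G(twoN - r, li, s));
  }
}

// Adjoint, one sector. G (2N x (N+1) x S) -> out (N x N x S) complex.
// With sym = true, G is assumed conjugate-symmetric in k (true for spectra of
// real slices); only rows k = -N..0 are processed, the rest mirrored.
static void sector_adjoint(const PPPlan& P, const cx_cube& G, cx_cube& out,
                           bool sym = false) {
  int N = P.N, twoN = P.twoN, S = G.n_slices;
  int nr = sym ? (N + 1) : twoN;      // rows actually transformed
  cx_mat A2(P.M, nr * S, fill::zeros);
  for (int s = 0; s < S; ++s)
    for (int r = 0; r < nr; ++r) {
      int c = s * nr + r;
      for (int li = 0; li <= N; ++li)
        A2(li, c) = G(r, li, s) * P.chirp_in_a(li, r);
    }
  fft_cols(A2, FFTW_FORWARD);
  for (int s = 0; s < S; ++s)
    A2.cols(s * nr, s * nr + nr - 1) %= P.Ba.cols(0, nr - 1);
  fft_cols(A2, FFTW_BACKWARD);
  const cx_mat& C2 = A2;
  // H: (2N x N*S) in k' = 0..2N-1 (uncentred) order, phase removed
  cx_mat H(twoN, N * S, fill::zeros);
  for (int s = 0; s < S; ++s) {
    for (int r = 0; r < nr; ++r) {
      int old = (r + N) % twoN;       // row in uncentred order
      cx_double ph = std::conj(P.phase_u(r));
      int c = s * nr + r;
      for (int vi = 0; vi < N; ++vi)
        H(old, s * N + vi) = C2(vi + N, c) * P.chirp_out_a(vi, r) * ph;
    }
    if (sym)                          // k = 1..N-1 from conj of k = -1..-(N-1)
      for (int kp = 1; kp < N; ++kp)
        for (int vi = 0; vi < N; ++vi)
          H(kp, s * N + vi) = std::conj(H(twoN - kp, s * N + vi));
  }
  fft_cols(H, FFTW_BACKWARD);
  cx_mat Y = H * (double)twoN;        // adjoint of unnormalised DFT
  out.set_size(N, N, S);
  for (int s = 0; s < S; ++s)
    out.slice(s) = Y.submat(0, s * N, N - 1, s * N + N - 1);
}

static void pp_forward(const PPPlan& P, const cube& xs, cx_cube& BH, cx_cube& BV) {
  sector_forward(P, xs, BH);
  cube xt(xs.n_rows, xs.n_cols, xs.n_slices);
  for (unsigned s = 0; s < xs.n_slices; ++s) xt.slice(s) = xs.slice(s).t();
  sector_forward(P, xt, BV);
}

// Complex adjoint A^H of the two-sector map (no real projection).
static void pp_adjoint(const PPPlan& P, const cx_cube& BH, const cx_cube& BV,
                       cx_cube& out, bool sym = false) {
  cx_cube aH, aV;
  sector_adjoint(P, BH, aH, sym);
  sector_adjoint(P, BV, aV, sym);
  out.set_size(aH.n_rows, aH.n_cols, aH.n_slices);
  for (unsigned s = 0; s < aH.n_slices; ++s)
    out.slice(s) = aH.slice(s) + aV.slice(s).st();
}

// Re(A^H (W .* G)) used by the normal equations; W applied per k row.
// G is conjugate-symmetric in k throughout the solver, so the sym path is exact.
static void normal_rhs(const PPPlan& P, const cx_cube& BH, const cx_cube& BV,
                       cube& out, bool sym = true) {
  cx_vec wc = conv_to<cx_vec>::from(P.w);
  cx_cube wBH = BH, wBV = BV, a;
  for (unsigned s = 0; s < BH.n_slices; ++s) {
    wBH.slice(s).each_col() %= wc;
    wBV.slice(s).each_col() %= wc;
  }
  pp_adjoint(P, wBH, wBV, a, sym);
  out.set_size(a.n_rows, a.n_cols, a.n_slices);
  for (unsigned s = 0; s < a.n_slices; ++s) out.slice(s) = real(a.slice(s));
}

static void normal_op(const PPPlan& P, const cube& x, cube& out) {
  cx_cube BH, BV;
  pp_forward(P, x, BH, BV);
  normal_rhs(P, BH, BV, out);
}

// Batched per-slice CG on Re(A^H W A) x = Re(A^H W G), warm start x0.
// Returns per-slice iteration counts and relative residuals.
static void cg_solve(const PPPlan& P, const cx_cube& BH, const cx_cube& BV,
                     cube& x, double tol, int maxit,
                     ivec& iters, vec& rel) {
  int S = BH.n_slices;
  cube b, Ax, Ap;
  normal_rhs(P, BH, BV, b, false);   // data may be an arbitrary complex spectrum
  bool cold = (x.n_elem == 0);
  if (cold) x.zeros(P.N, P.N, S);
  cube r;
  if (cold) {
    r = b;                           // A x0 = 0, no transform needed
  } else {
    normal_op(P, x, Ax);
    r = b - Ax;
  }
  cube p = r;
  vec rs(S), rs0(S);
  for (int s = 0; s < S; ++s) {
    rs(s) = accu(square(r.slice(s)));
    rs0(s) = accu(square(b.slice(s)));
  }
  iters.zeros(S); rel.zeros(S);
  uvec active(S, fill::ones);
  for (int s = 0; s < S; ++s)
    if (rs0(s) == 0.0 || rs(s) <= tol * tol * rs0(s)) active(s) = 0;
  int it = 0;
  while (it < maxit && accu(active) > 0) {
    normal_op(P, p, Ap);
    for (int s = 0; s < S; ++s) {
      if (!active(s)) continue;
      double pAp = accu(p.slice(s) % Ap.slice(s));
      if (pAp <= 0) { active(s) = 0; continue; }
      double alpha = rs(s) / pAp;
      x.slice(s) += alpha * p.slice(s);
      r.slice(s) -= alpha * Ap.slice(s);
      double rs_new = accu(square(r.slice(s)));
      p.slice(s) = r.slice(s) + (rs_new / rs(s)) * p.slice(s);
      rs(s) = rs_new;
      iters(s) = it + 1;
      if (rs(s) <= tol * tol * rs0(s)) active(s) = 0;
    }
    ++it;
  }
  for (int s = 0; s < S; ++s)
    rel(s) = rs0(s) > 0 ? std::sqrt(rs(s) / rs0(s)) : 0.0;
}

// [[Rcpp::export]]
Rcpp::List cpp_ppfft_forward(const arma::cube& xs) {
  PPPlan P = make_plan(xs.n_rows);
  cx_cube BH, BV;
  pp_forward(P, xs, BH, BV);
  return Rcpp::List::create(Rcpp::Named("BH") = BH, Rcpp::Named("BV") = BV);
}

// [[Rcpp::export]]
arma::cx_cube cpp_ppfft_adjoint(const arma::cx_cube& BH, const arma::cx_cube& BV) {
  PPPlan P = make_plan(BH.n_rows / 2);
  cx_cube out;
  pp_adjoint(P, BH, BV, out);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_pp_inverse(const arma::cx_cube& BH, const arma::cx_cube& BV,
                          double tol, int maxit, const arma::cube& x0) {
  PPPlan P = make_plan(BH.n_rows / 2);
  cube x = x0;   // may be 0-size
  ivec iters; vec rel;
  cg_solve(P, BH, BV, x, tol, maxit, iters, rel);
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("iters") = iters,
                            Rcpp::Named("rel") = rel);
}

// EST iteration for a stack of slices sharing one angle set.
// mBH/mBV hold measured line values in the masked columns (others ignored).
// maskBH/maskBV: 0/1 per line column for Fourier-domain replacement (duplicate
// 45 deg copies included); emaskBH/emaskBV: unique measured lines for the
// error metric.
// [[Rcpp::export]]
Rcpp::List cpp_est(const arma::cx_cube& mBH, const arma::cx_cube& mBV,
                   const arma::uvec& maskBH, const arma::uvec& maskBV,
                   const arma::uvec& emaskBH, const arma::uvec& emaskBV,
                   int n_iter, int inner, int first_inner,
                   bool positivity, const arma::cube& support,
                   int record_every) {
  int twoN = mBH.n_rows, N = twoN / 2, S = mBH.n_slices;
  PPPlan P = make_plan(N);
  bool has_supp = support.n_elem > 0;
  uvec mcolsBH = find(maskBH), mcolsBV = find(maskBV);
  uvec ecolsBH = find(emaskBH), ecolsBV = find(emaskBV);

  vec denom(S, fill::zeros);
  for (int s = 0; s < S; ++s) {
    for (unsigned j = 0; j < ecolsBH.n_elem; ++j)
      denom(s) += accu(abs(mBH.slice(s).col(ecolsBH(j))));
    for (unsigned j = 0; j < ecolsBV.n_elem; ++j)
      denom(s) += accu(abs(mBV.slice(s).col(ecolsBV(j))));
  }

  cube x(N, N, S, fill::zeros);
  cx_cube FBH(twoN, N + 1, S, fill::zeros), FBV(twoN, N + 1, S, fill::zeros);
  std::vector<int> rec_iters;
  std::vector<vec> rec_err;

  for (int it = 1; it <= n_iter; ++it) {
    // residual on measured lines only
    cx_cube dBH(twoN, N + 1, S, fill::zeros), dBV(twoN, N + 1, S, fill::zeros);
    for (int s = 0; s < S; ++s) {
      for (unsigned j = 0; j < mcolsBH.n_elem; ++j) {
        unsigned c = mcolsBH(j);
        dBH.slice(s).col(c) = mBH.slice(s).col(c) - FBH.slice(s).col(c);
      }
      for (unsigned j = 0; j < mcolsBV.n_elem; ++j) {
        unsigned c = mcolsBV(j);
        dBV.slice(s).col(c) = mBV.slice(s).col(c) - FBV.slice(s).col(c);
      }
    }
    // warm-started CG step toward the inverse PPFFT of (F with measured replaced)
    int n_inner = (it == 1) ? first_inner : inner;
    cube dx;
    {
      ivec itr; vec rel;
      cg_solve(P, dBH, dBV, dx, 0.0, n_inner, itr, rel);
    }
    x += dx;
    if (positivity) x.transform([](double v) { return v < 0 ? 0.0 : v; });
    if (has_supp) x %= support;
    pp_forward(P, x, FBH, FBV);
    // error metric after constraint application
    bool rec = (record_every > 0 && (it % record_every == 0)) || it == 1 || it == n_iter;
    if (rec) {
      vec err(S, fill::zeros);
      for (int s = 0; s < S; ++s) {
        double num = 0.0;
        for (unsigned j = 0; j < ecolsBH.n_elem; ++j) {
          unsigned c = ecolsBH(j);
          num += accu(abs(FBH.slice(s).col(c) - mBH.slice(s).col(c)));
        }
        for (unsigned j = 0; j < ecolsBV.n_elem; ++j) {
          unsigned c = ecolsBV(j);
          num += accu(abs(FBV.slice(s).col(c) - mBV.slice(s).col(c)));
        }
        err(s) = denom(s) > 0 ? num / denom(s) : 0.0;
      }
      rec_iters.push_back(it);
      rec_err.push_back(err);
    }
  }
  mat errm(rec_err.size(), S);
  for (unsigned i = 0; i < rec_err.size(); ++i) errm.row(i) = rec_err[i].t();
  return Rcpp::List::create(
    Rcpp::Named("x") = x,
    Rcpp::Named("error_history") = errm,
    Rcpp::Named("error_iters") = Rcpp::IntegerVector(rec_iters.begin(), rec_iters.end()));
}

// Ray-model projector: rotate about the y tilt axis, integrate along the beam
// (step = 1 voxel, bilinear in the x-z plane). vol (NX x NY x NZ);
// returns (NX x NY x n_angles) in voxel-length units (caller scales to OD).
// [[Rcpp::export]]
arma::cube cpp_project(const arma::cube& vol, const arma::vec& theta_rad) {
  int NX = vol.n_rows, NY = vol.n_cols, NZ = vol.n_slices;
  int NA = theta_rad.n_elem;
  double cx = NX / 2, cz = NZ / 2;
  int R = (int)std::ceil(std::sqrt((double)NX * NX + NZ * NZ) / 2.0) + 1;
  cube out(NX, NY, NA, fill::zeros);
  for (int a = 0; a < NA; ++a) {
    double ct = std::cos(theta_rad(a)), st = std::sin(theta_rad(a));
    for (int ti = 0; ti < NX; ++ti) {
      double t = ti - cx;
      for (int r = -R; r < R; ++r) {
        double u = t * ct - r * st + cx;
        double v = t * st + r * ct + cz;
        int i0 = (int)std::floor(u), k0 = (int)std::floor(v);
        if (i0 < -1 || i0 > NX - 1 || k0 < -1 || k0 > NZ - 1) continue;
        double fu = u - i0, fv = v - k0;
        double w00 = (1 - fu) * (1 - fv), w10 = fu * (1 - fv),
               w01 = (1 - fu) * fv, w11 = fu * fv;
        bool i0ok = i0 >= 0 && i0 < NX, i1ok = i0 + 1 >= 0 && i0 + 1 < NX;
        bool k0ok = k0 >= 0 && k0 < NZ, k1ok = k0 + 1 >= 0 && k0 + 1 < NZ;
        for (int y = 0; y < NY; ++y) {
          double acc = 0.0;
          if (i0ok && k0ok) acc += w00 * vol(i0, y, k0);
          if (i1ok && k0ok) acc += w10 * vol(i0 + 1, y, k0);
          if (i0ok && k1ok) acc += w01 * vol(i0, y, k0 + 1);
          if (i1ok && k1ok) acc += w11 * vol(i0 + 1, y, k0 + 1);
          out(ti, y, a) += acc;
        }
      }
    }
  }
  return out;
}
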