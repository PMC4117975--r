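// Fused objective/gradient evaluation for the coupled factorization
// objectives. Handles blocks of order 2 and 3 (the generic N-way case is
// served by the R reference implementation, which these routines must
// match up to floating-point associativity; see the consistency tests).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Khatri-Rao product handled column-by-column:
// kr.col(r) = kron(a.col(r), b.col(r)).
static arma::mat khatri_rao2(const arma::mat& a, const arma::mat& b) {
  arma::mat out(a.n_rows * b.n_rows, a.n_cols);
  for (arma::uword r = 0; r < a.n_cols; ++r)
    out.col(r) = arma::kron(a.col(r), b.col(r));
  return out;
}

// Core evaluator over factor matrices U (one per global mode) and optional
// per-block weights w.  Accumulates into gF/gW when want_grad.
static double eval_fg(const std::vector<arma::mat>& U,
                      const std::vector<arma::vec>& w,
                      const List& blocks, const List& block_dims,
                      const List& modes, const List& masks,
                      double alpha, double beta, double epsilon,
                      bool half, bool weighted, bool want_grad,
                      std::vector<arma::mat>& gF,
                      std::vector<arma::vec>& gW) {
  const double s = half ? 0.5 : 1.0;
  const int nb = blocks.size();
  const int ng = U.size();
  const arma::uword R = U[0].n_cols;
  double f = 0.0;

  for (int b = 0; b < nb; ++b) {
    arma::ivec gm = as<arma::ivec>(modes[b]);       // 1-based global ids
    arma::ivec dims = as<arma::ivec>(block_dims[b]);
    const int D = gm.n_elem;
    arma::vec wloc = weighted ? w[b] : arma::ones(R);
    const int g1 = gm[0] - 1;
    const arma::uword I = dims[0];
    arma::uword rest = 1;
    for (int d = 1; d < D; ++d) rest *= (arma::uword)dims[d];
    NumericVector bv = blocks[b];
    const arma::mat bm(bv.begin(), I, rest, false, true);
    bool masked = !Rf_isNull(masks[b]);

    if (D == 2) {
      const int g2 = gm[1] - 1;
      arma::mat resid = U[g1] * arma::diagmat(wloc) * U[g2].t() - bm;
      if (masked) {
        NumericVector mv = masks[b];
        const arma::mat W(mv.begin(), I, rest, false, true);
        resid %= W;
      }
      f += s * arma::accu(arma::square(resid));
      if (want_grad) {
        arma::mat M1 = resid * U[g2];
        gF[g1] += 2.0 * s * (M1 * arma::diagmat(wloc));
        if (weighted) gW[b] += 2.0 * s * arma::sum(U[g1] % M1, 0).t();
        gF[g2] += 2.0 * s * (resid.t() * U[g1] * arma::diagmat(wloc));
      }
    } else if (D == 3) {
      const int g2 = gm[1] - 1, g3 = gm[2] - 1;
      const arma::uword J = dims[1], K = dims[2];
      arma::mat K1 = khatri_rao2(U[g3], U[g2]);     // reversed order
      arma::mat resid = U[g1] * arma::diagmat(wloc) * K1.t() - bm;
      if (masked) {
        NumericVector mv = masks[b];
        const arma::mat W(mv.begin(), I, rest, false, true);
        resid %= W;
      }
      f += s * arma::accu(arma::square(resid));
      if (want_grad) {
        arma::mat M1 = resid * K1;
        gF[g1] += 2.0 * s * (M1 * arma::diagmat(wloc));
        if (weighted) gW[b] += 2.0 * s * arma::sum(U[g1] % M1, 0).t();
        arma::mat Wm = U[g1].t() * resid;           // R x (J*K)
        arma::mat M2(J, R), M3(K, R);
        for (arma::uword r = 0; r < R; ++r) {
          arma::vec wr = Wm.row(r).t();
          arma::mat Wr(wr.memptr(), J, K, false, true);
          M2.col(r) = Wr * U[g3].col(r);
          M3.col(r) = Wr.t() * U[g2].col(r);
        }
        gF[g2] += 2.0 * s * (M2 * arma::diagmat(wloc));
        gF[g3] += 2.0 * s * (M3 * arma::diagmat(wloc));
      }
    } else {
      stop("compiled path supports block orders 2 and 3 only");
    }
  }

  if (weighted) {
    if (alpha > 0) {
      for (int g = 0; g < ng; ++g) {
        arma::rowvec nrm = arma::sqrt(arma::sum(arma::square(U[g]), 0));
        f += s * alpha * arma::accu(arma::square(nrm - 1.0));
        if (want_grad) {
          arma::mat uhat = U[g];
          for (arma::uword r = 0; r < R; ++r)
            if (nrm[r] > 0) uhat.col(r) /= nrm[r]; else uhat.col(r).zeros();
          gF[g] += 2.0 * s * alpha * (U[g] - uhat);
        }
      }
    }
    if (beta > 0) {
      for (int b = 0; b < nb; ++b) {
        arma::vec sa = arma::sqrt(arma::square(w[b]) + epsilon);
        f += beta * arma::accu(sa);
        if (want_grad) gW[b] += beta * (w[b] / sa);
      }
    }
  }
  return f;
}

// List-of-matrices interface, mirroring the R reference evaluator.
// [[Rcpp::export(name = ".coupled_fg_cpp")]]
List coupled_fg_cpp(List blocks, List block_dims, List modes, List masks,
                    List factors, List weights, double alpha, double beta,
                    double epsilon, bool half, bool weighted,
                    bool want_grad) {
  const int nb = blocks.size();
  const int ng = factors.size();
  std::vector<arma::mat> U(ng);
  for (int g = 0; g < ng; ++g) U[g] = as<arma::mat>(factors[g]);
  const arma::uword R = U[0].n_cols;
  std::vector<arma::vec> w;
  if (weighted) {
    w.resize(nb);
    for (int b = 0; b < nb; ++b) w[b] = as<arma::vec>(weights[b]);
  }
  std::vector<arma::mat> gF;
  std::vector<arma::vec> gW;
  if (want_grad) {
    gF.resize(ng);
    for (int g = 0; g < ng; ++g) gF[g] = arma::zeros(U[g].n_rows, R);
    if (weighted) {
      gW.resize(nb);
      for (int b = 0; b < nb; ++b) gW[b] = arma::zeros(R);
    }
  }
  double f = eval_fg(U, w, blocks, block_dims, modes, masks, alpha, beta,
                     epsilon, half, weighted, want_grad, gF, gW);
  if (!want_grad) return List::create(Named("f") = f);
  List gFl(ng);
  for (int g = 0; g < ng; ++g) gFl[g] = wrap(gF[g]);
  List out = List::create(Named("f") = f, Named("gfactors") = gFl);
  if (weighted) {
    List gWl(nb);
    for (int b = 0; b < nb; ++b) gWl[b] = wrap(gW[b]);
    out["gweights"] = gWl;
  }
  return out;
}

// Packed-vector interface for the optimizer hot loop: x stacks vec() of
// each factor matrix in global mode order, then each block's weight
// vector.  Returns f and the gradient packed in the same order.
// [[Rcpp::export(name = ".coupled_fg_packed")]]
List coupled_fg_packed(NumericVector x, IntegerVector mode_rows, int R,
                       List blocks, List block_dims, List modes, List masks,
                       double alpha, double beta, double epsilon, bool half,
                       bool weighted) {
  const int ng = mode_rows.size();
  const int nb = blocks.size();
  std::vector<arma::mat> U(ng);
  std::vector<arma::vec> w;
  arma::uword pos = 0;
  for (int g = 0; g < ng; ++g) {
    U[g] = arma::mat(x.begin() + pos, mode_rows[g], R);
    pos += (arma::uword)mode_rows[g] * R;
  }
  if (weighted) {
    w.resize(nb);
    for (int b = 0; b < nb; ++b) {
      w[b] = arma::vec(x.begin() + pos, R);
      pos += R;
    }
  }
  if (pos != (arma::uword)x.size())
    stop("packed parameter vector has the wrong length");
  std::vector<arma::mat> gF(ng);
  std::vector<arma::vec> gW;
  for (int g = 0; g < ng; ++g) gF[g] = arma::zeros(mode_rows[g], R);
  if (weighted) {
    gW.resize(nb);
    for (int b = 0; b < nb; ++b) gW[b] = arma::zeros(R);
  }
  double f = eval_fg(U, w, blocks, block_dims, modes, masks, alpha, beta,
                     epsilon, half, weighted, true, gF, gW);
  NumericVector grad(x.size());
  pos = 0;
  for (int g = 0; g < ng; ++g) {
    std::copy(gF[g].memptr(), gF[g].memptr() + gF[g].n_elem,
              grad.begin() + pos);
    pos += gF[g].n_elem;
  }
  if (weighted)
    for (int b = 0; b < nb; ++b) {
      std::copy(gW[b].memptr(), gW[b].memptr() + R, grad.begin() + pos);
      pos += R;
    }
  return List::create(Named("f") = f, Named("g") = grad);
}
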