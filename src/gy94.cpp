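// Goldman-Yang codon model machinery.
//
// Transition probabilities are applied to conditional-likelihood matrices by
// uniformization (a Poisson-weighted series in the sparse rate matrix; every
// sense codon has at most nine single-nucleotide neighbours), which avoids
// dense eigendecompositions and is fast at the short branch lengths this
// analysis works at. Conditionals are kept pattern-major (sites x states) so
// the sparse inner loops are contiguous. Likelihood gradients with respect
// to all branch lengths come from one extra pre-order pass (dP/dt = Q P).
// An exact CTMC (Gillespie) simulator with per-site omega shares the sparse
// structure.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

constexpr int NS = 61;

// Sparse GY94 rate matrix, uniformized: M = I + Q/lambda.
struct Model {
  int nnz;
  std::vector<int> rowPtr, colIdx;   // off-diagonal q_ij, by row i
  std::vector<double> qval;          // q_ij (unscaled)
  std::vector<double> qdiag;         // q_ii (unscaled, negative)
  std::vector<double> mval;          // q_ij / lambda
  std::vector<double> mdiag;         // 1 + q_ii / lambda
  double mu;                         // mean flux: -sum pi_i q_ii
  double lambda;                     // max |q_ii| (uniformization rate)
};

// The sparsity pattern (which codon pairs touch) never changes; cache it
// once and only refill the numeric values per (kappa, omega, pi) call.
struct Sparsity {
  bool built = false;
  int np = 0;
  std::vector<int> rowPtr, colIdx;
  std::vector<int> slotIJ, slotJI;   // CSR slot of (i->j) and (j->i) per pair
};
Sparsity g_sp;

void buildSparsity(const IntegerMatrix& pairs) {
  int np = pairs.nrow();
  std::vector<int> deg(NS, 0);
  for (int k = 0; k < np; ++k) {
    ++deg[pairs(k, 0) - 1];
    ++deg[pairs(k, 1) - 1];
  }
  g_sp.rowPtr.assign(NS + 1, 0);
  for (int i = 0; i < NS; ++i) g_sp.rowPtr[i + 1] = g_sp.rowPtr[i] + deg[i];
  g_sp.colIdx.assign(g_sp.rowPtr[NS], 0);
  g_sp.slotIJ.assign(np, 0);
  g_sp.slotJI.assign(np, 0);
  std::vector<int> fill(NS, 0);
  for (int k = 0; k < np; ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    g_sp.slotIJ[k] = g_sp.rowPtr[i] + fill[i];
    g_sp.colIdx[g_sp.slotIJ[k]] = j;
    ++fill[i];
    g_sp.slotJI[k] = g_sp.rowPtr[j] + fill[j];
    g_sp.colIdx[g_sp.slotJI[k]] = i;
    ++fill[j];
  }
  g_sp.np = np;
  g_sp.built = true;
}

Model buildModel(double kappa, double omega, double synScale,
                 const arma::vec& pi, const IntegerMatrix& pairs) {
  if (!g_sp.built || g_sp.np != pairs.nrow()) buildSparsity(pairs);
  Model m;
  m.rowPtr = g_sp.rowPtr;
  m.colIdx = g_sp.colIdx;
  m.nnz = g_sp.rowPtr[NS];
  m.qval.resize(m.nnz);
  m.mval.resize(m.nnz);
  m.qdiag.assign(NS, 0.0);
  m.mdiag.resize(NS);
  m.mu = 0.0;
  int np = pairs.nrow();
  for (int k = 0; k < np; ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double s = 1.0;
    if (pairs(k, 2)) s *= kappa;
    s *= pairs(k, 3) ? synScale : omega;
    m.qval[g_sp.slotIJ[k]] = s * pi[j];
    m.qval[g_sp.slotJI[k]] = s * pi[i];
    m.qdiag[i] -= s * pi[j];
    m.qdiag[j] -= s * pi[i];
    m.mu += 2.0 * s * pi[i] * pi[j];
  }
  m.lambda = 0.0;
  for (int i = 0; i < NS; ++i) m.lambda = std::max(m.lambda, -m.qdiag[i]);
  for (int k = 0; k < m.nnz; ++k) m.mval[k] = m.qval[k] / m.lambda;
  for (int i = 0; i < NS; ++i) m.mdiag[i] = 1.0 + m.qdiag[i] / m.lambda;
  return m;
}

// out = X * (M')  for pattern-major X (n x NS): out[:,i] = sum_j M_ij X[:,j].
// Simultaneously accumulates acc[:,i] += p * out[:,i] (the Poisson-weighted
// series term), saving one full matrix pass per term.
void mMul(const Model& m, const arma::mat& X, arma::mat& out,
          arma::mat& acc, double p) {
  int n = X.n_rows;
  for (int i = 0; i < NS; ++i) {
    double* __restrict y = out.colptr(i);
    const double* __restrict xi = X.colptr(i);
    const double di = m.mdiag[i];
    for (int s = 0; s < n; ++s) y[s] = di * xi[s];
    int k0 = m.rowPtr[i], k1 = m.rowPtr[i + 1];
    for (int k = k0; k < k1; ++k) {
      const double* __restrict xj = X.colptr(m.colIdx[k]);
      const double v = m.mval[k];
      for (int s = 0; s < n; ++s) y[s] += v * xj[s];
    }
    double* __restrict a = acc.colptr(i);
    for (int s = 0; s < n; ++s) a[s] += p * y[s];
  }
}

// out = X * M  for pattern-major X: out[:,j] = sum_i M_ij X[:,i]
// (applies P(t)' in the pattern-major representation), with fused
// acc[:,j] += p * out[:,j].
void mMulT(const Model& m, const arma::mat& X, arma::mat& out,
           arma::mat& acc, double p) {
  int n = X.n_rows;
  for (int j = 0; j < NS; ++j) {
    double* __restrict y = out.colptr(j);
    const double* __restrict xj = X.colptr(j);
    const double dj = m.mdiag[j];
    for (int s = 0; s < n; ++s) y[s] = dj * xj[s];
  }
  for (int i = 0; i < NS; ++i) {
    const double* __restrict xi = X.colptr(i);
    for (int k = m.rowPtr[i]; k < m.rowPtr[i + 1]; ++k) {
      double* __restrict y = out.colptr(m.colIdx[k]);
      const double v = m.mval[k];
      for (int s = 0; s < n; ++s) y[s] += v * xi[s];
    }
  }
  for (int j = 0; j < NS; ++j) {
    double* __restrict a = acc.colptr(j);
    const double* __restrict y = out.colptr(j);
    for (int s = 0; s < n; ++s) a[s] += p * y[s];
  }
}

// out = X * (Q'/mu): out[:,i] = sum_j Q_ij X[:,j] / mu.
void qMul(const Model& m, const arma::mat& X, arma::mat& out) {
  int n = X.n_rows;
  out.set_size(n, NS);
  for (int i = 0; i < NS; ++i) {
    double* __restrict y = out.colptr(i);
    const double* __restrict xi = X.colptr(i);
    const double di = m.qdiag[i] / m.mu;
    for (int s = 0; s < n; ++s) y[s] = di * xi[s];
    for (int k = m.rowPtr[i]; k < m.rowPtr[i + 1]; ++k) {
      const double* __restrict xj = X.colptr(m.colIdx[k]);
      const double v = m.qval[k] / m.mu;
      for (int s = 0; s < n; ++s) y[s] += v * xj[s];
    }
  }
}

// C <- C applied through P(t) (pattern-major), by uniformization;
// t in expected substitutions per codon. transpose applies P(t)'.
void applyExp(const Model& m, double t, arma::mat& C, bool transpose = false,
              double tol = 1e-13) {
  double a = m.lambda * t / m.mu;
  if (a <= 0.0) return;
  double p = std::exp(-a), cum = p;
  arma::mat term = C, nxt(C.n_rows, NS);
  arma::mat acc = p * C;
  int K = (int)std::ceil(a + 12.0 * std::sqrt(a + 1.0)) + 20;
  for (int k = 1; k <= K; ++k) {
    p *= a / k;
    cum += p;
    if (transpose) mMulT(m, term, nxt, acc, p);
    else mMul(m, term, nxt, acc, p);
    term.swap(nxt);
    if (cum > 1.0 - tol) break;
  }
  C = std::move(acc);
}

struct TreeWork {
  std::vector<arma::mat> msg;            // per edge (npat x NS)
  std::vector<arma::mat> up;             // per internal node (npat x NS)
  std::vector<bool> hasUp;
  arma::vec lik;                         // per pattern
  int root, nnode;
};

// All tip-edge transition matrices restricted to the union of observed
// states, in one shared power series: the M^k Krylov sequence does not
// depend on branch length, only the Poisson weights do, so one sequence
// serves every tip edge.
void tipEdgeMatrices(const Model& m, const IntegerMatrix& tips,
                     const IntegerMatrix& edges, const NumericVector& blens,
                     const std::vector<int>& tipEdgeIdx,
                     std::vector<int>& stateRow,
                     std::vector<arma::mat>& acc, double tol) {
  int npat = tips.ncol();
  stateRow.assign(NS, -1);
  std::vector<int> uniq;
  for (int e : tipEdgeIdx) {
    int c = edges(e, 1);
    for (int s = 0; s < npat; ++s) {
      int st = tips(c - 1, s) - 1;
      if (stateRow[st] < 0) { stateRow[st] = (int)uniq.size(); uniq.push_back(st); }
    }
  }
  int nu = (int)uniq.size(), ne = (int)tipEdgeIdx.size();
  arma::mat Z(nu, NS, arma::fill::zeros);
  for (int u = 0; u < nu; ++u) Z(u, uniq[u]) = 1.0;

  std::vector<double> a(ne), p(ne), cum(ne);
  double amax = 0.0;
  acc.assign(ne, arma::mat());
  for (int j = 0; j < ne; ++j) {
    a[j] = m.lambda * blens[tipEdgeIdx[j]] / m.mu;
    p[j] = std::exp(-a[j]);
    cum[j] = p[j];
    acc[j] = p[j] * Z;
    amax = std::max(amax, a[j]);
  }
  if (amax <= 0.0) return;
  int K = (int)std::ceil(amax + 12.0 * std::sqrt(amax + 1.0)) + 20;
  arma::mat nxt(nu, NS);
  arma::mat dummy(nu, NS);
  for (int k = 1; k <= K; ++k) {
    mMul(m, Z, nxt, dummy, 0.0);
    Z.swap(nxt);
    bool all = true;
    for (int j = 0; j < ne; ++j) {
      if (cum[j] > 1.0 - tol) continue;
      p[j] *= a[j] / k;
      cum[j] += p[j];
      // acc_j += p_j * Z
      for (int i = 0; i < NS; ++i) {
        double* __restrict y = acc[j].colptr(i);
        const double* __restrict z = Z.colptr(i);
        for (int s = 0; s < nu; ++s) y[s] += p[j] * z[s];
      }
      if (cum[j] <= 1.0 - tol) all = false;
    }
    if (all) break;
  }
}

void postOrder(const Model& m, const IntegerMatrix& tips,
               const IntegerMatrix& edges, const NumericVector& blens,
               TreeWork& W, bool keepMsg, double tol) {
  int ntips = tips.nrow(), npat = tips.ncol(), nedge = edges.nrow();
  int nnode = 0;
  for (int k = 0; k < nedge; ++k)
    nnode = std::max(nnode, std::max(edges(k, 0), edges(k, 1)));
  W.nnode = nnode;
  W.root = edges(0, 0);
  W.up.assign(nnode + 1, arma::mat());
  W.hasUp.assign(nnode + 1, false);
  if (keepMsg) W.msg.assign(nedge, arma::mat());

  std::vector<int> tipEdgeIdx;
  for (int k = 0; k < nedge; ++k)
    if (edges(k, 1) <= ntips) tipEdgeIdx.push_back(k);
  std::vector<int> stateRow;
  std::vector<arma::mat> tipP;
  tipEdgeMatrices(m, tips, edges, blens, tipEdgeIdx, stateRow, tipP, tol);
  std::vector<int> whichTip(nedge, -1);
  for (size_t j = 0; j < tipEdgeIdx.size(); ++j) whichTip[tipEdgeIdx[j]] = (int)j;

  for (int k = nedge - 1; k >= 0; --k) {
    int p = edges(k, 0), c = edges(k, 1);
    arma::mat msg;
    if (c <= ntips) {
      const arma::mat& Pu = tipP[whichTip[k]];
      msg.set_size(npat, NS);
      for (int i = 0; i < NS; ++i) {
        double* __restrict y = msg.colptr(i);
        const double* __restrict e = Pu.colptr(i);
        for (int s = 0; s < npat; ++s) y[s] = e[stateRow[tips(c - 1, s) - 1]];
      }
    } else {
      msg = W.up[c];
      applyExp(m, blens[k], msg, false, tol);
    }
    if (!W.hasUp[p]) { W.up[p] = msg; W.hasUp[p] = true; }
    else W.up[p] %= msg;
    if (keepMsg) W.msg[k] = std::move(msg);
  }
}

double patternLogLik(const arma::vec& pi, const NumericVector& w,
                     TreeWork& W, bool& ok) {
  int npat = W.up[W.root].n_rows;
  W.lik = W.up[W.root] * pi;
  double ll = 0.0;
  ok = true;
  for (int s = 0; s < npat; ++s) {
    double v = W.lik[s];
    if (v <= 0.0 || !std::isfinite(v)) { ok = false; return -1e300; }
    ll += w[s] * std::log(v);
  }
  return ll;
}

} // namespace

// Log-likelihood of gapless codon site patterns under the single-omega GY94
// model. `edges` is the ape edge matrix (parent, child; cladewise), `tips`
// is ntips x npat of 1-based sense-codon indices, `weights` the pattern
// multiplicities.
// [[Rcpp::export(rng = false)]]
double cpp_gy94_loglik(IntegerMatrix tips, NumericVector weights,
                       IntegerMatrix edges, NumericVector blens,
                       double kappa, double omega, NumericVector pi_,
                       IntegerMatrix pairs, double tol = 1e-13) {
  arma::vec pi(pi_.begin(), pi_.size());
  Model m = buildModel(kappa, omega, 1.0, pi, pairs);
  TreeWork W;
  postOrder(m, tips, edges, blens, W, false, tol);
  bool ok;
  return patternLogLik(pi, weights, W, ok);
}

// Log-likelihood plus its gradient with respect to every branch length
// (in expected-substitutions-per-codon units), via a pre-order pass.
// [[Rcpp::export(rng = false)]]
List cpp_gy94_loglik_grad(IntegerMatrix tips, NumericVector weights,
                          IntegerMatrix edges, NumericVector blens,
                          double kappa, double omega, NumericVector pi_,
                          IntegerMatrix pairs, double tol = 1e-13) {
  arma::vec pi(pi_.begin(), pi_.size());
  Model m = buildModel(kappa, omega, 1.0, pi, pairs);
  int nedge = edges.nrow(), ntips = tips.nrow();
  TreeWork W;
  postOrder(m, tips, edges, blens, W, true, tol);
  bool ok;
  double ll = patternLogLik(pi, weights, W, ok);
  NumericVector grad(nedge);
  if (!ok)
    return List::create(_["loglik"] = ll, _["gradBlens"] = grad);

  int npat = W.lik.n_elem;
  arma::vec invLikW(npat);
  for (int s = 0; s < npat; ++s) invLikW[s] = weights[s] / W.lik[s];

  // down[v]: pattern-wise partial likelihood of everything outside v's
  // subtree, as seen entering v's parent edge.
  std::vector<arma::mat> down(W.nnode + 1);
  arma::mat qm;
  for (int k = 0; k < nedge; ++k) {   // cladewise: parents first
    int p = edges(k, 0), c = edges(k, 1);
    // F = (pi-weighted down[p]) * product of sibling messages
    arma::mat F;
    bool init = false;
    for (int k2 = 0; k2 < nedge; ++k2) {
      if (edges(k2, 0) != p || k2 == k) continue;
      if (!init) { F = W.msg[k2]; init = true; }
      else F %= W.msg[k2];
    }
    if (!init) F.ones(npat, NS);
    if (p == W.root) F.each_row() %= pi.t();
    else F %= down[p];
    // d lnL / d t_k = sum_s w_s <F(s,:), (Q/mu) msg_k(s,:)> / lik_s
    qMul(m, W.msg[k], qm);
    arma::vec per = arma::sum(F % qm, 1);
    grad[k] = arma::dot(per, invLikW);
    if (c > ntips) {
      applyExp(m, blens[k], F, true, tol);   // P(t)' F
      down[c] = std::move(F);
    }
  }
  return List::create(_["loglik"] = ll, _["gradBlens"] = grad);
}

// Flux decomposition of the scaled rate matrix (dN/dS site bookkeeping).
// [[Rcpp::export(rng = false)]]
NumericVector cpp_gy94_flux(double kappa, double omega, double synScale,
                            NumericVector pi_, IntegerMatrix pairs) {
  arma::vec pi(pi_.begin(), pi_.size());
  int np = pairs.nrow();
  double fN = 0.0, fS = 0.0;
  for (int k = 0; k < np; ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double s = 1.0;
    if (pairs(k, 2)) s *= kappa;
    s *= pairs(k, 3) ? synScale : omega;
    double f = 2.0 * s * pi[i] * pi[j];
    if (pairs(k, 3)) fS += f; else fN += f;
  }
  return NumericVector::create(_["fluxN"] = fN, _["fluxS"] = fS);
}

// Exact CTMC simulation of codon sites along a tree. Each site has its own
// omega, defined as the observable dN/dS: synScale multiplies the whole
// rate matrix (synonymous entries directly, nonsynonymous entries via
// omega * synScale), so synScale < 1 slows both rate classes uniformly
// while omega remains the nonsynonymous/synonymous ratio a single-omega
// estimator recovers. Time units are expected substitutions per codon
// under the neutral (omega = 1, synScale = 1) matrix with the same pi, so
// site-specific selection changes substitution counts rather than the
// clock. Root states are drawn from pi. Uses R's RNG; seed via set.seed()
// on the R side.
// [[Rcpp::export]]
List cpp_simulate_sites(IntegerMatrix edges, NumericVector blens, int ntips,
                        NumericVector omega_, double kappa, double synScale,
                        NumericVector pi_, IntegerMatrix pairs) {
  int nsites = omega_.size();
  arma::vec pi(pi_.begin(), pi_.size());
  int nedge = edges.nrow();

  std::vector<std::vector<int>> nb(NS), nbTs(NS), nbSyn(NS);
  for (int k = 0; k < pairs.nrow(); ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    nb[i].push_back(j); nbTs[i].push_back(pairs(k, 2)); nbSyn[i].push_back(pairs(k, 3));
    nb[j].push_back(i); nbTs[j].push_back(pairs(k, 2)); nbSyn[j].push_back(pairs(k, 3));
  }

  // neutral mean flux defines the time scale
  double mu0 = 0.0;
  for (int k = 0; k < pairs.nrow(); ++k) {
    int i = pairs(k, 0) - 1, j = pairs(k, 1) - 1;
    double s = pairs(k, 2) ? kappa : 1.0;
    mu0 += 2.0 * s * pi[i] * pi[j];
  }

  int nnode = 0;
  for (int k = 0; k < nedge; ++k)
    nnode = std::max(nnode, std::max(edges(k, 0), edges(k, 1)));

  IntegerMatrix tips(ntips, nsites);
  IntegerVector nSyn(nsites), nNonsyn(nsites);
  std::vector<int> state(nnode + 1, 0);
  std::vector<double> rate(16);

  for (int s = 0; s < nsites; ++s) {
    double om = omega_[s];
    double u = unif_rand(), acc = 0.0;
    int rootState = NS - 1;
    for (int i = 0; i < NS; ++i) {
      acc += pi[i];
      if (u <= acc) { rootState = i; break; }
    }
    state[edges(0, 0)] = rootState;
    int cs = 0, cn = 0;
    for (int k = 0; k < nedge; ++k) {  // cladewise: parent states set first
      int p = edges(k, 0), c = edges(k, 1);
      int st = state[p];
      double remain = blens[k];
      for (;;) {
        double tot = 0.0;
        size_t deg = nb[st].size();
        for (size_t q = 0; q < deg; ++q) {
          double r = pi[nb[st][q]] * synScale;
          if (nbTs[st][q]) r *= kappa;
          if (!nbSyn[st][q]) r *= om;
          rate[q] = r / mu0;
          tot += rate[q];
        }
        if (tot <= 0.0) break;
        double wait = exp_rand() / tot;
        if (wait >= remain) break;
        remain -= wait;
        double v = unif_rand() * tot, a2 = 0.0;
        size_t pick = deg - 1;
        for (size_t q = 0; q < deg; ++q) {
          a2 += rate[q];
          if (v <= a2) { pick = q; break; }
        }
        if (nbSyn[st][pick]) ++cs; else ++cn;
        st = nb[st][pick];
      }
      state[c] = st;
    }
    for (int tp = 1; tp <= ntips; ++tp) tips(tp - 1, s) = state[tp] + 1;
    nSyn[s] = cs;
    nNonsyn[s] = cn;
  }
  return List::create(_["tips"] = tips, _["nSyn"] = nSyn,
                      _["nNonsyn"] = nNonsyn);
}
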