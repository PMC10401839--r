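#include <Rcpp.h>
using namespace Rcpp;

// EM for the symmetric PLSA aspect model P(i,v) = sum_z P(z)P(i|z)P(v|z),
// restricted to observed (nonzero) cells of the co-occurrence matrix.
// Each iteration first evaluates the log-likelihood of the current
// parameters over the observed cells, tests relative convergence against
// the previous evaluation, and only then applies one E+M update. A small
// probability floor is applied after each M-step (then renormalized) to
// keep the log-likelihood finite on sparse data.
//
// ii, vv: 0-based cell indices; w: cell counts (1 for binary matrices).
// [[Rcpp::export]]
List plsa_em_cpp(IntegerVector ii, IntegerVector vv, NumericVector w,
                 int I, int V, int K,
                 NumericVector pz0, NumericMatrix pi0, NumericMatrix pv0,
                 int max_iter, double tol, double floor_p) {
  int ncell = ii.size();
  NumericVector pz = clone(pz0);
  NumericMatrix pi_z = clone(pi0);  // I x K
  NumericMatrix pv_z = clone(pv0);  // V x K
  std::vector<double> trace;
  std::vector<double> joint(K);
  NumericVector new_pz(K);
  NumericMatrix new_pi(I, K), new_pv(V, K);

  double R = 0.0;
  for (int c = 0; c < ncell; ++c) R += w[c];

  double prev_ll = NA_REAL;
  bool converged = false;
  int n_updates = 0;

  const int *pii = INTEGER(ii), *pvv = INTEGER(vv);
  const double *pw = REAL(w);
  double *ppz = REAL(pz), *ppi = REAL(pi_z), *ppv = REAL(pv_z);
  double *pnz = REAL(new_pz), *pni = REAL(new_pi), *pnv = REAL(new_pv);

  for (int t = 0; t <= max_iter; ++t) {
    // E-step pass: responsibilities and log-likelihood of current params
    std::fill(new_pz.begin(), new_pz.end(), 0.0);
    std::fill(new_pi.begin(), new_pi.end(), 0.0);
    std::fill(new_pv.begin(), new_pv.end(), 0.0);
    double ll = 0.0;
    for (int c = 0; c < ncell; ++c) {
      int i = pii[c], v = pvv[c];
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        joint[k] = ppz[k] * ppi[i + (size_t)k * I] * ppv[v + (size_t)k * V];
        s += joint[k];
      }
      if (s <= 0.0) {
        stop("observed cell (%d, %d) has zero modeled probability; "
             "probability floor is broken", i + 1, v + 1);
      }
      ll += pw[c] * std::log(s);
      double inv = pw[c] / s;
      for (int k = 0; k < K; ++k) {
        double r = joint[k] * inv;
        pnz[k] += r;
        pni[i + (size_t)k * I] += r;
        pnv[v + (size_t)k * V] += r;
      }
    }
    trace.push_back(ll);
    if (t > 0 && std::abs(ll - prev_ll) / std::abs(prev_ll) < tol) {
      converged = true;
      break;
    }
    prev_ll = ll;
    if (t == max_iter) break;  // budget exhausted; params stay at last M-step

    // M-step: normalize, then floor and renormalize
    for (int k = 0; k < K; ++k) {
      double nz = pnz[k];
      double *ci = ppi + (size_t)k * I, *cv = ppv + (size_t)k * V;
      const double *ni = pni + (size_t)k * I, *nv = pnv + (size_t)k * V;
      if (nz > 0.0) {
        for (int i = 0; i < I; ++i) ci[i] = ni[i] / nz;
        for (int v = 0; v < V; ++v) cv[v] = nv[v] / nz;
      } else {
        for (int i = 0; i < I; ++i) ci[i] = 1.0 / I;
        for (int v = 0; v < V; ++v) cv[v] = 1.0 / V;
      }
      ppz[k] = nz / R;
    }
    double zs = 0.0;
    for (int k = 0; k < K; ++k) {
      if (ppz[k] < floor_p) ppz[k] = floor_p;
      zs += ppz[k];
    }
    for (int k = 0; k < K; ++k) ppz[k] /= zs;
    for (int k = 0; k < K; ++k) {
      double *ci = ppi + (size_t)k * I, *cv = ppv + (size_t)k * V;
      double si = 0.0, sv = 0.0;
      for (int i = 0; i < I; ++i) {
        if (ci[i] < floor_p) ci[i] = floor_p;
        si += ci[i];
      }
      for (int i = 0; i < I; ++i) ci[i] /= si;
      for (int v = 0; v < V; ++v) {
        if (cv[v] < floor_p) cv[v] = floor_p;
        sv += cv[v];
      }
      for (int v = 0; v < V; ++v) cv[v] /= sv;
    }
    ++n_updates;
  }

  return List::create(
    _["pz"] = pz, _["pi_z"] = pi_z, _["pv_z"] = pv_z,
    _["loglik"] = trace.back(),
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["n_iter"] = n_updates,
    _["converged"] = converged
  );
}
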