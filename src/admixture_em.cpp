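#include <Rcpp.h>
using namespace Rcpp;

// EM for the binomial admixture likelihood
//   l = sum_ij [ g_ij log p_ij + (2 - g_ij) log(1 - p_ij) ],
//   p_ij = sum_k q_ik f_kj.
// Per allele copy, the posterior responsibility of ancestral origin k is
// a_ijk = q_ik f_kj / p_ij (alt copies) and b_ijk = q_ik (1 - f_kj) /
// (1 - p_ij) (ref copies); the M-step averages them into Q and F.
// Dosages g may be real-valued (expected counts). Returns the updated
// parameters, the per-iterate log-likelihood trace (non-decreasing), the
// number of M-step updates performed, and a convergence flag.
// [[Rcpp::export]]
List admixture_em_cpp(NumericMatrix g, NumericMatrix Q, NumericMatrix F,
                      int maxIter, double tol, double eps) {
    const int n = g.nrow(), m = g.ncol(), K = Q.ncol();
    std::vector<double> qnum(n * K), fnum(K * m), fden(K * m), pk(K);
    std::vector<double> trace;
    trace.reserve(maxIter + 1);
    bool converged = false;
    int updates = 0;

    for (int it = 0; it < maxIter; ++it) {
        std::fill(qnum.begin(), qnum.end(), 0.0);
        std::fill(fnum.begin(), fnum.end(), 0.0);
        std::fill(fden.begin(), fden.end(), 0.0);
        double ll = 0.0;
        for (int i = 0; i < n; ++i) {
            for (int j = 0; j < m; ++j) {
                double p = 0.0;
                for (int k = 0; k < K; ++k) {
                    pk[k] = Q(i, k) * F(k, j);
                    p += pk[k];
                }
                if (p < eps) p = eps;
                if (p > 1.0 - eps) p = 1.0 - eps;
                const double gij = g(i, j), hij = 2.0 - gij;
                ll += gij * std::log(p) + hij * std::log(1.0 - p);
                for (int k = 0; k < K; ++k) {
                    const double a = gij * pk[k] / p;
                    const double b = hij * Q(i, k) * (1.0 - F(k, j)) / (1.0 - p);
                    qnum[i * K + k] += a + b;
                    fnum[k * m + j] += a;
                    fden[k * m + j] += a + b;
                }
            }
        }
        trace.push_back(ll);
        if (!std::isfinite(ll))
            stop("non-finite admixture log-likelihood at iteration %d", it + 1);
        if (it > 0 && ll - trace[it - 1] < tol) {
            converged = true;
            break;
        }
        // M-step
        for (int i = 0; i < n; ++i) {
            double s = 0.0;
            for (int k = 0; k < K; ++k) s += qnum[i * K + k];
            if (s <= 0.0) s = 1.0;
            for (int k = 0; k < K; ++k) Q(i, k) = qnum[i * K + k] / s;
        }
        for (int k = 0; k < K; ++k) {
            for (int j = 0; j < m; ++j) {
                double den = fden[k * m + j];
                double f = den > 0.0 ? fnum[k * m + j] / den : 0.5;
                if (f < eps) f = eps;
                if (f > 1.0 - eps) f = 1.0 - eps;
                F(k, j) = f;
            }
        }
        ++updates;
    }

    if (!converged) {
        // evaluate the log-likelihood of the final iterate
        double ll = 0.0;
        for (int i = 0; i < n; ++i)
            for (int j = 0; j < m; ++j) {
                double p = 0.0;
                for (int k = 0; k < K; ++k) p += Q(i, k) * F(k, j);
                if (p < eps) p = eps;
                if (p > 1.0 - eps) p = 1.0 - eps;
                ll += g(i, j) * std::log(p) + (2.0 - g(i, j)) * std::log(1.0 - p);
            }
        trace.push_back(ll);
    }

    return List::create(_["Q"] = Q, _["F"] = F,
                        _["logLik"] = NumericVector(trace.begin(), trace.end()),
                        _["iter"] = updates, _["converged"] = converged);
}
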