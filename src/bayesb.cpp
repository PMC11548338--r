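#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the BayesB model
//   y = Q beta + Z gamma + e,
// flat prior on beta; per-marker mixture prior on gamma_j: point mass at 0
// with probability 1 - pi, and a normal with marker-specific variance
// s2_j ~ scaled-inv-chi2(nu, S) otherwise (the scaled-t slab written as a
// scale mixture of normals); e ~ N(0, sigma2 I) with sigma2 ~
// scaled-inv-chi2(nuE, SE). Uses R's RNG, so runs are reproducible from
// set.seed() in the caller. Returns posterior means after burn-in/thinning.
// [[Rcpp::export]]
List bayesb_gibbs_cpp(NumericVector y, NumericMatrix Qm, NumericMatrix Z,
                      int nIter, int burnIn, int thin, double pi0,
                      double nu, double S, double nuE, double SE,
                      bool updatePi) {
    const int n = y.size(), l = Qm.ncol(), g = Z.ncol();
    std::vector<double> qtq(l), ztz(g);
    for (int c = 0; c < l; ++c) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += Qm(i, c) * Qm(i, c);
        qtq[c] = s;
    }
    for (int j = 0; j < g; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
        ztz[j] = s;
    }

    std::vector<double> beta(l, 0.0), gamma(g, 0.0), s2j(g);
    std::vector<int> delta(g, 0);
    double ybar = 0.0, yss = 0.0;
    for (int i = 0; i < n; ++i) ybar += y[i];
    ybar /= n;
    for (int i = 0; i < n; ++i) yss += (y[i] - ybar) * (y[i] - ybar);
    double sigma2 = std::max(yss / std::max(1, n - 1) * 0.5, 1e-8);
    const double s2init = nu > 2.0 ? S * nu / (nu - 2.0) : S;
    std::fill(s2j.begin(), s2j.end(), s2init);
    beta[0] = ybar;   // first column of Qm is the intercept

    std::vector<double> e(n);
    for (int i = 0; i < n; ++i) {
        double fit = 0.0;
        for (int c = 0; c < l; ++c) fit += Qm(i, c) * beta[c];
        e[i] = y[i] - fit;
    }

    std::vector<double> betaSum(l, 0.0), gammaSum(g, 0.0), pipSum(g, 0.0);
    double sigma2Sum = 0.0, piSum = 0.0, pi = pi0;
    int nSamples = 0;

    for (int sweep = 1; sweep <= nIter; ++sweep) {
        // fixed effects, flat prior
        for (int c = 0; c < l; ++c) {
            double rhs = 0.0;
            for (int i = 0; i < n; ++i) {
                e[i] += Qm(i, c) * beta[c];
                rhs += Qm(i, c) * e[i];
            }
            beta[c] = rhs / qtq[c] + norm_rand() * std::sqrt(sigma2 / qtq[c]);
            for (int i = 0; i < n; ++i) e[i] -= Qm(i, c) * beta[c];
        }
        // marker effects
        int nIn = 0;
        for (int j = 0; j < g; ++j) {
            double rhs = 0.0;
            if (delta[j]) {
                for (int i = 0; i < n; ++i) {
                    e[i] += Z(i, j) * gamma[j];
                    rhs += Z(i, j) * e[i];
                }
            } else {
                for (int i = 0; i < n; ++i) rhs += Z(i, j) * e[i];
            }
            const double c1 = ztz[j], v = s2j[j];
            const double logOdds = std::log(pi / (1.0 - pi)) +
                0.5 * std::log(sigma2 / (c1 * v + sigma2)) +
                0.5 * rhs * rhs * v / (sigma2 * (c1 * v + sigma2));
            const double p1 = 1.0 / (1.0 + std::exp(-logOdds));
            if (unif_rand() < p1) {
                const double prec = c1 + sigma2 / v;
                gamma[j] = rhs / prec + norm_rand() * std::sqrt(sigma2 / prec);
                delta[j] = 1;
                ++nIn;
                for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * gamma[j];
                s2j[j] = (gamma[j] * gamma[j] + nu * S) / R::rchisq(nu + 1.0);
            } else {
                gamma[j] = 0.0;
                delta[j] = 0;
                s2j[j] = nu * S / R::rchisq(nu);   // prior draw keeps the chain proper
            }
        }
        // residual variance
        double ess = 0.0;
        for (int i = 0; i < n; ++i) ess += e[i] * e[i];
        sigma2 = (ess + nuE * SE) / R::rchisq((double) n + nuE);
        if (!std::isfinite(sigma2) || sigma2 <= 0.0)
            stop("divergent residual variance at sweep %d", sweep);
        if (updatePi) {
            pi = R::rbeta(1.0 + nIn, 1.0 + g - nIn);
            pi = std::min(std::max(pi, 1e-6), 1.0 - 1e-6);
        }
        // accumulate posterior means
        if (sweep > burnIn && (sweep - burnIn) % thin == 0) {
            for (int c = 0; c < l; ++c) betaSum[c] += beta[c];
            for (int j = 0; j < g; ++j) {
                gammaSum[j] += gamma[j];
                pipSum[j] += delta[j];
            }
            sigma2Sum += sigma2;
            piSum += pi;
            ++nSamples;
        }
    }
    if (nSamples == 0) stop("no posterior samples: check nIter/burnIn/thin");

    NumericVector betaHat(l), gammaHat(g), pip(g);
    for (int c = 0; c < l; ++c) betaHat[c] = betaSum[c] / nSamples;
    for (int j = 0; j < g; ++j) {
        gammaHat[j] = gammaSum[j] / nSamples;
        pip[j] = pipSum[j] / nSamples;
    }
    return List::create(_["beta"] = betaHat, _["gamma"] = gammaHat,
                        _["pip"] = pip, _["sigma2"] = sigma2Sum / nSamples,
                        _["pi"] = piSum / nSamples,
                        _["nSamples"] = nSamples);
}
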