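// Collapsed Gibbs sampler for the Hierarchical Dirichlet Process neutral
// model (metacommunity distribution beta with stick mass for unobserved
// taxa, speciation parameter theta, per-sample immigration rates I_i) and
// the posterior-predictive neutrality test that compares observed and
// synthetic Dirichlet-multinomial log-likelihoods draw by draw.
//
// Uses R's RNG throughout so set.seed() on the R side makes runs exact.

#include <Rcpp.h>
using namespace Rcpp;

// Dirichlet-multinomial log-likelihood of count matrix X (M x S) given the
// metacommunity distribution beta over S components plus unobserved mass
// (total concentration I_i), including the multinomial coefficient.
static double dm_loglik(const IntegerMatrix& X, const NumericVector& beta,
                        const NumericVector& I) {
    const int M = X.nrow(), S = X.ncol();
    double ll = 0.0;
    for (int i = 0; i < M; ++i) {
        double n = 0.0;
        for (int j = 0; j < S; ++j) n += X(i, j);
        ll += R::lgammafn(I[i]) - R::lgammafn(I[i] + n) + R::lgammafn(n + 1.0);
        for (int j = 0; j < S; ++j) {
            const double a = I[i] * beta[j];
            const double x = X(i, j);
            if (x > 0)
                ll += R::lgammafn(a + x) - R::lgammafn(a) -
                    R::lgammafn(x + 1.0);
        }
    }
    return ll;
}

// number of occupied tables when x customers enter a CRP(a) restaurant
static int antoniak_draw(int x, double a) {
    int t = 0;
    for (int c = 0; c < x; ++c)
        if (R::unif_rand() < a / (a + c)) ++t;
    return t;
}

// univariate slice sampler (stepping out) on an R function-free log target
template <class F>
static double slice_sample(double x0, const F& logf, double w, int m) {
    const double y = logf(x0) + std::log(R::unif_rand());
    double L = x0 - w * R::unif_rand();
    double Rr = L + w;
    int j = (int)std::floor(m * R::unif_rand());
    int k = m - 1 - j;
    while (j-- > 0 && y < logf(L)) L -= w;
    while (k-- > 0 && y < logf(Rr)) Rr += w;
    for (;;) {
        const double x1 = L + (Rr - L) * R::unif_rand();
        if (y < logf(x1)) return x1;
        if (x1 < x0) L = x1; else Rr = x1;
    }
}

// [[Rcpp::export]]
List cpp_hdp_gibbs(IntegerMatrix X, int sweeps, int burn_in, int thinning,
                   double prior_mu, double prior_sd) {
    const int M = X.nrow(), S = X.ncol();
    NumericVector n(M);
    for (int i = 0; i < M; ++i) {
        double s = 0.0;
        for (int j = 0; j < S; ++j) s += X(i, j);
        n[i] = s;
    }
    // state
    NumericVector beta(S + 1);
    {
        double tot = 0.0;
        for (int j = 0; j < S; ++j) {
            double cs = 0.0;
            for (int i = 0; i < M; ++i) cs += X(i, j);
            beta[j] = cs + 0.5;
            tot += beta[j];
        }
        tot += 1.0;
        beta[S] = 1.0;
        for (int j = 0; j <= S; ++j) beta[j] /= tot;
    }
    double theta = 10.0;
    NumericVector I(M, 10.0);
    IntegerMatrix t(M, S);

    const int n_keep = (sweeps - burn_in) / thinning;
    NumericMatrix beta_out(n_keep, S + 1);
    NumericVector theta_out(n_keep);
    NumericMatrix I_out(n_keep, M);
    NumericVector ll_out(n_keep);
    int keep = 0;

    for (int sweep = 1; sweep <= sweeps; ++sweep) {
        // 1. latent ancestral (table) counts via the restaurant franchise
        std::vector<double> T(S, 0.0);
        NumericVector trow(M, 0.0);
        for (int i = 0; i < M; ++i)
            for (int j = 0; j < S; ++j) {
                const int x = X(i, j);
                if (x == 0) { t(i, j) = 0; continue; }
                const int tij = antoniak_draw(x, I[i] * beta[j]);
                t(i, j) = tij;
                T[j] += tij;
                trow[i] += tij;
            }
        // 2. metacommunity distribution | tables: Dirichlet(T_1..T_S, theta)
        double tot = 0.0;
        for (int j = 0; j < S; ++j) {
            beta[j] = R::rgamma(T[j] > 0 ? T[j] : 1e-3, 1.0);
            tot += beta[j];
        }
        beta[S] = R::rgamma(theta, 1.0);
        tot += beta[S];
        for (int j = 0; j <= S; ++j) beta[j] /= tot;
        // 3. theta | tables (top-level CRP with S dishes, Ttot tables)
        double Ttot = 0.0;
        for (int j = 0; j < S; ++j) Ttot += T[j];
        {
            auto logf = [&](double lt) {
                const double th = std::exp(lt);
                return S * lt + R::lgammafn(th) - R::lgammafn(th + Ttot) +
                    R::dnorm(lt, prior_mu, prior_sd, 1);
            };
            theta = std::exp(slice_sample(std::log(theta), logf, 1.0, 20));
        }
        // 4. immigration rates | per-restaurant table totals
        for (int i = 0; i < M; ++i) {
            const double ti = trow[i], ni = n[i];
            auto logf = [&](double li) {
                const double Ii = std::exp(li);
                return ti * li + R::lgammafn(Ii) - R::lgammafn(Ii + ni) +
                    R::dnorm(li, prior_mu, prior_sd, 1);
            };
            I[i] = std::exp(slice_sample(std::log(I[i]), logf, 1.0, 20));
        }
        if (sweep > burn_in && (sweep - burn_in) % thinning == 0) {
            for (int j = 0; j <= S; ++j) beta_out(keep, j) = beta[j];
            theta_out[keep] = theta;
            for (int i = 0; i < M; ++i) I_out(keep, i) = I[i];
            ll_out[keep] = dm_loglik(X, beta, I);
            ++keep;
        }
    }
    return List::create(_["beta"] = beta_out, _["theta"] = theta_out,
                        _["immigration"] = I_out, _["loglik"] = ll_out);
}

// truncated stick-breaking draw of a neutral metacommunity, S sticks plus
// remainder mass in the last component
static void gem_draw(double theta, int S, std::vector<double>& out) {
    double remain = 1.0;
    for (int j = 0; j < S; ++j) {
        const double v = R::rbeta(1.0, theta);
        out[j] = v * remain;
        remain *= (1.0 - v);
    }
    out[S] = remain;
}

// refit of the metacommunity distribution on a synthetic count matrix
// with immigration rates and theta held fixed: a short collapsed-Gibbs
// chain over ancestral table counts whose final beta draw mirrors the
// posterior-draw character of the main fit (the observed-side beta is a
// posterior draw, so the synthetic-side refit must carry comparable
// posterior noise for the likelihood comparison to be calibrated)
static void refit_beta(const IntegerMatrix& X, const NumericVector& I,
                       double theta, std::vector<double>& beta, int iters) {
    const int M = X.nrow(), S = X.ncol();
    {   // init from pooled relative abundances
        double tot = 0.0;
        std::vector<double> cs(S, 0.0);
        for (int j = 0; j < S; ++j) {
            for (int i = 0; i < M; ++i) cs[j] += X(i, j);
            cs[j] += 0.5;
            tot += cs[j];
        }
        for (int j = 0; j < S; ++j) beta[j] = cs[j] / (tot + theta);
    }
    std::vector<double> T(S);
    for (int it = 0; it < iters; ++it) {
        std::fill(T.begin(), T.end(), 0.0);
        for (int i = 0; i < M; ++i)
            for (int j = 0; j < S; ++j) {
                const int x = X(i, j);
                if (x > 0) T[j] += antoniak_draw(x, I[i] * beta[j]);
            }
        double tot = 0.0;
        for (int j = 0; j < S; ++j) {
            beta[j] = R::rgamma(T[j] > 0 ? T[j] : 1e-3, 1.0);
            tot += beta[j];
        }
        tot += R::rgamma(theta, 1.0);   // residual stick mass
        for (int j = 0; j < S; ++j) beta[j] /= tot;
    }
}

// [[Rcpp::export]]
List cpp_neutrality(IntegerMatrix X, NumericMatrix beta_draws,
                    NumericVector theta_draws, NumericMatrix imm_draws,
                    bool complete, int refit_iters) {
    const int M = X.nrow(), S = X.ncol();
    const int K = beta_draws.nrow();
    NumericVector n(M);
    for (int i = 0; i < M; ++i) {
        double s = 0.0;
        for (int j = 0; j < S; ++j) s += X(i, j);
        n[i] = s;
    }
    NumericVector ll_obs(K), ll_syn(K);
    IntegerMatrix X0(M, S + 1);
    std::vector<double> bstar(S + 1), p(S + 1), b0(S + 1);
    for (int k = 0; k < K; ++k) {
        NumericVector bk = beta_draws(k, _);
        NumericVector Ik = imm_draws(k, _);
        ll_obs[k] = dm_loglik(X, bk, Ik);
        // synthetic matrix with the observed per-sample depths
        if (complete) gem_draw(theta_draws[k], S, bstar);
        else for (int j = 0; j <= S; ++j) bstar[j] = bk[j];
        for (int i = 0; i < M; ++i) {
            double g, gs = 0.0;
            for (int j = 0; j <= S; ++j) {
                g = R::rgamma(std::max(Ik[i] * bstar[j], 1e-9), 1.0);
                p[j] = g;
                gs += g;
            }
            // multinomial draw over S+1 cells
            int left = (int)n[i];
            double psum = gs;
            for (int j = 0; j <= S; ++j) {
                if (left <= 0) { X0(i, j) = 0; continue; }
                if (j == S) { X0(i, j) = left; break; }
                const int d = (int)R::rbinom(left, std::min(1.0, p[j] / psum));
                X0(i, j) = d;
                left -= d;
                psum -= p[j];
                if (psum <= 0) psum = 1e-300;
            }
        }
        // refit the metacommunity distribution on the synthetic matrix
        refit_beta(X0, Ik, theta_draws[k], b0, refit_iters);
        NumericVector b0v(S + 1);
        for (int j = 0; j <= S; ++j) b0v[j] = b0[j];
        // likelihood over the S+1 synthetic columns: beta already spans them
        NumericVector bfull = b0v;
        {
            double ll = 0.0;
            for (int i = 0; i < M; ++i) {
                double ni = 0.0;
                for (int j = 0; j <= S; ++j) ni += X0(i, j);
                ll += R::lgammafn(Ik[i]) - R::lgammafn(Ik[i] + ni) +
                    R::lgammafn(ni + 1.0);
                for (int j = 0; j <= S; ++j) {
                    const double a = Ik[i] * bfull[j];
                    const double x = X0(i, j);
                    if (x > 0)
                        ll += R::lgammafn(a + x) - R::lgammafn(a) -
                            R::lgammafn(x + 1.0);
                }
            }
            ll_syn[k] = ll;
        }
    }
    return List::create(_["loglik_obs"] = ll_obs, _["loglik_syn"] = ll_syn);
}
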