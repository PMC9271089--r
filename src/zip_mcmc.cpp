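#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for Bayesian zero-inflated Poisson
// spatial models with BYM convolution and linear spatio-temporal trend
// random effects.
//
//   y_r ~ ZIP(omega, mu_r),  log mu_r = off_r + X_r beta + u_a + v_a + d_a t_r
//
// Sweep: (a) latent structural-zero indicators (exact Bernoulli),
// (b) omega | indicators (conjugate Beta, Uniform(0,1) prior),
// (c) beta coordinates by adaptive random-walk Metropolis (flat prior on
// the intercept, Normal(0, 1/beta_prec) otherwise),
// (d) single-site adaptive Metropolis for u (iid Normal prior) and for v
// and d (ICAR full-conditional prior: mean = neighbour average, precision
// = tau * degree), (e) conjugate Gamma updates of the precisions,
// (f) sum-to-zero recentring of v and d with the shift absorbed by the
// intercept / the trend coefficient.
//
// All randomness flows through R's RNG so set.seed() gives bitwise
// reproducible chains.

static const double ETA_MAX = 50.0;

// [[Rcpp::export]]
List zip_mcmc_cpp(IntegerVector y, NumericVector off, NumericMatrix X,
                  IntegerVector area, NumericVector tvec,
                  IntegerVector edge_from, IntegerVector edge_to,
                  List nb_list, IntegerVector deg,
                  int n_areas, int n_comp,
                  bool use_u, bool use_v, bool use_d,
                  int trend_col,
                  int iters, int burn, int thin,
                  double beta_prec, double gam_shape, double gam_rate,
                  double omega_init, bool fix_omega)
{
    const int n = y.size();
    const int p = X.ncol();
    const int n_edges = edge_from.size();

    std::vector< std::vector<int> > rows_by_area(n_areas);
    for (int i = 0; i < n; ++i) rows_by_area[area[i]].push_back(i);
    std::vector< std::vector<int> > nbs(n_areas);
    for (int a = 0; a < n_areas; ++a) {
        IntegerVector nv = nb_list[a];
        for (int k = 0; k < nv.size(); ++k) nbs[a].push_back(nv[k]);
    }

    std::vector<double> lgy(n);
    std::vector<int> zero_rows;
    double sumy = 0.0, sumE = 0.0;
    for (int i = 0; i < n; ++i) {
        lgy[i] = R::lgammafn(y[i] + 1.0);
        if (y[i] == 0) zero_rows.push_back(i);
        sumy += y[i];
        sumE += std::exp(off[i]);
    }

    // state
    std::vector<double> beta(p, 0.0);
    beta[0] = std::log((sumy + 0.5) / sumE);
    std::vector<double> u(n_areas, 0.0), v(n_areas, 0.0), d(n_areas, 0.0);
    double omega = omega_init;
    double tau_u = 1.0, tau_v = 1.0, tau_d = 1.0;
    std::vector<char> active(n, 1);   // 1 = Poisson component

    std::vector<double> eta(n), mu(n);
    for (int i = 0; i < n; ++i) {
        eta[i] = off[i] + X(i, 0) * beta[0];
        mu[i] = std::exp(eta[i]);
    }

    // adaptive proposal scales (log scale) and acceptance bookkeeping
    std::vector<double> s_beta(p, 0.1), s_u(n_areas, 0.3),
                        s_v(n_areas, 0.3), s_d(n_areas, 0.6);
    std::vector<int> acc_beta(p, 0), att_beta(p, 0);
    std::vector<int> acc_u(n_areas, 0), att_u(n_areas, 0);
    std::vector<int> acc_v(n_areas, 0), att_v(n_areas, 0);
    std::vector<int> acc_d(n_areas, 0), att_d(n_areas, 0);
    long post_acc_beta = 0, post_att_beta = 0, post_acc_site = 0,
         post_att_site = 0;

    const int n_keep = (iters - burn) / thin;
    NumericMatrix B(n_keep, p);
    NumericMatrix U(use_u ? n_keep : 1, use_u ? n_areas : 1);
    NumericMatrix V(use_v ? n_keep : 1, use_v ? n_areas : 1);
    NumericMatrix Dm(use_d ? n_keep : 1, use_d ? n_areas : 1);
    NumericVector om_draws(n_keep), tu_draws(n_keep), tv_draws(n_keep),
                  td_draws(n_keep), dev_draws(n_keep);
    int keep_i = 0;

    auto adapt = [](double &s, int &acc, int &att) {
        if (att == 0) return;
        double rate = (double) acc / att;
        if (rate > 0.45) s *= std::exp(0.25);
        else if (rate < 0.20) s *= std::exp(-0.25);
        if (s < 1e-4) s = 1e-4;
        if (s > 10.0) s = 10.0;
        acc = 0; att = 0;
    };

    for (int it = 1; it <= iters; ++it) {
        // (a) latent indicators for observed zeros
        int nz = 0;
        if (!fix_omega || omega > 0.0) {
            for (size_t k = 0; k < zero_rows.size(); ++k) {
                int i = zero_rows[k];
                double p1 = omega;
                double p0 = (1.0 - omega) * std::exp(-mu[i]);
                double pz = p1 / (p1 + p0);
                if (unif_rand() < pz) { active[i] = 0; ++nz; }
                else active[i] = 1;
            }
        }
        // (b) omega | indicators  (Uniform(0,1) prior -> Beta posterior)
        if (!fix_omega)
            omega = R::rbeta(1.0 + nz, 1.0 + n - nz);

        // (c) fixed effects, coordinate-wise adaptive RW Metropolis
        for (int j = 0; j < p; ++j) {
            double db = s_beta[j] * norm_rand();
            double lldiff = 0.0;
            bool ok = true;
            for (int i = 0; i < n; ++i) {
                double x = X(i, j);
                if (x == 0.0) continue;
                double de = x * db;
                if (eta[i] + de > ETA_MAX) { ok = false; break; }
                if (!active[i]) continue;
                lldiff += y[i] * de - mu[i] * std::expm1(de);
            }
            if (j > 0)
                lldiff -= 0.5 * beta_prec *
                    ((beta[j] + db) * (beta[j] + db) - beta[j] * beta[j]);
            ++att_beta[j]; if (it > burn) ++post_att_beta;
            if (ok && std::log(unif_rand()) < lldiff) {
                beta[j] += db;
                for (int i = 0; i < n; ++i) {
                    double x = X(i, j);
                    if (x == 0.0) continue;
                    eta[i] += x * db;
                    mu[i] = std::exp(eta[i]);
                }
                ++acc_beta[j]; if (it > burn) ++post_acc_beta;
            }
        }

        // (d) single-site random effects
        if (use_u) {
            for (int a = 0; a < n_areas; ++a) {
                double du = s_u[a] * norm_rand();
                double lldiff = -0.5 * tau_u *
                    ((u[a] + du) * (u[a] + du) - u[a] * u[a]);
                bool ok = true;
                const std::vector<int> &rr = rows_by_area[a];
                for (size_t k = 0; k < rr.size(); ++k) {
                    int i = rr[k];
                    if (eta[i] + du > ETA_MAX) { ok = false; break; }
                    if (!active[i]) continue;
                    lldiff += y[i] * du - mu[i] * std::expm1(du);
                }
                ++att_u[a]; if (it > burn) ++post_att_site;
                if (ok && std::log(unif_rand()) < lldiff) {
                    u[a] += du;
                    for (size_t k = 0; k < rr.size(); ++k) {
                        int i = rr[k];
                        eta[i] += du; mu[i] = std::exp(eta[i]);
                    }
                    ++acc_u[a]; if (it > burn) ++post_acc_site;
                }
            }
        }
        if (use_v) {
            for (int a = 0; a < n_areas; ++a) {
                if (deg[a] == 0) continue;  // island: pinned at 0
                double m = 0.0;
                for (size_t k = 0; k < nbs[a].size(); ++k) m += v[nbs[a][k]];
                m /= deg[a];
                double prec = tau_v * deg[a];
                double dv = s_v[a] * norm_rand();
                double lldiff = -0.5 * prec *
                    ((v[a] + dv - m) * (v[a] + dv - m) - (v[a] - m) * (v[a] - m));
                bool ok = true;
                const std::vector<int> &rr = rows_by_area[a];
                for (size_t k = 0; k < rr.size(); ++k) {
                    int i = rr[k];
                    if (eta[i] + dv > ETA_MAX) { ok = false; break; }
                    if (!active[i]) continue;
                    lldiff += y[i] * dv - mu[i] * std::expm1(dv);
                }
                ++att_v[a]; if (it > burn) ++post_att_site;
                if (ok && std::log(unif_rand()) < lldiff) {
                    v[a] += dv;
                    for (size_t k = 0; k < rr.size(); ++k) {
                        int i = rr[k];
                        eta[i] += dv; mu[i] = std::exp(eta[i]);
                    }
                    ++acc_v[a]; if (it > burn) ++post_acc_site;
                }
            }
            // (f) recentre; intercept absorbs the shift exactly, so eta
            // is unchanged (only when no islands are pinned elsewhere)
            bool island = false;
            for (int a = 0; a < n_areas; ++a) if (deg[a] == 0) island = true;
            if (!island) {
                double mb = 0.0;
                for (int a = 0; a < n_areas; ++a) mb += v[a];
                mb /= n_areas;
                for (int a = 0; a < n_areas; ++a) v[a] -= mb;
                beta[0] += mb;
            }
        }
        if (use_d) {
            for (int a = 0; a < n_areas; ++a) {
                if (deg[a] == 0) continue;
                double m = 0.0;
                for (size_t k = 0; k < nbs[a].size(); ++k) m += d[nbs[a][k]];
                m /= deg[a];
                double prec = tau_d * deg[a];
                double dd = s_d[a] * norm_rand();
                double lldiff = -0.5 * prec *
                    ((d[a] + dd - m) * (d[a] + dd - m) - (d[a] - m) * (d[a] - m));
                bool ok = true;
                const std::vector<int> &rr = rows_by_area[a];
                for (size_t k = 0; k < rr.size(); ++k) {
                    int i = rr[k];
                    double de = dd * tvec[i];
                    if (eta[i] + de > ETA_MAX) { ok = false; break; }
                    if (!active[i]) continue;
                    lldiff += y[i] * de - mu[i] * std::expm1(de);
                }
                ++att_d[a]; if (it > burn) ++post_att_site;
                if (ok && std::log(unif_rand()) < lldiff) {
                    d[a] += dd;
                    for (size_t k = 0; k < rr.size(); ++k) {
                        int i = rr[k];
                        eta[i] += dd * tvec[i]; mu[i] = std::exp(eta[i]);
                    }
                    ++acc_d[a]; if (it > burn) ++post_acc_site;
                }
            }
            bool island = false;
            for (int a = 0; a < n_areas; ++a) if (deg[a] == 0) island = true;
            if (!island && trend_col >= 0) {
                double mb = 0.0;
                for (int a = 0; a < n_areas; ++a) mb += d[a];
                mb /= n_areas;
                for (int a = 0; a < n_areas; ++a) d[a] -= mb;
                beta[trend_col] += mb;
            }
        }

        // (e) conjugate Gamma precision updates
        if (use_u) {
            double ss = 0.0;
            for (int a = 0; a < n_areas; ++a) ss += u[a] * u[a];
            tau_u = R::rgamma(gam_shape + 0.5 * n_areas,
                              1.0 / (gam_rate + 0.5 * ss));
        }
        if (use_v) {
            double qf = 0.0;
            for (int e = 0; e < n_edges; ++e) {
                double dd = v[edge_from[e]] - v[edge_to[e]];
                qf += dd * dd;
            }
            tau_v = R::rgamma(gam_shape + 0.5 * (n_areas - n_comp),
                              1.0 / (gam_rate + 0.5 * qf));
        }
        if (use_d) {
            double qf = 0.0;
            for (int e = 0; e < n_edges; ++e) {
                double dd = d[edge_from[e]] - d[edge_to[e]];
                qf += dd * dd;
            }
            tau_d = R::rgamma(gam_shape + 0.5 * (n_areas - n_comp),
                              1.0 / (gam_rate + 0.5 * qf));
        }

        // adaptation (burn-in only; scales frozen afterwards)
        if (it <= burn && it % 50 == 0) {
            for (int j = 0; j < p; ++j) adapt(s_beta[j], acc_beta[j], att_beta[j]);
            for (int a = 0; a < n_areas; ++a) {
                adapt(s_u[a], acc_u[a], att_u[a]);
                adapt(s_v[a], acc_v[a], att_v[a]);
                adapt(s_d[a], acc_d[a], att_d[a]);
            }
        }

        // storage
        if (it > burn && (it - burn) % thin == 0) {
            for (int j = 0; j < p; ++j) B(keep_i, j) = beta[j];
            if (use_u) for (int a = 0; a < n_areas; ++a) U(keep_i, a) = u[a];
            if (use_v) for (int a = 0; a < n_areas; ++a) V(keep_i, a) = v[a];
            if (use_d) for (int a = 0; a < n_areas; ++a) Dm(keep_i, a) = d[a];
            om_draws[keep_i] = omega;
            tu_draws[keep_i] = tau_u; tv_draws[keep_i] = tau_v;
            td_draws[keep_i] = tau_d;
            double dev = 0.0;
            double l1mo = std::log1p(-omega);
            for (int i = 0; i < n; ++i) {
                if (y[i] == 0)
                    dev += std::log(omega + std::exp(l1mo - mu[i]));
                else
                    dev += l1mo + y[i] * eta[i] - mu[i] - lgy[i];
            }
            dev_draws[keep_i] = -2.0 * dev;
            ++keep_i;
        }
    }

    double acc_rate_beta = post_att_beta > 0 ?
        (double) post_acc_beta / post_att_beta : NA_REAL;
    double acc_rate_site = post_att_site > 0 ?
        (double) post_acc_site / post_att_site : NA_REAL;

    return List::create(
        _["beta"] = B, _["u"] = U, _["v"] = V, _["delta"] = Dm,
        _["omega"] = om_draws, _["tau_u"] = tu_draws, _["tau_v"] = tv_draws,
        _["tau_delta"] = td_draws, _["deviance"] = dev_draws,
        _["acc_rate_beta"] = acc_rate_beta, _["acc_rate_site"] = acc_rate_site);
}
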