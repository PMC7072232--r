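#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Collapsed-state Gibbs sampler for a Dirichlet-process mixture of
// binomials over a fixed grid of cellular prevalences.
//
// logL: one matrix per lesion, n_mutations x n_grid, holding
//       log P(alt_i | depth_i, xi_i(phi_g)). Cluster parameters are grid
//       indices (one per lesion, independent across lesions); the base
//       measure is uniform on the grid. Concentration has a Gamma(1,1)
//       prior resampled by the Escobar-West auxiliary scheme unless fixed.
//
// Returns the average pairwise co-clustering matrix over kept samples,
// the trace of the number of occupied clusters, and the last state.

static int sample_log_weights(const std::vector<double> &logw) {
    double mx = logw[0];
    for (size_t j = 1; j < logw.size(); ++j) if (logw[j] > mx) mx = logw[j];
    double tot = 0.0;
    std::vector<double> w(logw.size());
    for (size_t j = 0; j < logw.size(); ++j) { w[j] = std::exp(logw[j] - mx); tot += w[j]; }
    double u = unif_rand() * tot, acc = 0.0;
    for (size_t j = 0; j < logw.size(); ++j) { acc += w[j]; if (u <= acc) return (int)j; }
    return (int)logw.size() - 1;
}

// [[Rcpp::export(name = ".dp_binom_gibbs")]]
List dp_binom_gibbs(List logL_list, int n_iter, int burn_in, int thin,
                    double alpha_init, bool fix_alpha) {
    int L = logL_list.size();
    std::vector<NumericMatrix> logL;
    for (int l = 0; l < L; ++l) logL.push_back(as<NumericMatrix>(logL_list[l]));
    int n = logL[0].nrow(), G = logL[0].ncol();

    // log marginal likelihood of a singleton under the uniform grid prior
    std::vector<double> log_marg(n, 0.0);
    for (int i = 0; i < n; ++i) {
        for (int l = 0; l < L; ++l) {
            double mx = logL[l](i, 0);
            for (int g = 1; g < G; ++g) if (logL[l](i, g) > mx) mx = logL[l](i, g);
            double s = 0.0;
            for (int g = 0; g < G; ++g) s += std::exp(logL[l](i, g) - mx);
            log_marg[i] += mx + std::log(s) - std::log((double)G);
        }
    }

    // state: single initial cluster
    std::vector<int> z(n, 0);
    std::vector<int> counts; counts.push_back(n);
    std::vector<std::vector<int>> grid; // grid[k][l]
    grid.push_back(std::vector<int>(L, G - 1));
    double alpha = alpha_init;

    NumericMatrix cocount(n, n);
    int n_kept = 0;
    std::vector<int> k_trace;
    std::vector<double> logw;

    auto sample_cluster_grids = [&](void) {
        int K = counts.size();
        std::vector<double> colsum(G);
        for (int k = 0; k < K; ++k) {
            for (int l = 0; l < L; ++l) {
                std::fill(colsum.begin(), colsum.end(), 0.0);
                for (int i = 0; i < n; ++i)
                    if (z[i] == k)
                        for (int g = 0; g < G; ++g) colsum[g] += logL[l](i, g);
                grid[k][l] = sample_log_weights(colsum);
            }
        }
    };
    sample_cluster_grids();

    for (int iter = 0; iter < n_iter; ++iter) {
        // reassign each mutation
        for (int i = 0; i < n; ++i) {
            int k_old = z[i];
            counts[k_old]--;
            if (counts[k_old] == 0) { // remove empty cluster (swap with last)
                int last = counts.size() - 1;
                if (k_old != last) {
                    counts[k_old] = counts[last];
                    grid[k_old] = grid[last];
                    for (int j = 0; j < n; ++j) if (z[j] == last) z[j] = k_old;
                }
                counts.pop_back(); grid.pop_back();
            }
            int K = counts.size();
            logw.assign(K + 1, 0.0);
            for (int k = 0; k < K; ++k) {
                double lp = std::log((double)counts[k]);
                for (int l = 0; l < L; ++l) lp += logL[l](i, grid[k][l]);
                logw[k] = lp;
            }
            logw[K] = std::log(alpha) + log_marg[i];
            int k_new = sample_log_weights(logw);
            if (k_new == K) { // open a new cluster, draw its grid point
                std::vector<int> gnew(L);
                std::vector<double> w(G);
                for (int l = 0; l < L; ++l) {
                    for (int g = 0; g < G; ++g) w[g] = logL[l](i, g);
                    gnew[l] = sample_log_weights(w);
                }
                counts.push_back(1); grid.push_back(gnew);
            } else {
                counts[k_new]++;
            }
            z[i] = k_new;
        }

        sample_cluster_grids();

        if (!fix_alpha) { // Escobar & West (1995), Gamma(1,1) prior
            int K = counts.size();
            double a0 = 1.0, b0 = 1.0;
            double eta = R::rbeta(alpha + 1.0, (double)n);
            double odds = (a0 + K - 1.0) / ((double)n * (b0 - std::log(eta)));
            double shape = (unif_rand() < odds / (1.0 + odds)) ? a0 + K : a0 + K - 1.0;
            alpha = R::rgamma(shape, 1.0 / (b0 - std::log(eta)));
            if (alpha < 1e-6) alpha = 1e-6;
        }

        if (iter >= burn_in && (iter - burn_in) % thin == 0) {
            n_kept++;
            k_trace.push_back((int)counts.size());
            for (int i = 0; i < n; ++i)
                for (int j = i; j < n; ++j)
                    if (z[i] == z[j]) cocount(i, j) += 1.0;
        }
    }

    NumericMatrix coprob(n, n);
    for (int i = 0; i < n; ++i)
        for (int j = i; j < n; ++j) {
            double p = (n_kept > 0) ? cocount(i, j) / n_kept : NA_REAL;
            coprob(i, j) = p; coprob(j, i) = p;
        }

    return List::create(_["cocluster"] = coprob,
                        _["k_trace"] = wrap(k_trace),
                        _["n_kept"] = n_kept,
                        _["alpha_last"] = alpha,
                        _["z_last"] = wrap(z));
}
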