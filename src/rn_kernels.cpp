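#include <Rcpp.h>
using namespace Rcpp;

// Integer power by repeated multiplication; exponents here are bounded by
// V_j (occasions per station), so this beats pow() in the hot loop.
static inline double ipow(double base, int e) {
    double out = 1.0;
    for (int k = 0; k < e; ++k) out *= base;
    return out;
}

// Per-cell marginal likelihood sum_{z=0}^{zmax} Pois(z | lam) Binom(y | v, 1-(1-r)^z),
// accumulated in natural space (every term lies in [0,1]).  The Poisson and
// geometric factors are carried forward multiplicatively so the z-loop is
// transcendental-free after the initial exp(-lam).
static double cell_marg_lik(int y, int v, double lam, double r, int zmax,
                            double choose_vy) {
    if (lam <= 0.0) return (y == 0) ? 1.0 : 0.0;
    double pois = std::exp(-lam);      // Pois(0 | lam)
    double q = 1.0 - r;                // (1-r)^z, z = 0
    double qz = 1.0;
    double acc = (y == 0) ? pois : 0.0;  // z = 0 term: p = 0
    for (int z = 1; z <= zmax; ++z) {
        pois *= lam / z;
        qz *= q;
        double p = 1.0 - qz;
        double term;
        if (y == 0) {
            term = pois * ipow(qz, v);
        } else {
            term = pois * choose_vy * ipow(p, y) * ipow(qz, v - y);
        }
        acc += term;
        // Poisson tail beyond z bounds the remaining mass once z > lam.
        if (z > lam && pois < acc * 1e-16) break;
    }
    return acc;
}

// Marginal log-likelihood per species row: sum over stations of
// log sum_z Pois(z | lambda_ij) Binom(Y_ij | V_j, 1 - (1 - r_ij)^z).
// logLam and r are S x J matrices (constant columns/rows encode the
// model variants).  Returns -Inf for rows whose truncated sum underflows;
// the Metropolis caller treats that as a rejected region.
// [[Rcpp::export]]
NumericVector rn_marg_loglik(IntegerMatrix Y, IntegerVector V,
                             NumericMatrix logLam, NumericMatrix r,
                             int zmax) {
    int S = Y.nrow(), J = Y.ncol();
    NumericVector out(S);
    for (int i = 0; i < S; ++i) {
        double ll = 0.0;
        for (int j = 0; j < J; ++j) {
            int y = Y(i, j), v = V[j];
            double lam = std::exp(logLam(i, j));
            double cvy = (y == 0) ? 1.0 : Rf_choose((double)v, (double)y);
            double lik = cell_marg_lik(y, v, lam, r(i, j), zmax, cvy);
            if (lik <= 0.0) { ll = R_NegInf; break; }
            ll += std::log(lik);
        }
        out[i] = ll;
    }
    return out;
}

// Exact draw of Z_ij from its full conditional
//   P(Z = z | ...) propto Pois(z | lambda_ij) Binom(Y_ij | V_j, 1-(1-r_ij)^z)
// over z in {0..zmax}; rows with w_i = 0 are fixed at Z = 0.
// Uses R's RNG so set.seed() governs the draws.
// [[Rcpp::export]]
IntegerMatrix rn_draw_z(IntegerMatrix Y, IntegerVector V,
                        NumericMatrix logLam, NumericMatrix r,
                        IntegerVector w, int zmax) {
    int S = Y.nrow(), J = Y.ncol();
    IntegerMatrix Z(S, J);
    std::vector<double> terms(zmax + 1);
    for (int i = 0; i < S; ++i) {
        if (w[i] == 0) { for (int j = 0; j < J; ++j) Z(i, j) = 0; continue; }
        for (int j = 0; j < J; ++j) {
            int y = Y(i, j), v = V[j];
            double lam = std::exp(logLam(i, j));
            double q = 1.0 - r(i, j);
            double cvy = (y == 0) ? 1.0 : Rf_choose((double)v, (double)y);
            double pois = std::exp(-lam);
            double qz = 1.0;
            double total = 0.0;
            int zhi = 0;
            terms[0] = (y == 0) ? pois : 0.0;
            total = terms[0];
            for (int z = 1; z <= zmax; ++z) {
                pois *= lam / z;
                qz *= q;
                double term = (y == 0)
                    ? pois * ipow(qz, v)
                    : pois * cvy * ipow(1.0 - qz, y) * ipow(qz, v - y);
                terms[z] = term;
                total += term;
                zhi = z;
                if (z > lam && pois < total * 1e-16) break;
            }
            int draw = 0;
            if (total > 0.0) {
                double u = unif_rand() * total, cum = 0.0;
                draw = zhi;  // guard against floating-point shortfall
                for (int z = 0; z <= zhi; ++z) {
                    cum += terms[z];
                    if (u <= cum) { draw = z; break; }
                }
            } else {
                // degenerate cell (all mass underflowed): fall back to the
                // likelihood-free minimum consistent with the data
                draw = (y > 0) ? 1 : 0;
            }
            Z(i, j) = draw;
        }
    }
    return Z;
}
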