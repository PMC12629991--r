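#include <Rcpp.h>
using namespace Rcpp;

static inline double clip4(double x) {
    if (x > 4.0) return 4.0;
    if (x < -4.0) return -4.0;
    return x;
}

// Stochastic-gradient layout optimizer for the fuzzy k-NN graph embedding
// (the UMAP cross-entropy objective with negative sampling).
//
// emb: n x d matrix, modified in place (initial layout, e.g. spectral).
// head/tail: 0-based endpoints of graph edges; weight: edge membership
// strengths in (0, 1]. a, b: parameters of the low-dimensional similarity
// curve 1 / (1 + a * d^(2b)). Uses R's RNG, so results are reproducible
// under set.seed().

// [[Rcpp::export(name = ".umap_layout_cpp")]]
NumericMatrix umap_layout_cpp(NumericMatrix emb, IntegerVector head,
                              IntegerVector tail, NumericVector weight,
                              double a, double b, int n_epochs,
                              double initial_alpha, double gamma,
                              int neg_sample_rate) {
    const int n = emb.nrow(), d = emb.ncol(), ne = head.size();

    double wmax = 0.0;
    for (int e = 0; e < ne; ++e) if (weight[e] > wmax) wmax = weight[e];
    std::vector<double> eps(ne), eons(ne), eonns(ne);
    for (int e = 0; e < ne; ++e) {
        eps[e] = wmax / weight[e];           // epochs per sample
        eons[e] = eps[e];                    // epoch of next (positive) sample
        eonns[e] = eps[e] / neg_sample_rate; // epoch of next negative batch
    }

    for (int epoch = 1; epoch <= n_epochs; ++epoch) {
        double alpha = initial_alpha *
            (1.0 - (double)(epoch - 1) / (double)n_epochs);
        for (int e = 0; e < ne; ++e) {
            if (eons[e] > epoch) continue;
            int j = head[e], kk = tail[e];
            // positive (attractive) update
            double d2 = 0.0;
            for (int t = 0; t < d; ++t) {
                double diff = emb(j, t) - emb(kk, t);
                d2 += diff * diff;
            }
            if (d2 > 0.0) {
                double gc = (-2.0 * a * b * std::pow(d2, b - 1.0)) /
                            (a * std::pow(d2, b) + 1.0);
                for (int t = 0; t < d; ++t) {
                    double g = clip4(gc * (emb(j, t) - emb(kk, t)));
                    emb(j, t) += alpha * g;
                    emb(kk, t) -= alpha * g;
                }
            }
            eons[e] += eps[e];

            if (neg_sample_rate < 1) continue;  // attraction-only phase
            // negative (repulsive) updates
            int n_neg = (int)((epoch - eonns[e]) * neg_sample_rate / eps[e]);
            if (n_neg < 1) n_neg = 1;
            for (int s = 0; s < n_neg; ++s) {
                int r = (int)(unif_rand() * n);
                if (r >= n) r = n - 1;
                if (r == j) continue;
                double d2n = 0.0;
                for (int t = 0; t < d; ++t) {
                    double diff = emb(j, t) - emb(r, t);
                    d2n += diff * diff;
                }
                double gc;
                if (d2n > 0.0)
                    gc = (2.0 * gamma * b) /
                         ((0.001 + d2n) * (a * std::pow(d2n, b) + 1.0));
                else
                    gc = 0.0;
                for (int t = 0; t < d; ++t) {
                    double g = d2n > 0.0
                        ? clip4(gc * (emb(j, t) - emb(r, t)))
                        : 4.0;
                    emb(j, t) += alpha * g;
                }
            }
            eonns[e] += n_neg * eps[e] / neg_sample_rate;
        }
    }
    return emb;
}
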