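#include <Rcpp.h>
using namespace Rcpp;

// Optimized GeRM scorer.
//
// enc: integer-encoded sequence, A=0 C=1 G=2 T=3, N (or any ambiguity) = 4.
// Scores are indexed by k-mer start (length L - k + 1). For the k-mer
// starting at p, the score sums exp(-lambda * Hamming(A0, Ai)) * weight(i)
// over neighbour offsets i with k <= |i| <= w; neighbours that fall outside
// the sequence, and k-mers containing N, contribute nothing. A central k-mer
// containing N scores 0.
//
// weight_scheme 0: (w - |i|) / w   (symmetric; decays 1 -> 0 with distance)
// weight_scheme 1: |w - i| / w     (literal asymmetric form, for comparison)

// [[Rcpp::export(name = ".germ_score_cpp")]]
NumericVector germ_score_cpp(IntegerVector enc, int k, int w, double lambda,
                             int weight_scheme) {
    const int L = enc.size();
    const int np = L - k + 1;
    if (np < 1) return NumericVector(0);

    NumericVector out(np);

    // k-mer validity (no N) via rolling count of ambiguous bases
    std::vector<char> valid(np);
    {
        int bad = 0;
        for (int j = 0; j < k; ++j) if (enc[j] > 3) ++bad;
        valid[0] = bad == 0;
        for (int p = 1; p < np; ++p) {
            if (enc[p - 1] > 3) --bad;
            if (enc[p + k - 1] > 3) ++bad;
            valid[p] = bad == 0;
        }
    }

    std::vector<double> simtab(k + 1);
    for (int d = 0; d <= k; ++d) simtab[d] = std::exp(-lambda * d);

    for (int p = 0; p < np; ++p) {
        if (!valid[p]) { out[p] = 0.0; continue; }
        double g = 0.0;
        for (int side = 0; side < 2; ++side) {
            for (int a = k; a <= w; ++a) {
                int i = side == 0 ? -a : a;
                int q = p + i;
                if (q < 0 || q >= np) continue;
                if (!valid[q]) continue;
                int d = 0;
                for (int j = 0; j < k; ++j)
                    if (enc[p + j] != enc[q + j]) ++d;
                double wt = weight_scheme == 0
                    ? (double)(w - a) / (double)w
                    : std::abs((double)(w - i)) / (double)w;
                g += simtab[d] * wt;
            }
        }
        out[p] = g;
    }
    return out;
}
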