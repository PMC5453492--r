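#include <Rcpp.h>
#include <string>

using namespace Rcpp;

namespace {
char comp(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
    }
}
} // namespace

// Self-comparison dot plot: point (i, j) iff the windows starting at i and j
// match at >= min_identity on either strand. Symmetric by construction.
// [[Rcpp::export]]
LogicalMatrix dotplot_cpp(std::string seq, int window, double min_identity) {
    const int n = (int)seq.size() - window + 1;
    LogicalMatrix out(n, n);
    const int need = (int)std::ceil(min_identity * window);
    for (int i = 0; i < n; ++i) {
        out(i, i) = true;
        for (int j = i + 1; j < n; ++j) {
            int mf = 0, mr = 0;
            for (int t = 0; t < window; ++t) {
                if (seq[i + t] == seq[j + t]) ++mf;
                if (seq[i + t] == comp(seq[j + window - 1 - t])) ++mr;
            }
            if (mf >= need || mr >= need) {
                out(i, j) = true;
                out(j, i) = true;
            }
        }
    }
    return out;
}
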