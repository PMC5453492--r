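#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>

using namespace Rcpp;

// Wraparound dynamic programming: global-in-sequence alignment of seq
// against an unbounded cyclic concatenation of monomer, free start and end
// phase. D[i][j] = best score of seq[1..i] ending at monomer column j.
//
//   D[i][j] = max( D[i-1][j-1*] + s(a_i, m_j),   (* cyclic)
//                  D[i-1][j]    + indel,          (seq base vs gap)
//                  D[i][j-1*]   + indel )         (monomer base deleted)
//
// The cyclic within-row dependency is resolved by two sweeps per row: a
// full-turn deletion costs p*indel < 0 and is never optimal, so left-chains
// never wrap more than once and two sweeps reach the fixpoint.

namespace {

const int NEG = INT_MIN / 4;

inline int subst(char a, char b, int match, int mismatch) {
    return a == b ? match : mismatch;
}

void wdp_fill(const std::string& seq, const std::string& mon,
              int match, int mismatch, int indel,
              std::vector<std::vector<int>>& D) {
    const int n = (int)seq.size(), p = (int)mon.size();
    D.assign(n + 1, std::vector<int>(p, 0));
    for (int i = 1; i <= n; ++i) {
        std::vector<int>& cur = D[i];
        const std::vector<int>& prev = D[i - 1];
        for (int j = 0; j < p; ++j) {
            int jm1 = (j == 0) ? p - 1 : j - 1;
            int best = prev[jm1] + subst(seq[i - 1], mon[j], match, mismatch);
            int up = prev[j] + indel;
            if (up > best) best = up;
            cur[j] = best;
        }
        for (int sweep = 0; sweep < 2; ++sweep) {
            for (int j = 0; j < p; ++j) {
                int jm1 = (j == 0) ? p - 1 : j - 1;
                int left = cur[jm1] + indel;
                if (left > cur[j]) cur[j] = left;
            }
        }
    }
}

} // namespace

// [[Rcpp::export]]
int wraparound_score_cpp(std::string seq, std::string monomer,
                         int match, int mismatch, int indel) {
    std::vector<std::vector<int>> D;
    wdp_fill(seq, monomer, match, mismatch, indel, D);
    const int n = (int)seq.size(), p = (int)monomer.size();
    int best = NEG;
    for (int j = 0; j < p; ++j) best = std::max(best, D[n][j]);
    return best;
}

// Score plus per-base monomer column assignment (1-based; 0 = insertion).
// [[Rcpp::export]]
List wraparound_align_cpp(std::string seq, std::string monomer,
                          int match, int mismatch, int indel) {
    std::vector<std::vector<int>> D;
    wdp_fill(seq, monomer, match, mismatch, indel, D);
    const int n = (int)seq.size(), p = (int)monomer.size();
    int best = NEG, bj = 0;
    for (int j = 0; j < p; ++j)
        if (D[n][j] > best) { best = D[n][j]; bj = j; }

    IntegerVector cols(n, 0);
    int i = n, j = bj;
    while (i > 0) {
        int jm1 = (j == 0) ? p - 1 : j - 1;
        int v = D[i][j];
        if (v == D[i - 1][jm1] + subst(seq[i - 1], monomer[j], match, mismatch)) {
            cols[i - 1] = j + 1;
            --i;
            j = jm1;
        } else if (v == D[i - 1][j] + indel) {
            cols[i - 1] = 0; // seq base opposite a gap
            --i;
        } else {
            // monomer deletion: move left within the row (value strictly grows,
            // so this cannot loop)
            j = jm1;
        }
    }
    return List::create(_["score"] = best, _["columns"] = cols);
}
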