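#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include "kmer_utils.h"

using namespace Rcpp;

namespace {

std::string revcomp_str(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (char& c : r) {
        switch (c) {
        case 'A': c = 'T'; break;
        case 'C': c = 'G'; break;
        case 'G': c = 'C'; break;
        case 'T': c = 'A'; break;
        default: c = 'N';
        }
    }
    return r;
}

// maximal ungapped segment score through an exact word seed
int extend_seed(const std::string& q, const std::string& s,
                int qpos, int spos, int w, int match, int mismatch) {
    int score = w * match;
    // right
    int run = 0, best_r = 0;
    int i = qpos + w, j = spos + w;
    while (i < (int)q.size() && j < (int)s.size()) {
        run += (q[i] == s[j]) ? match : mismatch;
        if (run > best_r) best_r = run;
        if (run < best_r - 20 * match) break; // X-drop
        ++i; ++j;
    }
    // left
    run = 0;
    int best_l = 0;
    i = qpos - 1; j = spos - 1;
    while (i >= 0 && j >= 0) {
        run += (q[i] == s[j]) ? match : mismatch;
        if (run > best_l) best_l = run;
        if (run < best_l - 20 * match) break;
        --i; --j;
    }
    return score + best_r + best_l;
}

} // namespace

// Best seeded ungapped local alignment score of `query` against each subject
// (either strand), requiring an exact shared word of length word_size.
// Subjects with no shared word score 0.
// [[Rcpp::export]]
IntegerVector seeded_ungapped_best_cpp(std::string query,
                                       CharacterVector subjects,
                                       int word_size, int match,
                                       int mismatch) {
    // index query words, both strands
    std::string qf = query, qr = revcomp_str(query);
    std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> qindex;
    std::vector<uint64_t> codes;
    std::vector<int> pos;
    for (int strand = 0; strand < 2; ++strand) {
        const std::string& q = strand == 0 ? qf : qr;
        enumerate_kmers(q, word_size, codes, pos);
        for (size_t t = 0; t < codes.size(); ++t)
            qindex[codes[t]].push_back({strand, pos[t]});
    }

    IntegerVector out(subjects.size(), 0);
    for (int si = 0; si < subjects.size(); ++si) {
        std::string s = as<std::string>(subjects[si]);
        enumerate_kmers(s, word_size, codes, pos);
        int best = 0;
        // avoid re-extending the same (strand, diagonal)
        std::unordered_map<int64_t, char> seen;
        for (size_t t = 0; t < codes.size(); ++t) {
            auto it = qindex.find(codes[t]);
            if (it == qindex.end()) continue;
            for (auto& qh : it->second) {
                const std::string& q = qh.first == 0 ? qf : qr;
                int64_t key = (int64_t)qh.first * 20000000
                              + (pos[t] - qh.second) + 10000000;
                if (seen.count(key)) continue;
                seen[key] = 1;
                int sc = extend_seed(q, s, qh.second, pos[t], word_size,
                                     match, mismatch);
                if (sc > best) best = sc;
            }
        }
        out[si] = best;
    }
    return out;
}
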