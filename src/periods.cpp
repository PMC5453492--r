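#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include "kmer_utils.h"

using namespace Rcpp;

// support[d] = number of positions i with seq[i..i+k) == seq[i+d..i+d+k)
// for 1 <= d <= max_period. Hash-based: only genuine k-mer recurrences are
// visited, so cost is near-linear for non-repetitive sequence.
// [[Rcpp::export]]
IntegerVector period_support_cpp(std::string seq, int k, int max_period) {
    std::vector<uint64_t> codes;
    std::vector<int> pos;
    enumerate_kmers(seq, k, codes, pos);
    IntegerVector support(max_period, 0);
    std::unordered_map<uint64_t, std::vector<int>> occ;
    occ.reserve(codes.size());
    for (size_t t = 0; t < codes.size(); ++t)
        occ[codes[t]].push_back(pos[t]);
    for (auto& kv : occ) {
        const std::vector<int>& v = kv.second;
        size_t lo = 0;
        for (size_t hi = 1; hi < v.size(); ++hi) {
            while (v[hi] - v[lo] > max_period) ++lo;
            for (size_t t = lo; t < hi; ++t) {
                int d = v[hi] - v[t];
                if (d >= 1) ++support[d - 1];
            }
        }
    }
    return support;
}

// 0-based start positions i with an exact k-mer match at distance d.
// [[Rcpp::export]]
IntegerVector period_positions_cpp(std::string seq, int k, int d) {
    std::vector<uint64_t> codes;
    std::vector<int> pos;
    enumerate_kmers(seq, k, codes, pos);
    // index codes by position for O(1) lookup at i and i+d
    std::unordered_map<int, uint64_t> at;
    at.reserve(codes.size());
    for (size_t t = 0; t < codes.size(); ++t) at[pos[t]] = codes[t];
    std::vector<int> out;
    for (size_t t = 0; t < codes.size(); ++t) {
        auto it = at.find(pos[t] + d);
        if (it != at.end() && it->second == codes[t]) out.push_back(pos[t]);
    }
    return wrap(out);
}
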