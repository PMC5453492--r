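#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
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

// Maximal-scoring ungapped segment on a fixed diagonal (Kadane over
// match/mismatch scores). Returns matches and length of the best segment.
// ext_mismatch is the extension drop penalty: it keeps a segment from
// bridging into unrelated sequence while tolerating scattered errors.
void best_segment(const std::string& q, const std::string& s, int diag,
                  int ext_mismatch, int& best_matches, int& best_len) {
    // diag = spos - qpos; overlap in query coordinates
    int q0 = std::max(0, -diag);
    int q1 = std::min((int)q.size(), (int)s.size() - diag);
    best_matches = 0;
    best_len = 0;
    if (q1 <= q0) return;
    int score = 0, matches = 0, len = 0, best_score = -1;
    for (int i = q0; i < q1; ++i) {
        bool m = q[i] == s[i + diag];
        int inc = m ? 1 : -ext_mismatch;
        if (score + inc < 0) {
            score = 0; matches = 0; len = 0;
            if (m) { score = 1; matches = 1; len = 1; }
            continue;
        }
        score += inc;
        matches += m ? 1 : 0;
        len += 1;
        if (score > best_score) {
            best_score = score;
            best_matches = matches;
            best_len = len;
        }
    }
}

} // namespace

// Seed-and-extend read recruitment. A read hits a contig iff a shared
// seed_k-mer (either strand) lies on a diagonal whose maximal ungapped
// segment covers >= min_cov of the read at identity >= min_identity.
// Returns one row per (read, contig) hit with the best segment identity.
// [[Rcpp::export]]
DataFrame recruit_cpp(CharacterVector reads, CharacterVector contigs,
                      int seed_k, double min_identity, double min_cov) {
    const int nc = contigs.size();
    std::vector<std::string> cs(nc);
    for (int i = 0; i < nc; ++i) cs[i] = as<std::string>(contigs[i]);

    // index forward k-mers of contigs
    std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
    std::vector<uint64_t> codes;
    std::vector<int> pos;
    for (int ci = 0; ci < nc; ++ci) {
        enumerate_kmers(cs[ci], seed_k, codes, pos);
        for (size_t t = 0; t < codes.size(); ++t)
            index[codes[t]].push_back({ci, pos[t]});
    }

    std::vector<int> out_read, out_contig;
    std::vector<double> out_identity;

    const int ext_mismatch = 3;
    for (int ri = 0; ri < reads.size(); ++ri) {
        std::string fwd = as<std::string>(reads[ri]);
        std::string rev = revcomp_str(fwd);
        int rl = (int)fwd.size();
        if (rl < seed_k) continue;
        // candidate (contig, strand, diagonal) triples
        std::unordered_set<int64_t> cand;
        std::unordered_map<int, std::pair<int, int>> best; // contig -> (matches, len)
        for (int strand = 0; strand < 2; ++strand) {
            const std::string& q = strand == 0 ? fwd : rev;
            enumerate_kmers(q, seed_k, codes, pos);
            for (size_t t = 0; t < codes.size(); ++t) {
                auto it = index.find(codes[t]);
                if (it == index.end()) continue;
                for (auto& hit : it->second) {
                    int diag = hit.second - pos[t];
                    int64_t key = ((int64_t)hit.first * 2 + strand) * 1000000
                                  + (diag + 500000);
                    if (!cand.insert(key).second) continue;
                    int m, len;
                    best_segment(q, cs[hit.first], diag, ext_mismatch, m, len);
                    auto& b = best[hit.first];
                    if (m > b.first) b = {m, len};
                }
            }
        }
        std::vector<std::pair<int, std::pair<int, int>>> hits(best.begin(),
                                                              best.end());
        std::sort(hits.begin(), hits.end());
        for (auto& kv : hits) {
            int m = kv.second.first, len = kv.second.second;
            if (len == 0) continue;
            double cov = (double)len / rl;
            double ident = (double)m / len;
            if (cov >= min_cov && ident >= min_identity) {
                out_read.push_back(ri + 1);
                out_contig.push_back(kv.first + 1);
                out_identity.push_back(ident);
            }
        }
    }
    return DataFrame::create(_["read"] = out_read, _["contig"] = out_contig,
                             _["identity"] = out_identity,
                             _["stringsAsFactors"] = false);
}
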