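#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include "kmer_utils.h"
#include "flat_table.h"

using namespace Rcpp;

namespace {

const uint8_t RETAINED = 2, WALKED = 4, IN_CYCLE = 8, VISITED = 16;

void count_kmers_flat(const std::vector<std::string>& seqs, int k,
                      FlatTable& tab) {
    std::vector<uint64_t> codes;
    for (const auto& s : seqs) {
        enumerate_canonical(s, k, codes);
        for (uint64_t c : codes) tab.increment(c);
    }
}

// Oriented k-mer: forward code plus its reverse complement, updated in O(1)
// per extension so graph walks never loop over k.
struct OKmer {
    uint64_t f, r;
    uint64_t canon() const { return f < r ? f : r; }
};

struct Graph {
    int k;
    uint64_t mask;
    int shift; // 2*(k-1)
    FlatTable* tab;
    bool skip_cycle = false;

    // slot of a live node, SIZE_MAX otherwise
    size_t get(uint64_t canon) const {
        size_t i = tab->find(canon);
        if (i == SIZE_MAX || !(tab->flags[i] & RETAINED)) return SIZE_MAX;
        if (skip_cycle && (tab->flags[i] & IN_CYCLE)) return SIZE_MAX;
        return i;
    }
    OKmer step(const OKmer& x, uint64_t b) const {
        return {((x.f << 2) | b) & mask,
                (x.r >> 2) | ((3ULL - b) << shift)};
    }
    static OKmer flip(const OKmer& x) { return {x.r, x.f}; }
    int successors(const OKmer& x, OKmer out[4], size_t slot[4]) const {
        int n = 0;
        for (uint64_t b = 0; b < 4; ++b) {
            OKmer y = step(x, b);
            size_t s = get(y.canon());
            if (s != SIZE_MAX) {
                out[n] = y;
                slot[n] = s;
                ++n;
            }
        }
        return n;
    }
    int n_predecessors(const OKmer& x) const {
        OKmer rx = flip(x);
        int n = 0;
        for (uint64_t b = 0; b < 4; ++b)
            if (get(step(rx, b).canon()) != SIZE_MAX) ++n;
        return n;
    }
};

OKmer make_okmer(uint64_t fwd, int k) { return {fwd, revcomp_code(fwd, k)}; }

std::string path_to_seq(const std::vector<OKmer>& path, int k) {
    std::string s = decode_kmer(path[0].f, k);
    for (size_t i = 1; i < path.size(); ++i)
        s.push_back(BITS2BASE[path[i].f & 3ULL]);
    return s;
}

} // namespace

// [[Rcpp::export]]
DataFrame kmer_count_table_cpp(CharacterVector seqs, int k) {
    std::vector<std::string> v(seqs.size());
    for (int i = 0; i < seqs.size(); ++i) v[i] = as<std::string>(seqs[i]);
    FlatTable tab;
    tab.init(1 << 12);
    count_kmers_flat(v, k, tab);
    std::vector<uint64_t> keys;
    keys.reserve(tab.n);
    for (size_t i = 0; i <= tab.mask; ++i)
        if (tab.flags[i] & 1) keys.push_back(tab.keys[i]);
    std::sort(keys.begin(), keys.end());
    CharacterVector kmer(keys.size());
    IntegerVector count(keys.size());
    for (size_t i = 0; i < keys.size(); ++i) {
        kmer[i] = decode_kmer(keys[i], k);
        count[i] = tab.vals[tab.find(keys[i])];
    }
    return DataFrame::create(_["kmer"] = kmer, _["count"] = count,
                             _["stringsAsFactors"] = false);
}

// Mean multiplicity of canonical k-mers (for the noise threshold) without
// materialising the k-mer strings.
// [[Rcpp::export]]
List kmer_count_summary_cpp(CharacterVector seqs, int k) {
    std::vector<std::string> v(seqs.size());
    size_t total_bases = 0;
    for (int i = 0; i < seqs.size(); ++i) {
        v[i] = as<std::string>(seqs[i]);
        total_bases += v[i].size();
    }
    FlatTable tab;
    tab.init(total_bases / 2 + 1024);
    count_kmers_flat(v, k, tab);
    double total = 0;
    for (size_t i = 0; i <= tab.mask; ++i)
        if (tab.flags[i] & 1) total += tab.vals[i];
    return List::create(_["distinct"] = (double)tab.n,
                        _["total"] = total,
                        _["mean"] = tab.n ? total / tab.n : 0.0);
}

// De Bruijn assembly with cycle recovery for tandem arrays.
//
// Phase 1 removes k-mers below min_count. Phase 2 walks from high-count
// k-mers along the highest-count successor and extracts directed cycles
// (collapsed tandem arrays), each emitted unrolled to 3 monomer periods.
// Phase 3 extracts conservative maximal non-branching paths (unitigs) from
// the remaining k-mers. Contigs shorter than min_contig_length are dropped.
// n_reads of a contig = number of reads sharing >= 1 k-mer with it.
// [[Rcpp::export]]
List assemble_cpp(CharacterVector reads, int k, int min_count,
                  int min_contig_length, int max_period) {
    std::vector<std::string> rv(reads.size());
    size_t total_bases = 0;
    for (int i = 0; i < reads.size(); ++i) {
        rv[i] = as<std::string>(reads[i]);
        total_bases += rv[i].size();
    }

    FlatTable tab;
    tab.init(total_bases / 2 + 1024);
    count_kmers_flat(rv, k, tab);

    size_t n_retained = 0;
    for (size_t i = 0; i <= tab.mask; ++i) {
        if ((tab.flags[i] & 1) && tab.vals[i] >= min_count) {
            tab.flags[i] |= RETAINED;
            ++n_retained;
        }
    }

    Graph g{k, (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1), 2 * (k - 1),
            &tab};

    // deterministic start order: count desc, code asc
    std::vector<std::pair<int64_t, uint64_t>> by_count;
    by_count.reserve(n_retained);
    for (size_t i = 0; i <= tab.mask; ++i)
        if (tab.flags[i] & RETAINED)
            by_count.push_back({-(int64_t)tab.vals[i], tab.keys[i]});
    std::sort(by_count.begin(), by_count.end());

    std::vector<std::string> contig_seq;
    std::vector<int> contig_period;
    std::vector<bool> contig_cycle;

    // ---- Phase 2: cycle recovery (max-count successor walks) ----
    const size_t max_steps = 2 * (size_t)(max_period + k);
    OKmer succ[4];
    size_t sslot[4];

    for (auto& pr : by_count) {
        uint64_t start = pr.second;
        size_t st = tab.find(start);
        if (tab.flags[st] & WALKED) continue;
        tab.flags[st] |= WALKED;
        std::vector<OKmer> path;
        std::unordered_map<uint64_t, int> seen; // canonical -> index in path
        OKmer cur = make_okmer(start, k);
        path.push_back(cur);
        seen[start] = 0;
        while (path.size() < max_steps) {
            int ns = g.successors(cur, succ, sslot);
            if (ns == 0) break;
            // highest-count successor; ties -> smallest oriented code
            int bi = 0;
            for (int i = 1; i < ns; ++i) {
                if (tab.vals[sslot[i]] > tab.vals[sslot[bi]] ||
                    (tab.vals[sslot[i]] == tab.vals[sslot[bi]] &&
                     succ[i].f < succ[bi].f))
                    bi = i;
            }
            OKmer best = succ[bi];
            uint64_t can = best.canon();
            auto hit = seen.find(can);
            if (hit != seen.end()) {
                // revisited our own path: directed cycle if same orientation
                int at = hit->second;
                if (path[at].f == best.f) {
                    std::vector<OKmer> cyc(path.begin() + at, path.end());
                    // one base per cycle k-mer (last base); any rotation of
                    // the resulting cyclic string is a valid monomer phase
                    size_t P = cyc.size();
                    std::string s(P, 'A');
                    for (size_t i = 0; i < P; ++i)
                        s[i] = BITS2BASE[cyc[i].f & 3ULL];
                    std::string unrolled = s + s + s;
                    for (auto& q : cyc)
                        tab.flags[tab.find(q.canon())] |= IN_CYCLE;
                    contig_seq.push_back(unrolled);
                    contig_period.push_back((int)P);
                    contig_cycle.push_back(true);
                }
                break;
            }
            if (tab.flags[sslot[bi]] & WALKED) break; // explored territory
            tab.flags[sslot[bi]] |= WALKED;
            seen[can] = (int)path.size();
            path.push_back(best);
            cur = best;
        }
    }

    // ---- Phase 3: conservative unitigs on the non-cycle subgraph ----
    Graph gl = g;
    gl.skip_cycle = true;

    auto walk_dir = [&](OKmer from, std::vector<OKmer>& out) {
        // extend right while the edge is the unique out-edge of cur and the
        // unique in-edge of next (conservative truncation at any branch)
        OKmer cur = from;
        while (true) {
            int ns = gl.successors(cur, succ, sslot);
            if (ns != 1) break;
            OKmer nxt = succ[0];
            if (gl.n_predecessors(nxt) != 1) break;
            if (tab.flags[sslot[0]] & VISITED) break; // loops back
            tab.flags[sslot[0]] |= VISITED;
            out.push_back(nxt);
            cur = nxt;
        }
    };

    for (auto& pr : by_count) {
        uint64_t start = pr.second;
        size_t st = tab.find(start);
        if (tab.flags[st] & (VISITED | IN_CYCLE)) continue;
        tab.flags[st] |= VISITED;
        OKmer s0 = make_okmer(start, k);
        std::vector<OKmer> right, left;
        walk_dir(s0, right);
        walk_dir(Graph::flip(s0), left);
        std::vector<OKmer> path;
        path.reserve(left.size() + 1 + right.size());
        for (auto it = left.rbegin(); it != left.rend(); ++it)
            path.push_back(Graph::flip(*it));
        path.push_back(s0);
        for (auto& x : right) path.push_back(x);
        contig_seq.push_back(path_to_seq(path, k));
        contig_period.push_back(NA_INTEGER);
        contig_cycle.push_back(false);
    }

    // ---- length filter ----
    std::vector<int> keep;
    for (size_t i = 0; i < contig_seq.size(); ++i)
        if ((int)contig_seq[i].size() >= min_contig_length)
            keep.push_back((int)i);

    // ---- per-contig read support ----
    FlatTable kmer2contig;
    size_t contig_bases = 0;
    for (size_t ci = 0; ci < keep.size(); ++ci)
        contig_bases += contig_seq[keep[ci]].size();
    kmer2contig.init(contig_bases + 1024);
    std::vector<uint64_t> codes;
    for (size_t ci = 0; ci < keep.size(); ++ci) {
        enumerate_canonical(contig_seq[keep[ci]], k, codes);
        for (uint64_t c : codes) kmer2contig.put(c, (int32_t)ci);
    }
    std::vector<int> n_reads(keep.size(), 0);
    std::unordered_set<int> hit;
    for (const auto& r : rv) {
        enumerate_canonical(r, k, codes);
        hit.clear();
        for (uint64_t c : codes) {
            size_t s = kmer2contig.find(c);
            if (s != SIZE_MAX) hit.insert(kmer2contig.vals[s]);
        }
        for (int ci : hit) ++n_reads[ci];
    }

    CharacterVector seq_out(keep.size());
    IntegerVector period_out(keep.size()), reads_out(keep.size());
    LogicalVector cycle_out(keep.size());
    for (size_t i = 0; i < keep.size(); ++i) {
        seq_out[i] = contig_seq[keep[i]];
        period_out[i] = contig_period[keep[i]];
        cycle_out[i] = (bool)contig_cycle[keep[i]];
        reads_out[i] = n_reads[i];
    }
    return List::create(_["seq"] = seq_out, _["n_reads"] = reads_out,
                        _["is_cycle"] = cycle_out, _["period"] = period_out,
                        _["n_kmers_retained"] = (double)n_retained);
}
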