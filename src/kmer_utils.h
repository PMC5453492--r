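#ifndef SATSEEKER_KMER_UTILS_H
#define SATSEEKER_KMER_UTILS_H

#include <cstdint>
#include <string>
#include <vector>

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else (N, ...) = -1.
static inline int base2bits(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_code(uint64_t x, int k) {
    uint64_t r = 0;
    for (int i = 0; i < k; ++i) {
        r = (r << 2) | (3ULL - (x & 3ULL));
        x >>= 2;
    }
    return r;
}

static inline uint64_t canonical_code(uint64_t x, int k) {
    uint64_t r = revcomp_code(x, k);
    return x < r ? x : r;
}

static inline std::string decode_kmer(uint64_t x, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = BITS2BASE[x & 3ULL];
        x >>= 2;
    }
    return s;
}

// Enumerate valid k-mer codes of a sequence; pos[i] is the 0-based start of
// codes[i]. Windows containing non-ACGT bases are skipped.
static inline void enumerate_kmers(const std::string& seq, int k,
                                   std::vector<uint64_t>& codes,
                                   std::vector<int>& pos) {
    codes.clear();
    pos.clear();
    const int n = (int)seq.size();
    if (n < k) return;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t cur = 0;
    int filled = 0;
    for (int i = 0; i < n; ++i) {
        int b = base2bits(seq[i]);
        if (b < 0) {
            filled = 0;
            cur = 0;
            continue;
        }
        cur = ((cur << 2) | (uint64_t)b) & mask;
        if (++filled >= k) {
            codes.push_back(cur);
            pos.push_back(i - k + 1);
        }
    }
}

// Rolling enumeration of canonical k-mer codes (min of forward and
// reverse-complement code at each window).
static inline void enumerate_canonical(const std::string& seq, int k,
                                       std::vector<uint64_t>& codes) {
    codes.clear();
    const int n = (int)seq.size();
    if (n < k) return;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int shift = 2 * (k - 1);
    uint64_t fwd = 0, rev = 0;
    int filled = 0;
    for (int i = 0; i < n; ++i) {
        int b = base2bits(seq[i]);
        if (b < 0) {
            filled = 0;
            fwd = rev = 0;
            continue;
        }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
        if (++filled >= k) codes.push_back(fwd < rev ? fwd : rev);
    }
}

#endif
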