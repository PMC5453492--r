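#ifndef SATSEEKER_FLAT_TABLE_H
#define SATSEEKER_FLAT_TABLE_H

#include <cstdint>
#include <vector>

// Minimal open-addressing (linear probing) hash table from 64-bit k-mer
// codes to a count plus flag byte. Far faster than std::unordered_map for
// the assembler's access pattern (tens of millions of point lookups).
struct FlatTable {
    std::vector<uint64_t> keys;
    std::vector<int32_t> vals;
    std::vector<uint8_t> flags; // bit 0: occupied; bits 1..7: user flags
    size_t mask = 0;
    size_t n = 0;

    static size_t hash64(uint64_t x) {
        x *= 0x9E3779B97F4A7C15ULL;
        x ^= x >> 29;
        return (size_t)x;
    }

    void init(size_t expected) {
        size_t cap = 64;
        while (cap < expected * 2) cap <<= 1;
        keys.assign(cap, 0);
        vals.assign(cap, 0);
        flags.assign(cap, 0);
        mask = cap - 1;
        n = 0;
    }

    void grow() {
        FlatTable bigger;
        bigger.init((mask + 1));
        for (size_t i = 0; i <= mask; ++i) {
            if (flags[i] & 1) {
                size_t j = bigger.slot_for_insert(keys[i]);
                bigger.keys[j] = keys[i];
                bigger.vals[j] = vals[i];
                bigger.flags[j] = flags[i];
                ++bigger.n;
            }
        }
        keys.swap(bigger.keys);
        vals.swap(bigger.vals);
        flags.swap(bigger.flags);
        mask = bigger.mask;
        n = bigger.n;
    }

    size_t slot_for_insert(uint64_t key) const {
        size_t i = hash64(key) & mask;
        while ((flags[i] & 1) && keys[i] != key) i = (i + 1) & mask;
        return i;
    }

    // returns slot index, SIZE_MAX if absent
    size_t find(uint64_t key) const {
        size_t i = hash64(key) & mask;
        while (flags[i] & 1) {
            if (keys[i] == key) return i;
            i = (i + 1) & mask;
        }
        return SIZE_MAX;
    }

    void increment(uint64_t key) {
        if (n * 10 > (mask + 1) * 6) grow();
        size_t i = slot_for_insert(key);
        if (!(flags[i] & 1)) {
            keys[i] = key;
            vals[i] = 0;
            flags[i] = 1;
            ++n;
        }
        ++vals[i];
    }

    // insert if absent with value v (no growth check: size beforehand)
    size_t put(uint64_t key, int32_t v) {
        if (n * 10 > (mask + 1) * 6) grow();
        size_t i = slot_for_insert(key);
        if (!(flags[i] & 1)) {
            keys[i] = key;
            vals[i] = v;
            flags[i] = 1;
            ++n;
        }
        return i;
    }
};

#endif
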