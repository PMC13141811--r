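#include <Rcpp.h>
#include <cstdint>

// splitmix64: the k-th output for a given seed is a pure function of
// (seed, k), so priorities can be drawn (or re-drawn) for any contiguous
// range of the stream without carrying generator state across calls.
static inline uint64_t splitmix64_at(uint64_t seed, uint64_t k) {
    uint64_t z = seed + k * 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

// Draws `n` values of the priority stream for `seed`, starting at 1-based
// position `from`. Each value is the high 53 bits of a splitmix64 output,
// returned as an exactly-representable double in [0, 2^53).
// [[Rcpp::export(name = ".priority_draws")]]
Rcpp::NumericVector priority_draws_cpp(double seed, double from, double n) {
    if (n < 0 || from < 1)
        Rcpp::stop("invalid draw range");
    uint64_t s = static_cast<uint64_t>(seed);
    uint64_t k0 = static_cast<uint64_t>(from);
    R_xlen_t len = static_cast<R_xlen_t>(n);
    Rcpp::NumericVector out(len);
    for (R_xlen_t i = 0; i < len; ++i) {
        uint64_t v = splitmix64_at(s, k0 + static_cast<uint64_t>(i));
        out[i] = static_cast<double>(v >> 11);
    }
    return out;
}
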