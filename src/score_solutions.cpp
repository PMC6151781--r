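#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Bit-packed filter scoring. Each (descriptor, range) candidate value has a
// 0/1 pass column over the molecules of one class; columns are packed into
// 64-bit words so that a k-condition filter is scored by word-wise AND and
// popcount. Packing happens once per optimizer run.

// [[Rcpp::export(name = ".packPassBits")]]
RawVector packPassBits(IntegerMatrix pass01) {
    const int n = pass01.nrow(), V = pass01.ncol();
    const int nWords = (n + 63) / 64;
    RawVector out(static_cast<R_xlen_t>(nWords) * 8 * V);
    std::vector<uint64_t> col(nWords);
    for (int v = 0; v < V; ++v) {
        std::fill(col.begin(), col.end(), 0ULL);
        for (int i = 0; i < n; ++i)
            if (pass01(i, v))
                col[i >> 6] |= (1ULL << (i & 63));
        std::memcpy(&out[static_cast<R_xlen_t>(v) * nWords * 8], col.data(),
                    nWords * 8);
    }
    out.attr("n") = n;
    out.attr("nWords") = nWords;
    return out;
}

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
    return __builtin_popcountll(x);
#else
    int c = 0;
    while (x) { x &= x - 1; ++c; }
    return c;
#endif
}

// S: M x k matrix of 1-based value indices; packA/packI from packPassBits.
// [[Rcpp::export(name = ".scorePackedCpp")]]
List scorePacked(IntegerMatrix S, RawVector packA, RawVector packI) {
    const int M = S.nrow(), k = S.ncol();
    const int nA = as<int>(packA.attr("n"));
    const int wA = as<int>(packA.attr("nWords"));
    const int nI = as<int>(packI.attr("n"));
    const int wI = as<int>(packI.attr("nWords"));
    const uint64_t *pA = reinterpret_cast<const uint64_t *>(RAW(packA));
    const uint64_t *pI = reinterpret_cast<const uint64_t *>(RAW(packI));
    NumericVector pa(M), pna(M);
    for (int m = 0; m < M; ++m) {
        int cA = 0, cI = 0;
        for (int w = 0; w < wA; ++w) {
            uint64_t acc = pA[static_cast<size_t>(S(m, 0) - 1) * wA + w];
            for (int j = 1; j < k; ++j)
                acc &= pA[static_cast<size_t>(S(m, j) - 1) * wA + w];
            cA += popcount64(acc);
        }
        for (int w = 0; w < wI; ++w) {
            uint64_t acc = pI[static_cast<size_t>(S(m, 0) - 1) * wI + w];
            for (int j = 1; j < k; ++j)
                acc &= pI[static_cast<size_t>(S(m, j) - 1) * wI + w];
            cI += popcount64(acc);
        }
        pa[m] = 100.0 * cA / nA;
        pna[m] = 100.0 * cI / nI;
    }
    return List::create(_["pa"] = pa, _["pna"] = pna);
}
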