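/* Bit packing: remove unused high bits from a vector of unsigned values,
 * concatenating the low `bit_depth` bits of each value LSB-first into a
 * dense byte string. Exact inverse provided. */

#include <R.h>
#include <Rinternals.h>
#include <stdint.h>

SEXP C_pack_bits(SEXP values_, SEXP bit_depth_)
{
    const int bd = asInteger(bit_depth_);
    if (bd < 1 || bd > 32) error("bit_depth must be in 1..32");
    const R_xlen_t n = xlength(values_);
    const int *v = INTEGER(values_);
    /* R integers are < 2^31, so widths >= 31 can never overflow */
    const uint32_t lim = bd >= 31 ? 0u : ((uint32_t)1u << bd);

    R_xlen_t nbytes = (n * bd + 7) / 8;
    SEXP out_ = PROTECT(allocVector(RAWSXP, nbytes));
    Rbyte *out = RAW(out_);
    memset(out, 0, nbytes);

    uint64_t acc = 0;
    int nacc = 0;
    R_xlen_t pos = 0;
    for (R_xlen_t i = 0; i < n; i++) {
        if (v[i] == NA_INTEGER || v[i] < 0 || (lim && (uint32_t)v[i] >= lim))
            error("value %d at position %lld does not fit in %d bits",
                  v[i], (long long)(i + 1), bd);
        acc |= ((uint64_t)(uint32_t)v[i]) << nacc;
        nacc += bd;
        while (nacc >= 8) {
            out[pos++] = (Rbyte)(acc & 0xFF);
            acc >>= 8;
            nacc -= 8;
        }
    }
    if (nacc > 0) out[pos++] = (Rbyte)(acc & 0xFF);
    UNPROTECT(1);
    return out_;
}

SEXP C_unpack_bits(SEXP bytes_, SEXP bit_depth_, SEXP n_)
{
    const int bd = asInteger(bit_depth_);
    if (bd < 1 || bd > 32) error("bit_depth must be in 1..32");
    const R_xlen_t n = (R_xlen_t)asReal(n_);
    const R_xlen_t nbytes = xlength(bytes_);
    if ((n * bd + 7) / 8 > nbytes)
        error("payload too short: need %lld bytes for %lld values at %d bits, have %lld",
              (long long)((n * bd + 7) / 8), (long long)n, bd, (long long)nbytes);
    const Rbyte *in = RAW(bytes_);

    SEXP out_ = PROTECT(allocVector(INTSXP, n));
    int *out = INTEGER(out_);
    uint64_t acc = 0;
    int nacc = 0;
    R_xlen_t pos = 0;
    const uint32_t msk = bd >= 32 ? 0xFFFFFFFFu : (((uint32_t)1u << bd) - 1u);
    for (R_xlen_t i = 0; i < n; i++) {
        while (nacc < bd) {
            acc |= ((uint64_t)in[pos++]) << nacc;
            nacc += 8;
        }
        out[i] = (int)(acc & msk);
        acc >>= bd;
        nacc -= bd;
    }
    UNPROTECT(1);
    return out_;
}
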