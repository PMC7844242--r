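/* Bitshuffle prefilter on byte streams: within each chunk the i-th bit of
 * every byte is gathered into a contiguous bit plane, so that payloads whose
 * bytes share bit patterns (e.g. sparse binary maps, packed low-entropy
 * intensities) become long runs that downstream codecs squeeze harder.
 * A trailing partial chunk shorter than 8 bytes is copied verbatim. */

#include <R.h>
#include <Rinternals.h>
#include <stdint.h>
#include <string.h>

static void shuffle_chunk(const Rbyte *in, Rbyte *out, R_xlen_t len)
{
    memset(out, 0, len);
    for (int p = 0; p < 8; p++) {
        for (R_xlen_t i = 0; i < len; i++) {
            R_xlen_t j = (R_xlen_t)p * len + i;   /* output bit position */
            out[j >> 3] |= (Rbyte)(((in[i] >> p) & 1u) << (j & 7));
        }
    }
}

static void unshuffle_chunk(const Rbyte *in, Rbyte *out, R_xlen_t len)
{
    memset(out, 0, len);
    for (int p = 0; p < 8; p++) {
        for (R_xlen_t i = 0; i < len; i++) {
            R_xlen_t j = (R_xlen_t)p * len + i;
            out[i] |= (Rbyte)(((in[j >> 3] >> (j & 7)) & 1u) << p);
        }
    }
}

static SEXP do_bitshuffle(SEXP data_, SEXP chunk_size_, int inverse)
{
    const R_xlen_t n = xlength(data_);
    R_xlen_t chunk = (R_xlen_t)asReal(chunk_size_);
    if (chunk < 8) error("chunk_size must be at least 8 bytes");
    const Rbyte *in = RAW(data_);
    SEXP out_ = PROTECT(allocVector(RAWSXP, n));
    Rbyte *out = RAW(out_);
    R_xlen_t off = 0;
    while (off < n) {
        R_xlen_t len = (n - off < chunk) ? (n - off) : chunk;
        if (len < 8) {
            memcpy(out + off, in + off, len);
        } else if (inverse) {
            unshuffle_chunk(in + off, out + off, len);
        } else {
            shuffle_chunk(in + off, out + off, len);
        }
        off += len;
    }
    UNPROTECT(1);
    return out_;
}

SEXP C_bitshuffle(SEXP data_, SEXP chunk_size_)
{
    return do_bitshuffle(data_, chunk_size_, 0);
}

SEXP C_bitunshuffle(SEXP data_, SEXP chunk_size_)
{
    return do_bitshuffle(data_, chunk_size_, 1);
}
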