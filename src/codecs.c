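/* Bindings to the zstd, lz4 and snappy lossless codecs plus zlib's CRC-32.
 * deflate/bzip2/lzma are handled in R via memCompress(). Decompression
 * failures raise R errors; they are never silently swallowed. */

#include <R.h>
#include <Rinternals.h>
#include <stdint.h>

#include <zstd.h>
#include <lz4.h>
#include <lz4hc.h>
#include <snappy-c.h>
#include <zlib.h>
#include <bzlib.h>
#include <lzma.h>

SEXP C_zstd_compress(SEXP data_, SEXP level_)
{
    const size_t n = (size_t)xlength(data_);
    const int level = asInteger(level_);
    size_t bound = ZSTD_compressBound(n);
    SEXP buf_ = PROTECT(allocVector(RAWSXP, bound));
    size_t sz = ZSTD_compress(RAW(buf_), bound, RAW(data_), n, level);
    if (ZSTD_isError(sz)) error("zstd compression failed: %s", ZSTD_getErrorName(sz));
    SEXP out_ = PROTECT(allocVector(RAWSXP, sz));
    memcpy(RAW(out_), RAW(buf_), sz);
    UNPROTECT(2);
    return out_;
}

SEXP C_zstd_decompress(SEXP data_, SEXP orig_size_)
{
    const size_t n = (size_t)xlength(data_);
    const size_t osz = (size_t)asReal(orig_size_);
    SEXP out_ = PROTECT(allocVector(RAWSXP, osz));
    size_t sz = ZSTD_decompress(RAW(out_), osz, RAW(data_), n);
    if (ZSTD_isError(sz)) error("zstd decompression failed: %s", ZSTD_getErrorName(sz));
    if (sz != osz) error("zstd decompression produced %lu bytes, expected %lu",
                         (unsigned long)sz, (unsigned long)osz);
    UNPROTECT(1);
    return out_;
}

SEXP C_zstd_max_level(void)
{
    return ScalarInteger(ZSTD_maxCLevel());
}

SEXP C_lz4_compress(SEXP data_, SEXP high_compression_)
{
    const int n = (int)xlength(data_);
    const int hc = asLogical(high_compression_);
    int bound = LZ4_compressBound(n);
    SEXP buf_ = PROTECT(allocVector(RAWSXP, bound));
    int sz = hc
        ? LZ4_compress_HC((const char *)RAW(data_), (char *)RAW(buf_), n, bound, LZ4HC_CLEVEL_MAX)
        : LZ4_compress_default((const char *)RAW(data_), (char *)RAW(buf_), n, bound);
    if (sz <= 0) error("lz4 compression failed");
    SEXP out_ = PROTECT(allocVector(RAWSXP, sz));
    memcpy(RAW(out_), RAW(buf_), sz);
    UNPROTECT(2);
    return out_;
}

SEXP C_lz4_decompress(SEXP data_, SEXP orig_size_)
{
    const int n = (int)xlength(data_);
    const int osz = (int)asReal(orig_size_);
    SEXP out_ = PROTECT(allocVector(RAWSXP, osz));
    int sz = LZ4_decompress_safe((const char *)RAW(data_), (char *)RAW(out_), n, osz);
    if (sz < 0) error("lz4 decompression failed (corrupted stream)");
    if (sz != osz) error("lz4 decompression produced %d bytes, expected %d", sz, osz);
    UNPROTECT(1);
    return out_;
}

SEXP C_snappy_compress(SEXP data_)
{
    const size_t n = (size_t)xlength(data_);
    size_t bound = snappy_max_compressed_length(n);
    SEXP buf_ = PROTECT(allocVector(RAWSXP, bound));
    size_t sz = bound;
    if (snappy_compress((const char *)RAW(data_), n, (char *)RAW(buf_), &sz) != SNAPPY_OK)
        error("snappy compression failed");
    SEXP out_ = PROTECT(allocVector(RAWSXP, sz));
    memcpy(RAW(out_), RAW(buf_), sz);
    UNPROTECT(2);
    return out_;
}

SEXP C_snappy_decompress(SEXP data_, SEXP orig_size_)
{
    const size_t n = (size_t)xlength(data_);
    size_t osz = (size_t)asReal(orig_size_);
    SEXP out_ = PROTECT(allocVector(RAWSXP, osz));
    size_t sz = osz;
    if (snappy_uncompress((const char *)RAW(data_), n, (char *)RAW(out_), &sz) != SNAPPY_OK)
        error("snappy decompression failed (corrupted stream)");
    if (sz != osz) error("snappy decompression produced %lu bytes, expected %lu",
                         (unsigned long)sz, (unsigned long)osz);
    UNPROTECT(1);
    return out_;
}

SEXP C_deflate_compress(SEXP data_, SEXP level_)
{
    const uLong n = (uLong)xlength(data_);
    uLong bound = compressBound(n);
    SEXP buf_ = PROTECT(allocVector(RAWSXP, bound));
    uLong sz = bound;
    int rc = compress2((Bytef *)RAW(buf_), &sz, (const Bytef *)RAW(data_), n,
                       asInteger(level_));
    if (rc != Z_OK) error("deflate compression failed (zlib error %d)", rc);
    SEXP out_ = PROTECT(allocVector(RAWSXP, sz));
    memcpy(RAW(out_), RAW(buf_), sz);
    UNPROTECT(2);
    return out_;
}

SEXP C_deflate_decompress(SEXP data_, SEXP orig_size_)
{
    uLong osz = (uLong)asReal(orig_size_);
    SEXP out_ = PROTECT(allocVector(RAWSXP, osz));
    uLong sz = osz;
    int rc = uncompress((Bytef *)RAW(out_), &sz, (const Bytef *)RAW(data_),
                        (uLong)xlength(data_));
    if (rc != Z_OK) error("deflate decompression failed (zlib error %d)", rc);
    if (sz != osz) error("deflate decompression produced %lu bytes, expected %lu",
                         (unsigned long)sz, (unsigned long)osz);
    UNPROTECT(1);
    return out_;
}

SEXP C_bzip2_compress(SEXP data_, SEXP block_size_)
{
    unsigned n = (unsigned)xlength(data_);
    unsigned bound = n + n / 100 + 600;
    SEXP buf_ = PROTECT(allocVector(RAWSXP, bound));
    unsigned sz = bound;
    int rc = BZ2_bzBuffToBuffCompress((char *)RAW(buf_), &sz, (char *)RAW(data_),
                                      n, asInteger(block_size_), 0, 0);
    if (rc != BZ_OK) error("bzip2 compression failed (error %d)", rc);
    SEXP out_ = PROTECT(allocVector(RAWSXP, sz));
    memcpy(RAW(out_), RAW(buf_), sz);
    UNPROTECT(2);
    return out_;
}

SEXP C_bzip2_decompress(SEXP data_, SEXP orig_size_)
{
    unsigned osz = (unsigned)asReal(orig_size_);
    SEXP out_ = PROTECT(allocVector(RAWSXP, osz));
    unsigned sz = osz;
    int rc = BZ2_bzBuffToBuffDecompress((char *)RAW(out_), &sz, (char *)RAW(data_),
                                        (unsigned)xlength(data_), 0, 0);
    if (rc != BZ_OK) error("bzip2 decompression failed (error %d)", rc);
    if (sz != osz) error("bzip2 decompression produced %u bytes, expected %u", sz, osz);
    UNPROTECT(1);
    return out_;
}

SEXP C_lzma_compress(SEXP data_, SEXP preset_)
{
    size_t n = (size_t)xlength(data_);
    size_t bound = lzma_stream_buffer_bound(n);
    SEXP buf_ = PROTECT(allocVector(RAWSXP, bound));
    size_t pos = 0;
    lzma_ret rc = lzma_easy_buffer_encode((uint32_t)asInteger(preset_), LZMA_CHECK_CRC32,
                                          NULL, (const uint8_t *)RAW(data_), n,
                                          (uint8_t *)RAW(buf_), &pos, bound);
    if (rc != LZMA_OK) error("lzma compression failed (error %d)", (int)rc);
    SEXP out_ = PROTECT(allocVector(RAWSXP, pos));
    memcpy(RAW(out_), RAW(buf_), pos);
    UNPROTECT(2);
    return out_;
}

SEXP C_lzma_decompress(SEXP data_, SEXP orig_size_)
{
    size_t osz = (size_t)asReal(orig_size_);
    SEXP out_ = PROTECT(allocVector(RAWSXP, osz));
    uint64_t memlimit = UINT64_MAX;
    size_t in_pos = 0, out_pos = 0;
    lzma_ret rc = lzma_stream_buffer_decode(&memlimit, 0, NULL,
                                            (const uint8_t *)RAW(data_),
                                            &in_pos, (size_t)xlength(data_),
                                            (uint8_t *)RAW(out_), &out_pos, osz);
    if (rc != LZMA_OK) error("lzma decompression failed (error %d)", (int)rc);
    if (out_pos != osz) error("lzma decompression produced %lu bytes, expected %lu",
                              (unsigned long)out_pos, (unsigned long)osz);
    UNPROTECT(1);
    return out_;
}

SEXP C_crc32(SEXP data_)
{
    uLong crc = crc32(0L, Z_NULL, 0);
    crc = crc32(crc, (const Bytef *)RAW(data_), (uInt)xlength(data_));
    return ScalarReal((double)crc);
}
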