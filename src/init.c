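#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP C_label_components(SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP C_pack_bits(SEXP, SEXP);
extern SEXP C_unpack_bits(SEXP, SEXP, SEXP);
extern SEXP C_bitshuffle(SEXP, SEXP);
extern SEXP C_bitunshuffle(SEXP, SEXP);
extern SEXP C_zstd_compress(SEXP, SEXP);
extern SEXP C_zstd_decompress(SEXP, SEXP);
extern SEXP C_zstd_max_level(void);
extern SEXP C_lz4_compress(SEXP, SEXP);
extern SEXP C_lz4_decompress(SEXP, SEXP);
extern SEXP C_snappy_compress(SEXP);
extern SEXP C_snappy_decompress(SEXP, SEXP);
extern SEXP C_deflate_compress(SEXP, SEXP);
extern SEXP C_deflate_decompress(SEXP, SEXP);
extern SEXP C_bzip2_compress(SEXP, SEXP);
extern SEXP C_bzip2_decompress(SEXP, SEXP);
extern SEXP C_lzma_compress(SEXP, SEXP);
extern SEXP C_lzma_decompress(SEXP, SEXP);
extern SEXP C_crc32(SEXP);

static const R_CallMethodDef callMethods[] = {
    {"C_label_components", (DL_FUNC) &C_label_components, 5},
    {"C_pack_bits",        (DL_FUNC) &C_pack_bits,        2},
    {"C_unpack_bits",      (DL_FUNC) &C_unpack_bits,      3},
    {"C_bitshuffle",       (DL_FUNC) &C_bitshuffle,       2},
    {"C_bitunshuffle",     (DL_FUNC) &C_bitunshuffle,     2},
    {"C_zstd_compress",    (DL_FUNC) &C_zstd_compress,    2},
    {"C_zstd_decompress",  (DL_FUNC) &C_zstd_decompress,  2},
    {"C_zstd_max_level",   (DL_FUNC) &C_zstd_max_level,   0},
    {"C_lz4_compress",     (DL_FUNC) &C_lz4_compress,     2},
    {"C_lz4_decompress",   (DL_FUNC) &C_lz4_decompress,   2},
    {"C_snappy_compress",  (DL_FUNC) &C_snappy_compress,  1},
    {"C_snappy_decompress",(DL_FUNC) &C_snappy_decompress,2},
    {"C_deflate_compress",   (DL_FUNC) &C_deflate_compress,   2},
    {"C_deflate_decompress", (DL_FUNC) &C_deflate_decompress, 2},
    {"C_bzip2_compress",     (DL_FUNC) &C_bzip2_compress,     2},
    {"C_bzip2_decompress",   (DL_FUNC) &C_bzip2_decompress,   2},
    {"C_lzma_compress",      (DL_FUNC) &C_lzma_compress,      2},
    {"C_lzma_decompress",    (DL_FUNC) &C_lzma_decompress,    2},
    {"C_crc32",            (DL_FUNC) &C_crc32,            1},
    {NULL, NULL, 0}
};

void R_init_recode(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
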