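# zstd / lz4 / snappy / bz2 / zlib live in the same prefix as R itself;
# lzma comes from the system liblzma-dev (searched last, so it cannot
# shadow the toolchain's own headers)
PKG_CPPFLAGS = -I"$(R_HOME)/../../include" -idirafter /usr/include
PKG_LIBS = -L"$(R_HOME)/../../lib" -Wl,-rpath,"$(R_HOME)/../../lib" -L/usr/lib/x86_64-linux-gnu -lzstd -llz4 -lsnappy -lbz2 -llzma -lz
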