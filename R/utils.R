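# run expr under a temporary RNG state seeded with `seed` (NULL = use the
# current stream)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

u32_to_raw <- function(x) {
  x <- as.double(x)
  as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 256^2 %% 256, x %/% 256^3 %% 256))
}

raw_to_u32 <- function(r) {
  sum(as.double(as.integer(r)) * 256^(0:3))
}

u64_to_raw <- function(x) {
  x <- as.double(x)  # exact below 2^53
  c(u32_to_raw(x %% 2^32), u32_to_raw(x %/% 2^32))
}

raw_to_u64 <- function(r) {
  raw_to_u32(r[1:4]) + raw_to_u32(r[5:8]) * 2^32
}

crc32_raw <- function(data) .Call(C_crc32, data)

# accumulate val into m at (possibly duplicated) linear indices
add_at <- function(m, idx, val) {
  acc <- rowsum(val, idx)
  m[as.integer(rownames(acc))] <- m[as.integer(rownames(acc))] + acc[, 1]
  m
}
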