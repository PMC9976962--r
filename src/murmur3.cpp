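#include <Rcpp.h>
#include <cstdint>
#include <cstring>

// MurmurHash3 x86_32 (public-domain algorithm by Austin Appleby).
static uint32_t murmur3_32(const char *key, size_t len, uint32_t seed) {
  const uint32_t c1 = 0xcc9e2d51u, c2 = 0x1b873593u;
  uint32_t h = seed;
  const size_t nblocks = len / 4;
  for (size_t i = 0; i < nblocks; ++i) {
    uint32_t k;
    std::memcpy(&k, key + i * 4, 4);
    k *= c1; k = (k << 15) | (k >> 17); k *= c2;
    h ^= k; h = (h << 13) | (h >> 19); h = h * 5 + 0xe6546b64u;
  }
  uint32_t k = 0;
  const uint8_t *tail = (const uint8_t *)(key + nblocks * 4);
  switch (len & 3) {
  case 3: k ^= (uint32_t)tail[2] << 16; // fallthrough
  case 2: k ^= (uint32_t)tail[1] << 8;  // fallthrough
  case 1: k ^= (uint32_t)tail[0];
    k *= c1; k = (k << 15) | (k >> 17); k *= c2; h ^= k;
  }
  h ^= (uint32_t)len;
  h ^= h >> 16; h *= 0x85ebca6bu; h ^= h >> 13; h *= 0xc2b2ae35u; h ^= h >> 16;
  return h;
}

// [[Rcpp::export]]
Rcpp::NumericVector murmur3_hash(Rcpp::CharacterVector x, int seed) {
  const R_xlen_t n = x.size();
  Rcpp::NumericVector out(n); // doubles hold uint32 exactly
  const uint32_t s = (uint32_t)seed;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *str = CHAR(STRING_ELT(x, i));
    out[i] = (double)murmur3_32(str, std::strlen(str), s);
  }
  return out;
}
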