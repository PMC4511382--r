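#include <Rcpp.h>
#include <cstdint>

using namespace Rcpp;

// MurmurHash2, 32-bit, Austin Appleby's public-domain reference algorithm.
// Feature indices must be identical between training and prediction and
// across platforms, so the hash is fixed here rather than delegated to a
// platform-dependent routine.
static uint32_t murmur2(const char *key, int len, uint32_t seed) {
  const uint32_t m = 0x5bd1e995;
  const int r = 24;
  uint32_t h = seed ^ static_cast<uint32_t>(len);
  const unsigned char *data = reinterpret_cast<const unsigned char *>(key);
  while (len >= 4) {
    uint32_t k;
    std::memcpy(&k, data, 4);
    k *= m; k ^= k >> r; k *= m;
    h *= m; h ^= k;
    data += 4; len -= 4;
  }
  switch (len) {
  case 3: h ^= static_cast<uint32_t>(data[2]) << 16;
  case 2: h ^= static_cast<uint32_t>(data[1]) << 8;
  case 1: h ^= static_cast<uint32_t>(data[0]); h *= m;
  }
  h ^= h >> 13; h *= m; h ^= h >> 15;
  return h;
}

// [[Rcpp::export(name = ".murmur32")]]
IntegerVector murmur32(CharacterVector keys, int bits, int seed = 0) {
  if (bits < 1 || bits > 30) stop("bits must be in [1, 30]");
  const uint32_t mask = (1u << bits) - 1u;
  const R_xlen_t n = keys.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(keys[i])) { out[i] = NA_INTEGER; continue; }
    const char *s = CHAR(STRING_ELT(keys, i));
    uint32_t h = murmur2(s, static_cast<int>(std::strlen(s)),
                         static_cast<uint32_t>(seed));
    out[i] = static_cast<int>(h & mask);
  }
  return out;
}
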