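#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// 128-bit FNV-1a digest, hex-encoded.  Process-independent and
// platform-stable (unlike R's or C++'s salted string hashes), so WL tokens
// and TF-IDF vocabularies are reproducible across runs and machines.
// [[Rcpp::export]]
CharacterVector fnv128_hex(CharacterVector x) {
  const unsigned __int128 prime =
      ((unsigned __int128)0x0000000001000000ULL << 64) | 0x000000000000013BULL;
  const unsigned __int128 offset =
      ((unsigned __int128)0x6c62272e07bb0142ULL << 64) | 0x62b821756295c58dULL;
  static const char* hexd = "0123456789abcdef";
  R_xlen_t n = x.size();
  CharacterVector out(n);
  char buf[33];
  buf[32] = '\0';
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(x, i));
    unsigned __int128 h = offset;
    for (const unsigned char* p = (const unsigned char*)s; *p; ++p) {
      h ^= (unsigned __int128)(*p);
      h *= prime;
    }
    for (int j = 31; j >= 0; --j) {
      buf[j] = hexd[(unsigned)(h & 0xF)];
      h >>= 4;
    }
    out[i] = buf;
  }
  return out;
}
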