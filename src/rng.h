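#ifndef AACDDM_RNG_H
#define AACDDM_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained counter-seeded RNG for the bulk path simulator, so that
// million-path simulations are reproducible from an integer seed and do not
// churn R's global RNG stream. xoshiro256++ (Blackman & Vigna) with a
// splitmix64 seeder; normals via the Marsaglia-Tsang 128-layer ziggurat.

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // uniform on (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

class ZigguratNormal {
  uint32_t kn[128];
  double wn[128], fn[128];
public:
  ZigguratNormal() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline double draw(Xoshiro256& rng) {
    const double r = 3.442619855899;
    for (;;) {
      int32_t hz = (int32_t)(rng.next() >> 32);
      uint32_t iz = hz & 127;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      // slow path
      double x = hz * wn[iz];
      if (iz == 0) {  // tail
        double y;
        do {
          x = -std::log(rng.unif()) / r;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
      // otherwise loop with a fresh hz
    }
  }
};

#endif
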