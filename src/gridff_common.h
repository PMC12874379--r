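#ifndef GRIDFF_COMMON_H
#define GRIDFF_COMMON_H

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

// Units: energy eV, length Angstrom, charge e, time fs.
namespace gridff {

constexpr double K_E = 14.399645;        // Coulomb constant, eV*Angstrom/e^2
constexpr double K_B = 8.617333262e-5;   // Boltzmann, eV/K

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm2() const { return x * x + y * y + z * z; }
  double norm() const { return std::sqrt(norm2()); }
};

// z-fastest contiguous layout: idx = (ix*ny + iy)*nz + iz
inline R_xlen_t grid_index(int ix, int iy, int iz, int ny, int nz) {
  return ((R_xlen_t)ix * ny + iy) * nz + iz;
}

// counter-based RNG: splitmix64-style hash -> U(0,1) -> N(0,1)
inline std::uint64_t mix64(std::uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

inline double hash_u01(std::uint64_t seed, std::uint64_t stream,
                       std::uint64_t counter, std::uint64_t lane) {
  std::uint64_t h = mix64(seed);
  h = mix64(h ^ mix64(stream + 0x3c6ef372fe94f82aULL));
  h = mix64(h ^ mix64(counter + 0x1b873593ULL));
  h = mix64(h ^ mix64(lane + 0x85ebca6bULL));
  // 53-bit mantissa uniform in (0,1)
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

inline double hash_normal(std::uint64_t seed, std::uint64_t stream,
                          std::uint64_t counter, std::uint64_t lane) {
  double u1 = hash_u01(seed, stream, counter, 2 * lane);
  double u2 = hash_u01(seed, stream, counter, 2 * lane + 1);
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

}  // namespace gridff

#endif
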