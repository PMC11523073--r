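#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// xorshift64* PRNG with explicit arithmetic so streams are identical across
// compilers (std:: distributions are implementation-defined).
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) {
    s = seed * 6364136223846793005ULL + 1442695040888963407ULL;
    if (s == 0) s = 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// Uniform random rotation matrix from a Shoemake quaternion.
static void random_rotation(XorShift &rng, double R[3][3]) {
  const double two_pi = 6.283185307179586476925286766559;
  double u1 = rng.unif(), u2 = rng.unif(), u3 = rng.unif();
  double a = std::sqrt(1.0 - u1), b = std::sqrt(u1);
  double x = a * std::sin(two_pi * u2);
  double y = a * std::cos(two_pi * u2);
  double z = b * std::sin(two_pi * u3);
  double w = b * std::cos(two_pi * u3);
  R[0][0] = 1 - 2 * (y * y + z * z);
  R[0][1] = 2 * (x * y - z * w);
  R[0][2] = 2 * (x * z + y * w);
  R[1][0] = 2 * (x * y + z * w);
  R[1][1] = 1 - 2 * (x * x + z * z);
  R[1][2] = 2 * (y * z - x * w);
  R[2][0] = 2 * (x * z - y * w);
  R[2][1] = 2 * (y * z + x * w);
  R[2][2] = 1 - 2 * (x * x + y * y);
}

//' @name cpp_sasa
//' @noRd
// [[Rcpp::export(name = "cpp_sasa")]]
double cpp_sasa(NumericMatrix coords, NumericVector radii, double probe,
                int n_points) {
  const int n = coords.nrow();
  const double four_pi = 12.566370614359172953850573533118;
  // golden-spiral unit sphere points (seed-free, deterministic)
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * k;
    px[k] = rho * std::cos(phi);
    py[k] = rho * std::sin(phi);
    pz[k] = z;
  }
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  double area = 0.0;
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double cut = R[i] + R[j];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = coords(i, 0) + R[i] * px[k];
      double qy = coords(i, 1) + R[i] * py[k];
      double qz = coords(i, 2) + R[i] * pz[k];
      bool exposed = true;
      for (size_t m = 0; m < nbr.size(); ++m) {
        int j = nbr[m];
        double dx = qx - coords(j, 0);
        double dy = qy - coords(j, 1);
        double dz = qz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) {
          exposed = false;
          break;
        }
      }
      if (exposed) ++acc;
    }
    area += four_pi * R[i] * R[i] * (double)acc / n_points;
  }
  return area;
}

//' @name cpp_pa_area
//' @noRd
// [[Rcpp::export(name = "cpp_pa_area")]]
double cpp_pa_area(NumericMatrix coords, NumericVector radii, int n_orient,
                   double grid, double seed) {
  const int n = coords.nrow();
  XorShift rng((uint64_t)seed);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, (double)radii[i]);

  std::vector<double> px(n), py(n);
  std::vector<uint8_t> cell;
  double total = 0.0;
  double R[3][3];

  for (int o = 0; o < n_orient; ++o) {
    random_rotation(rng, R);
    double minx = 1e300, maxx = -1e300, miny = 1e300, maxy = -1e300;
    for (int i = 0; i < n; ++i) {
      double x = R[0][0] * coords(i, 0) + R[0][1] * coords(i, 1) +
                 R[0][2] * coords(i, 2);
      double y = R[1][0] * coords(i, 0) + R[1][1] * coords(i, 1) +
                 R[1][2] * coords(i, 2);
      px[i] = x;
      py[i] = y;
      minx = std::min(minx, x - radii[i]);
      maxx = std::max(maxx, x + radii[i]);
      miny = std::min(miny, y - radii[i]);
      maxy = std::max(maxy, y + radii[i]);
    }
    // dither the grid origin so discretization bias averages out over
    // orientations
    minx -= rng.unif() * grid;
    miny -= rng.unif() * grid;
    int nx = (int)std::ceil((maxx - minx) / grid) + 1;
    int ny = (int)std::ceil((maxy - miny) / grid) + 1;
    cell.assign((size_t)nx * ny, 0);
    for (int i = 0; i < n; ++i) {
      double r = radii[i];
      double cx = (px[i] - minx) / grid - 0.5;  // cell-center coordinates
      double cy = (py[i] - miny) / grid - 0.5;
      int ix0 = std::max(0, (int)std::ceil(cx - r / grid));
      int ix1 = std::min(nx - 1, (int)std::floor(cx + r / grid));
      for (int ix = ix0; ix <= ix1; ++ix) {
        double dx = (ix - cx) * grid;
        double h = r * r - dx * dx;
        if (h < 0) continue;
        double half = std::sqrt(h) / grid;
        int iy0 = std::max(0, (int)std::ceil(cy - half));
        int iy1 = std::min(ny - 1, (int)std::floor(cy + half));
        if (iy0 > iy1) continue;
        std::fill(cell.begin() + (size_t)ix * ny + iy0,
                  cell.begin() + (size_t)ix * ny + iy1 + 1, (uint8_t)1);
      }
    }
    size_t covered = 0;
    for (size_t k = 0; k < cell.size(); ++k) covered += cell[k];
    total += (double)covered * grid * grid;
  }
  return total / n_orient;
}
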