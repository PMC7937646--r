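// Analytic CPU ray caster over procedural scene primitives.
//
// Scene model: a textured ground plane (y = 0), vertical cylinders
// ("trunks") with banded bark texture, and thin 3D line segments rendered
// as capsules ("clutter"). Textures are deterministic hash-based value
// noise (fractal sum, gain 0.5 per octave => ~1/f amplitude, ~1/f^2
// power), so renders are bit-reproducible for a fixed texture seed with
// no RNG state involved.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---- deterministic lattice noise -----------------------------------------

static inline uint32_t hash2i(int32_t xi, int32_t yi, uint32_t seed) {
  uint32_t h = seed + 0x9e3779b9u;
  h ^= (uint32_t)xi * 0x85ebca6bu;
  h = (h << 13) | (h >> 19);
  h *= 0xc2b2ae35u;
  h ^= (uint32_t)yi * 0x27d4eb2fu;
  h = (h << 11) | (h >> 21);
  h *= 0x165667b1u;
  h ^= h >> 16;
  return h;
}

static inline double rnd01(int32_t xi, int32_t yi, uint32_t seed) {
  return hash2i(xi, yi, seed) * (1.0 / 4294967296.0);
}

static inline double fade(double t) { return t * t * t * (t * (t * 6 - 15) + 10); }

static double vnoise(double x, double y, uint32_t seed) {
  double fx = std::floor(x), fy = std::floor(y);
  int32_t x0 = (int32_t)fx, y0 = (int32_t)fy;
  double u = fade(x - fx), v = fade(y - fy);
  double a = rnd01(x0, y0, seed),     b = rnd01(x0 + 1, y0, seed);
  double c = rnd01(x0, y0 + 1, seed), d = rnd01(x0 + 1, y0 + 1, seed);
  return (a * (1 - u) + b * u) * (1 - v) + (c * (1 - u) + d * u) * v;
}

// fractal value noise, zero-mean, range roughly [-0.5, 0.5]
static double fbm(double x, double y, uint32_t seed, int octaves, double gain) {
  double amp = 1.0, sum = 0.0, norm = 0.0;
  for (int o = 0; o < octaves; ++o) {
    sum += amp * (vnoise(x, y, seed + 101u * (uint32_t)o) - 0.5);
    norm += amp;
    amp *= gain;
    x *= 2.0; y *= 2.0;
  }
  return sum / norm;
}

static inline double clamp01(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---- scene plumbing -------------------------------------------------------

struct Ground {
  bool present;
  double base[3];
  double noise_amp, noise_scale, gain;
  int octaves;
  uint32_t seed;
  double stripe_amp, stripe_period, stripe_dir_rad;
  double cross_amp, cross_period;
  bool has_tile; double tile_period;
};

struct TrunkTex {
  double base[3];
  double noise_amp, noise_scale, gain;
  int octaves;
  double band_v_amp, band_v_period; // around circumference (m)
  double band_h_amp, band_h_period; // along height (m)
  uint32_t seed;
  bool has_tile; double tile_period;
};

// bilinear periodic lookup in a square noise tile (unit-variance field)
static double tile_sample(const NumericMatrix& tile, double x, double y,
                          double period) {
  int n = tile.nrow();
  double fx = (x / period) * n, fy = (y / period) * n;
  fx -= std::floor(fx / n) * n; fy -= std::floor(fy / n) * n;
  int x0 = (int)fx, y0 = (int)fy;
  double ax = fx - x0, ay = fy - y0;
  int x1 = (x0 + 1) % n, y1 = (y0 + 1) % n;
  return tile(y0, x0) * (1 - ax) * (1 - ay) + tile(y0, x1) * ax * (1 - ay) +
         tile(y1, x0) * (1 - ax) * ay + tile(y1, x1) * ax * ay;
}

struct Light { double dir[3]; double ambient, diffuse; };

// [[Rcpp::export]]
NumericMatrix raycast_rays(NumericMatrix dirs, NumericVector origin, List scene) {
  const int n = dirs.nrow();
  NumericMatrix out(n, 3);
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  // background (optionally textured over view direction: canopy/foliage)
  NumericVector bg = scene["background"];
  double bg_grad = scene.containsElementNamed("background_grad") ?
    as<double>(scene["background_grad"]) : 0.0;
  bool bg_has_tile = false; double bg_amp = 0.0, bg_period = 1.0;
  NumericMatrix bg_tile(0, 0);
  if (scene.containsElementNamed("background_tex") &&
      !Rf_isNull(scene["background_tex"])) {
    List bt = scene["background_tex"];
    bg_has_tile = true;
    bg_tile = as<NumericMatrix>(bt["tile"]);
    bg_amp = as<double>(bt["amp"]);
    bg_period = as<double>(bt["period_rad"]);
  }

  // light
  Light light;
  {
    List li = scene["light"];
    NumericVector ld = li["dir"];
    double nrm = std::sqrt(ld[0]*ld[0] + ld[1]*ld[1] + ld[2]*ld[2]);
    light.dir[0] = ld[0]/nrm; light.dir[1] = ld[1]/nrm; light.dir[2] = ld[2]/nrm;
    light.ambient = as<double>(li["ambient"]);
    light.diffuse = as<double>(li["diffuse"]);
  }

  // ground
  Ground gr; gr.present = false; gr.has_tile = false;
  if (scene.containsElementNamed("ground") && !Rf_isNull(scene["ground"])) {
    List g = scene["ground"];
    gr.present = true;
    NumericVector base = g["base"];
    gr.base[0] = base[0]; gr.base[1] = base[1]; gr.base[2] = base[2];
    gr.noise_amp = as<double>(g["noise_amp"]);
    gr.noise_scale = as<double>(g["noise_scale"]);
    gr.octaves = as<int>(g["octaves"]);
    gr.gain = g.containsElementNamed("gain") ? as<double>(g["gain"]) : 0.5;
    gr.seed = (uint32_t)as<double>(g["seed"]);
    gr.stripe_amp = as<double>(g["stripe_amp"]);
    gr.stripe_period = as<double>(g["stripe_period"]);
    gr.stripe_dir_rad = as<double>(g["stripe_dir_deg"]) * M_PI / 180.0;
    gr.cross_amp = as<double>(g["cross_amp"]);
    gr.cross_period = as<double>(g["cross_period"]);
    gr.has_tile = g.containsElementNamed("tile") && !Rf_isNull(g["tile"]);
    gr.tile_period = gr.has_tile ? as<double>(g["tile_period"]) : 1.0;
  }
  NumericMatrix ground_tile(0, 0);
  if (gr.has_tile) ground_tile = as<NumericMatrix>(as<List>(scene["ground"])["tile"]);

  // trunks: matrix cols cx, cz, radius, height
  NumericMatrix trunks(0, 4);
  TrunkTex ttex; ttex.has_tile = false;
  bool have_trunks = false;
  if (scene.containsElementNamed("trunks") && !Rf_isNull(scene["trunks"])) {
    trunks = as<NumericMatrix>(scene["trunks"]);
    have_trunks = trunks.nrow() > 0;
    if (have_trunks) {
      List t = scene["trunk_tex"];
      NumericVector base = t["base"];
      ttex.base[0] = base[0]; ttex.base[1] = base[1]; ttex.base[2] = base[2];
      ttex.noise_amp = as<double>(t["noise_amp"]);
      ttex.noise_scale = as<double>(t["noise_scale"]);
      ttex.octaves = as<int>(t["octaves"]);
      ttex.gain = t.containsElementNamed("gain") ? as<double>(t["gain"]) : 0.5;
      ttex.band_v_amp = as<double>(t["band_v_amp"]);
      ttex.band_v_period = as<double>(t["band_v_period"]);
      ttex.band_h_amp = as<double>(t["band_h_amp"]);
      ttex.band_h_period = as<double>(t["band_h_period"]);
      ttex.seed = (uint32_t)as<double>(t["seed"]);
      ttex.has_tile = t.containsElementNamed("tile") && !Rf_isNull(t["tile"]);
      ttex.tile_period = ttex.has_tile ? as<double>(t["tile_period"]) : 1.0;
    }
  }
  NumericMatrix trunk_tile(0, 0);
  if (have_trunks && ttex.has_tile)
    trunk_tile = as<NumericMatrix>(as<List>(scene["trunk_tex"])["tile"]);

  // clutter: matrix cols x1,y1,z1,x2,y2,z2,radius,albedo
  NumericMatrix seg(0, 8);
  bool have_seg = false;
  if (scene.containsElementNamed("clutter") && !Rf_isNull(scene["clutter"])) {
    seg = as<NumericMatrix>(scene["clutter"]);
    have_seg = seg.nrow() > 0;
  }

  const double EPS = 1e-9;

  for (int i = 0; i < n; ++i) {
    double dx = dirs(i, 0), dy = dirs(i, 1), dz = dirs(i, 2);
    double dn = std::sqrt(dx*dx + dy*dy + dz*dz);
    dx /= dn; dy /= dn; dz /= dn;

    double tbest = R_PosInf;
    int hit_kind = 0;   // 0 none, 1 ground, 2 trunk, 3 segment
    int hit_idx = -1;
    double nx = 0, ny = 1, nz = 0;

    // ground plane y = 0
    if (gr.present && dy < -EPS && oy > 0) {
      double t = -oy / dy;
      if (t > EPS && t < tbest) { tbest = t; hit_kind = 1; }
    }

    // trunks (finite vertical cylinders, y in [0, h])
    if (have_trunks) {
      for (int k = 0; k < trunks.nrow(); ++k) {
        double cx = trunks(k, 0), cz = trunks(k, 1);
        double R = trunks(k, 2), H = trunks(k, 3);
        double fx = ox - cx, fz = oz - cz;
        double a = dx*dx + dz*dz;
        if (a < EPS) continue;
        double b = 2.0 * (fx*dx + fz*dz);
        double c = fx*fx + fz*fz - R*R;
        double disc = b*b - 4*a*c;
        if (disc < 0) continue;
        double sq = std::sqrt(disc);
        double t = (-b - sq) / (2*a);
        if (t < EPS) t = (-b + sq) / (2*a);
        if (t < EPS || t >= tbest) continue;
        double hy = oy + t * dy;
        if (hy < 0 || hy > H) continue;
        tbest = t; hit_kind = 2; hit_idx = k;
      }
    }

    // clutter capsules: closest-approach hit (thin segments)
    if (have_seg) {
      for (int k = 0; k < seg.nrow(); ++k) {
        double ax = seg(k, 0), ay = seg(k, 1), az = seg(k, 2);
        double bx2 = seg(k, 3), by2 = seg(k, 4), bz2 = seg(k, 5);
        double R = seg(k, 6);
        double ux = bx2 - ax, uy = by2 - ay, uz = bz2 - az;
        double wx = ax - ox, wy = ay - oy, wz = az - oz;
        // closest approach between ray o + t d (unit d) and segment a + s u:
        // t = d.w + s d.u ; s = (u.w - (d.w)(d.u)) / ((d.u)^2 - u.u)
        double du = dx*ux + dy*uy + dz*uz;
        double dw = dx*wx + dy*wy + dz*wz;
        double uw = ux*wx + uy*wy + uz*wz;
        double uu = ux*ux + uy*uy + uz*uz;
        double den = du*du - uu;
        double s = (den < -1e-12) ? (uw - dw*du) / den : 0.0;
        if (s < 0) s = 0; else if (s > 1) s = 1;
        double tray = dw + s*du;
        if (tray < EPS || tray >= tbest) continue;
        double px = ox + tray*dx, py = oy + tray*dy, pz = oz + tray*dz;
        double qx = ax + s*ux, qy = ay + s*uy, qz = az + s*uz;
        double ddx = px - qx, ddy = py - qy, ddz = pz - qz;
        double dist2 = ddx*ddx + ddy*ddy + ddz*ddz;
        if (dist2 > R*R) continue;
        // pull hit slightly toward viewer along the ray
        double adj = std::sqrt(R*R - dist2);
        double th = tray - adj;
        if (th < EPS || th >= tbest) continue;
        tbest = th; hit_kind = 3; hit_idx = k;
      }
    }

    double col[3];
    if (hit_kind == 0) {
      double g = 1.0 + bg_grad * dy;
      if (bg_has_tile) {
        double az = std::atan2(dz, dx), el = std::asin(dy);
        g *= 1.0 + bg_amp * tile_sample(bg_tile, az, el, bg_period);
      }
      col[0] = bg[0] * g; col[1] = bg[1] * g; col[2] = bg[2] * g;
    } else if (hit_kind == 1) {
      double hx = ox + tbest*dx, hz = oz + tbest*dz;
      nx = 0; ny = 1; nz = 0;
      double tex = 0.5 + (gr.has_tile ?
        gr.noise_amp * tile_sample(ground_tile, hx, hz, gr.tile_period) :
        gr.noise_amp * fbm(hx * gr.noise_scale, hz * gr.noise_scale,
                           gr.seed, gr.octaves, gr.gain));
      if (gr.stripe_amp > 0 || gr.cross_amp > 0) {
        double cs = std::cos(gr.stripe_dir_rad), sn = std::sin(gr.stripe_dir_rad);
        double xr = cs*hx + sn*hz;   // across-track coordinate
        double zr = -sn*hx + cs*hz;  // along-track coordinate
        if (gr.stripe_amp > 0)
          tex += gr.stripe_amp * std::sin(2.0 * M_PI * xr / gr.stripe_period);
        if (gr.cross_amp > 0) {
          double mod = 0.5 + 0.5 * vnoise(xr * 0.7, zr * 0.7, gr.seed + 77u);
          tex += gr.cross_amp * mod * std::sin(2.0 * M_PI * zr / gr.cross_period);
        }
      }
      tex = clamp01(tex, 0.03, 1.0);
      double lam = light.ambient + light.diffuse * std::max(0.0, ny * light.dir[1]);
      for (int c = 0; c < 3; ++c) col[c] = gr.base[c] * tex * lam;
    } else if (hit_kind == 2) {
      double cx = trunks(hit_idx, 0), cz = trunks(hit_idx, 1);
      double R = trunks(hit_idx, 2);
      double hx = ox + tbest*dx, hy = oy + tbest*dy, hz = oz + tbest*dz;
      nx = (hx - cx) / R; ny = 0; nz = (hz - cz) / R;
      double ang = std::atan2(hz - cz, hx - cx);
      double scirc = ang * R; // arclength around circumference
      double tnoise = ttex.has_tile ?
        tile_sample(trunk_tile, scirc + 0.37 * (double)hit_idx,
                    hy + 0.61 * (double)hit_idx, ttex.tile_period) :
        fbm(scirc * ttex.noise_scale, hy * ttex.noise_scale * 0.35,
            ttex.seed + (uint32_t)(hit_idx * 131), ttex.octaves, ttex.gain);
      double tex = 0.5 + ttex.noise_amp * tnoise
        + ttex.band_v_amp * std::sin(2.0 * M_PI * scirc / ttex.band_v_period)
        + ttex.band_h_amp * std::sin(2.0 * M_PI * hy / ttex.band_h_period);
      tex = clamp01(tex, 0.03, 1.0);
      double ndl = nx*light.dir[0] + ny*light.dir[1] + nz*light.dir[2];
      double lam = light.ambient + light.diffuse * std::max(0.0, ndl);
      for (int c = 0; c < 3; ++c) col[c] = ttex.base[c] * tex * lam;
    } else {
      // segment: albedo gray, lambert with capsule normal
      double ax = seg(hit_idx, 0), ay = seg(hit_idx, 1), az = seg(hit_idx, 2);
      double ux = seg(hit_idx, 3) - ax, uy = seg(hit_idx, 4) - ay, uz = seg(hit_idx, 5) - az;
      double alb = seg(hit_idx, 7);
      double px = ox + tbest*dx, py = oy + tbest*dy, pz = oz + tbest*dz;
      double uu = ux*ux + uy*uy + uz*uz;
      double s = uu > 1e-12 ? ((px-ax)*ux + (py-ay)*uy + (pz-az)*uz) / uu : 0.0;
      if (s < 0) s = 0; else if (s > 1) s = 1;
      double qx = ax + s*ux, qy = ay + s*uy, qz = az + s*uz;
      nx = px - qx; ny = py - qy; nz = pz - qz;
      double nn = std::sqrt(nx*nx + ny*ny + nz*nz);
      if (nn > 1e-12) { nx /= nn; ny /= nn; nz /= nn; }
      else { nx = -dx; ny = -dy; nz = -dz; }
      double ndl = nx*light.dir[0] + ny*light.dir[1] + nz*light.dir[2];
      double lam = light.ambient + light.diffuse * std::max(0.0, ndl);
      for (int c = 0; c < 3; ++c) col[c] = alb * lam;
    }

    out(i, 0) = clamp01(col[0], 0.0, 1.0);
    out(i, 1) = clamp01(col[1], 0.0, 1.0);
    out(i, 2) = clamp01(col[2], 0.0, 1.0);
  }
  return out;
}
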