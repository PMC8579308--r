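#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// 1D squared-distance transform along a sampled line with physical sample
// spacing `s` (Felzenszwalb & Huttenlocher lower-envelope-of-parabolas).
// f holds squared distances on input (INF where no feature), overwritten
// with the transformed values.
static void dt1d(std::vector<double>& f, double s) {
    const int n = (int)f.size();
    if (n == 0) return;
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<int> v(n);
    std::vector<double> z(n + 1), d(n);
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        if (f[q] == INF) continue;
        if (f[v[0]] == INF && k == 0 && v[0] != q) { v[0] = q; continue; }
        double xq = q * s;
        while (true) {
            double xv = v[k] * s;
            double sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
            if (sep <= z[k]) {
                --k;
            } else {
                ++k;
                v[k] = q;
                z[k] = sep;
                z[k + 1] = INF;
                break;
            }
        }
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * s;
        while (z[k + 1] < xq) ++k;
        double xv = v[k] * s;
        d[q] = (f[v[k]] == INF) ? INF : (xq - xv) * (xq - xv) + f[v[k]];
    }
    for (int q = 0; q < n; ++q) f[q] = d[q];
}

//' @noRd
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector feature, IntegerVector dims,
                        NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
    const double INF = std::numeric_limits<double>::infinity();
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = feature[i] ? 0.0 : INF;

    std::vector<double> line;
    // pass 1: x
    line.resize(nx);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y) {
            R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
            for (int x = 0; x < nx; ++x) line[x] = out[base + x];
            dt1d(line, dx);
            for (int x = 0; x < nx; ++x) out[base + x] = line[x];
        }
    // pass 2: y
    line.resize(ny);
    for (int z = 0; z < nz; ++z)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = (R_xlen_t)z * nx * ny + x;
            for (int y = 0; y < ny; ++y) line[y] = out[base + (R_xlen_t)y * nx];
            dt1d(line, dy);
            for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = line[y];
        }
    // pass 3: z
    line.resize(nz);
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = (R_xlen_t)y * nx + x;
            for (int z = 0; z < nz; ++z) line[z] = out[base + (R_xlen_t)z * nxy];
            dt1d(line, dz);
            for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nxy] = line[z];
        }
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = (out[i] == INF) ? NA_REAL : std::sqrt(out[i]);
    return out;
}

// Point-in-polygon (crossing number), boundary-inclusive: points lying on a
// polygon edge count as inside. Used to rasterize convex hulls the way
// region-properties "convex area" is defined (pixel centers in or on hull).
// [[Rcpp::export(name = ".points_in_polygon_cpp")]]
LogicalVector points_in_polygon_cpp(NumericVector px, NumericVector py,
                                    NumericVector vx, NumericVector vy) {
    const int n = px.size(), m = vx.size();
    LogicalVector res(n);
    const double eps = 1e-9;
    for (int i = 0; i < n; ++i) {
        const double x = px[i], y = py[i];
        bool inside = false, onedge = false;
        for (int j = 0, k = m - 1; j < m; k = j++) {
            const double xj = vx[j], yj = vy[j], xk = vx[k], yk = vy[k];
            // on-segment test
            double cross = (xk - xj) * (y - yj) - (yk - yj) * (x - xj);
            if (std::fabs(cross) < eps &&
                x >= std::fmin(xj, xk) - eps && x <= std::fmax(xj, xk) + eps &&
                y >= std::fmin(yj, yk) - eps && y <= std::fmax(yj, yk) + eps) {
                onedge = true;
                break;
            }
            if (((yj > y) != (yk > y)) &&
                (x < (xk - xj) * (y - yj) / (yk - yj) + xj))
                inside = !inside;
        }
        res[i] = inside || onedge;
    }
    return res;
}
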