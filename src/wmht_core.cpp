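#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Voxel-wise GLCM texture maps over 3x3 axial patches.
//
// q: quantized volume (dim nx x ny x nz), in-brain values 1..N, background 0.
// For every voxel with a full in-plane 3x3 neighbourhood, the 8 directional
// co-occurrence tables (E, W, N, S and the four diagonals, distance 1) are
// accumulated over all ordered voxel pairs lying fully inside the patch,
// pairs touching background excluded, then normalized and reduced to the
// four Haralick features. Entropy uses the natural log; 0*log(0) := 0.
// Voxels on slice borders or whose patch yields no countable pair are
// flagged invalid (NA in the maps, FALSE in the valid mask).
// [[Rcpp::export]]
List cpp_texture_maps(IntegerVector q, int N) {
    IntegerVector dims = q.attr("dim");
    if (dims.size() != 3) stop("quantized volume must be a 3D array");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;

    NumericVector contrast(nvox, NA_REAL), energy(nvox, NA_REAL),
        entropy(nvox, NA_REAL), homog(nvox, NA_REAL);
    LogicalVector valid(nvox, false);

    const int dxs[8] = { 1, -1, 0,  0, 1, -1,  1, -1};
    const int dys[8] = { 0,  0, 1, -1, 1, -1, -1,  1};

    std::vector<double> P((size_t)N * N);

    for (int z = 0; z < nz; ++z) {
        const R_xlen_t zoff = (R_xlen_t)z * nx * ny;
        for (int y = 1; y < ny - 1; ++y) {
            for (int x = 1; x < nx - 1; ++x) {
                std::fill(P.begin(), P.end(), 0.0);
                double total = 0.0;
                for (int d = 0; d < 8; ++d) {
                    const int dx = dxs[d], dy = dys[d];
                    // start-voxel range such that both ends stay in-patch
                    const int x0 = std::max(x - 1, x - 1 - dx);
                    const int x1 = std::min(x + 1, x + 1 - dx);
                    const int y0 = std::max(y - 1, y - 1 - dy);
                    const int y1 = std::min(y + 1, y + 1 - dy);
                    for (int py = y0; py <= y1; ++py) {
                        for (int px = x0; px <= x1; ++px) {
                            int a = q[zoff + px + (R_xlen_t)py * nx];
                            int b = q[zoff + (px + dx) + (R_xlen_t)(py + dy) * nx];
                            if (a > 0 && b > 0) {
                                P[(size_t)(a - 1) * N + (b - 1)] += 1.0;
                                total += 1.0;
                            }
                        }
                    }
                }
                if (total <= 0.0) continue;
                double con = 0.0, ene = 0.0, ent = 0.0, hom = 0.0;
                for (int i = 0; i < N; ++i) {
                    for (int j = 0; j < N; ++j) {
                        double p = P[(size_t)i * N + j] / total;
                        if (p > 0.0) {
                            con += p * (i - j) * (i - j);
                            ene += p * p;
                            ent -= p * std::log(p);
                            hom += p / (1.0 + std::abs(i - j));
                        }
                    }
                }
                R_xlen_t idx = zoff + x + (R_xlen_t)y * nx;
                contrast[idx] = con;
                energy[idx]   = ene;
                entropy[idx]  = ent;
                homog[idx]    = hom;
                valid[idx]    = true;
            }
        }
    }

    contrast.attr("dim") = dims; energy.attr("dim") = dims;
    entropy.attr("dim") = dims;  homog.attr("dim") = dims;
    valid.attr("dim") = dims;
    return List::create(_["contrast"] = contrast, _["energy"] = energy,
                        _["entropy"] = entropy, _["homogeneity"] = homog,
                        _["valid"] = valid);
}

// Felzenszwalb & Huttenlocher 1D squared distance transform.
static void edt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
    std::vector<int> v(n);
    std::vector<double> zed(n + 1);
    int k = 0;
    v[0] = 0;
    zed[0] = -std::numeric_limits<double>::infinity();
    zed[1] =  std::numeric_limits<double>::infinity();
    for (int qi = 1; qi < n; ++qi) {
        double s;
        while (true) {
            s = ((f[qi] + (double)qi * qi) - (f[v[k]] + (double)v[k] * v[k])) /
                (2.0 * qi - 2.0 * v[k]);
            if (s <= zed[k]) { --k; } else break;
        }
        ++k;
        v[k] = qi;
        zed[k] = s;
        zed[k + 1] = std::numeric_limits<double>::infinity();
    }
    k = 0;
    for (int qi = 0; qi < n; ++qi) {
        while (zed[k + 1] < qi) ++k;
        double dq = qi - v[k];
        d[qi] = dq * dq + f[v[k]];
    }
}

// Exact 2D squared Euclidean distance transform (pixel units) to the
// nearest nonzero pixel of a binary slice. Empty slice -> all Inf.
// Column pass: 1D nearest-set distance by two linear sweeps (finite
// sentinel for empty columns keeps the row-pass envelope well defined,
// since the parabola algebra cannot mix infinities); row pass: lower
// envelope of parabolas.
// [[Rcpp::export]]
NumericMatrix cpp_sedt2d(IntegerMatrix mask) {
    const int nx = mask.nrow(), ny = mask.ncol();
    const double INF = std::numeric_limits<double>::infinity();
    const int BIG = nx + ny + 4;          // > any attainable 1D distance
    const double SENT = 1e12;             // finite stand-in for "no pixel"
    NumericMatrix out(nx, ny);

    bool slice_empty = true;
    for (int yi = 0; yi < ny && slice_empty; ++yi)
        for (int xi = 0; xi < nx; ++xi)
            if (mask(xi, yi)) { slice_empty = false; break; }
    if (slice_empty) {
        std::fill(out.begin(), out.end(), INF);
        return out;
    }

    std::vector<int> run(nx);
    for (int yi = 0; yi < ny; ++yi) {
        int r = BIG;
        for (int xi = 0; xi < nx; ++xi) {
            r = mask(xi, yi) ? 0 : (r < BIG ? r + 1 : BIG);
            run[xi] = r;
        }
        r = BIG;
        for (int xi = nx - 1; xi >= 0; --xi) {
            r = mask(xi, yi) ? 0 : (r < BIG ? r + 1 : BIG);
            if (r < run[xi]) run[xi] = r;
            out(xi, yi) = (run[xi] >= BIG) ? SENT
                          : (double)run[xi] * run[xi];
        }
    }

    std::vector<double> f(ny), d(ny);
    for (int xi = 0; xi < nx; ++xi) {
        for (int yi = 0; yi < ny; ++yi) f[yi] = out(xi, yi);
        edt1d(f, d, ny);
        for (int yi = 0; yi < ny; ++yi) out(xi, yi) = d[yi];
    }
    return out;
}

// 26-connectivity 3D connected components of a binary volume.
// Returns integer labels (0 = background), labelled in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask) {
    IntegerVector dims = mask.attr("dim");
    if (dims.size() != 3) stop("mask must be a 3D array");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
    IntegerVector labels(nvox, 0);
    int next = 0;
    std::queue<R_xlen_t> bfs;
    for (R_xlen_t s = 0; s < nvox; ++s) {
        if (mask[s] == 0 || labels[s] != 0) continue;
        labels[s] = ++next;
        bfs.push(s);
        while (!bfs.empty()) {
            R_xlen_t cur = bfs.front(); bfs.pop();
            int cz = cur / ((R_xlen_t)nx * ny);
            int rem = cur - (R_xlen_t)cz * nx * ny;
            int cy = rem / nx, cx = rem % nx;
            for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int px = cx + dx, py = cy + dy, pz = cz + dz;
                if (px < 0 || py < 0 || pz < 0 || px >= nx || py >= ny || pz >= nz)
                    continue;
                R_xlen_t idx = px + (R_xlen_t)py * nx + (R_xlen_t)pz * nx * ny;
                if (mask[idx] != 0 && labels[idx] == 0) {
                    labels[idx] = next;
                    bfs.push(idx);
                }
            }
        }
    }
    labels.attr("dim") = dims;
    return labels;
}
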