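#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel grids are column-major (R array layout), voxel indices 0-based.
// M is the top 3 rows of a 4x4 affine mapping output voxel indices to
// source voxel indices (all geometry composition happens in R).

static inline double trilinear(const double *src, int nx, int ny, int nz,
                               double x, double y, double z, bool *ok) {
    const double eps = 1e-9;
    if (!std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z)) {
        *ok = false;
        return 0.0;
    }
    if (x < -eps || y < -eps || z < -eps ||
        x > nx - 1 + eps || y > ny - 1 + eps || z > nz - 1 + eps) {
        *ok = false;
        return 0.0;
    }
    *ok = true;
    if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
    if (x > nx - 1) x = nx - 1;
    if (y > ny - 1) y = ny - 1;
    if (z > nz - 1) z = nz - 1;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx - 2 < 0 ? 0 : nx - 2;
    if (y0 > ny - 2) y0 = ny - 2 < 0 ? 0 : ny - 2;
    if (z0 > nz - 2) z0 = nz - 2 < 0 ? 0 : nz - 2;
    int x1 = x0 + 1 < nx ? x0 + 1 : x0;
    int y1 = y0 + 1 < ny ? y0 + 1 : y0;
    int z1 = z0 + 1 < nz ? z0 + 1 : z0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    size_t sxy = (size_t)nx * ny;
    #define S(i,j,k) src[(size_t)(i) + (size_t)(j)*nx + (size_t)(k)*sxy]
    double c00 = S(x0,y0,z0)*(1-fx) + S(x1,y0,z0)*fx;
    double c10 = S(x0,y1,z0)*(1-fx) + S(x1,y1,z0)*fx;
    double c01 = S(x0,y0,z1)*(1-fx) + S(x1,y0,z1)*fx;
    double c11 = S(x0,y1,z1)*(1-fx) + S(x1,y1,z1)*fx;
    #undef S
    double c0 = c00*(1-fy) + c10*fy;
    double c1 = c01*(1-fy) + c11*fy;
    return c0*(1-fz) + c1*fz;
}

static inline double nearestv(const double *src, int nx, int ny, int nz,
                              double x, double y, double z, bool *ok) {
    if (!std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z)) {
        *ok = false;
        return 0.0;
    }
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
        *ok = false;
        return 0.0;
    }
    *ok = true;
    return src[(size_t)i + (size_t)j*nx + (size_t)k*(size_t)nx*ny];
}

// [[Rcpp::export]]
List cpp_resample_affine(NumericVector src, IntegerVector sdim,
                         IntegerVector odim, NumericMatrix M, int nearest) {
    int nx = sdim[0], ny = sdim[1], nz = sdim[2];
    int ox = odim[0], oy = odim[1], oz = odim[2];
    size_t n = (size_t)ox * oy * oz;
    NumericVector out(n);
    LogicalVector oof(n);
    const double *s = src.begin();
    double m00=M(0,0), m01=M(0,1), m02=M(0,2), m03=M(0,3);
    double m10=M(1,0), m11=M(1,1), m12=M(1,2), m13=M(1,3);
    double m20=M(2,0), m21=M(2,1), m22=M(2,2), m23=M(2,3);
    size_t idx = 0;
    for (int k = 0; k < oz; ++k) {
        for (int j = 0; j < oy; ++j) {
            double xj = m01*j + m03 + m02*k;
            double yj = m11*j + m13 + m12*k;
            double zj = m21*j + m23 + m22*k;
            for (int i = 0; i < ox; ++i, ++idx) {
                double x = m00*i + xj, y = m10*i + yj, z = m20*i + zj;
                bool ok;
                double v = nearest ? nearestv(s, nx, ny, nz, x, y, z, &ok)
                                   : trilinear(s, nx, ny, nz, x, y, z, &ok);
                out[idx] = v;
                oof[idx] = !ok;
            }
        }
    }
    return List::create(_["data"] = out, _["oof"] = oof);
}

// 1 - NCC between fixed and moving-resampled-through-M, over in-field voxels.
// [[Rcpp::export]]
double cpp_cost_ncc(NumericVector mov, IntegerVector mdim,
                    NumericVector fix, IntegerVector fdim, NumericMatrix M,
                    int stride) {
    int nx = mdim[0], ny = mdim[1], nz = mdim[2];
    int ox = fdim[0], oy = fdim[1], oz = fdim[2];
    const double *s = mov.begin();
    const double *f = fix.begin();
    double m00=M(0,0), m01=M(0,1), m02=M(0,2), m03=M(0,3);
    double m10=M(1,0), m11=M(1,1), m12=M(1,2), m13=M(1,3);
    double m20=M(2,0), m21=M(2,1), m22=M(2,2), m23=M(2,3);
    if (stride < 1) stride = 1;
    double sa=0, sb=0, saa=0, sbb=0, sab=0;
    size_t cnt = 0;
    for (int k = 0; k < oz; k += stride) {
        for (int j = 0; j < oy; j += stride) {
            double xj = m01*j + m03 + m02*k;
            double yj = m11*j + m13 + m12*k;
            double zj = m21*j + m23 + m22*k;
            size_t row = (size_t)j * ox + (size_t)k * ox * oy;
            for (int i = 0; i < ox; i += stride) {
                double x = m00*i + xj, y = m10*i + yj, z = m20*i + zj;
                bool ok;
                double v = trilinear(s, nx, ny, nz, x, y, z, &ok);
                if (!ok) continue;
                double a = f[row + i];
                sa += a; sb += v; saa += a*a; sbb += v*v; sab += a*v;
                ++cnt;
            }
        }
    }
    if (cnt < 27) return 2.0;  // essentially no overlap
    double n = (double)cnt;
    double va = saa - sa*sa/n, vb = sbb - sb*sb/n, cab = sab - sa*sb/n;
    if (va <= 0 || vb <= 0) return 2.0;
    double ncc = cab / std::sqrt(va * vb);
    return 1.0 - ncc;
}

// Negative mutual information, joint histogram with linear (partial-volume)
// weighting of the interpolated moving value so the cost is continuous in M.
// [[Rcpp::export]]
double cpp_cost_mi(NumericVector mov, IntegerVector mdim,
                   NumericVector fix, IntegerVector fdim, NumericMatrix M,
                   int nbins, double flo, double fhi, double mlo, double mhi,
                   int stride, int normalized) {
    int nx = mdim[0], ny = mdim[1], nz = mdim[2];
    int ox = fdim[0], oy = fdim[1], oz = fdim[2];
    const double *s = mov.begin();
    const double *f = fix.begin();
    double m00=M(0,0), m01=M(0,1), m02=M(0,2), m03=M(0,3);
    double m10=M(1,0), m11=M(1,1), m12=M(1,2), m13=M(1,3);
    double m20=M(2,0), m21=M(2,1), m22=M(2,2), m23=M(2,3);
    std::vector<double> H((size_t)nbins * nbins, 0.0);
    double fr = (fhi > flo) ? (nbins - 1e-9) / (fhi - flo) : 0.0;
    double mr = (mhi > mlo) ? (nbins - 1.0)  / (mhi - mlo) : 0.0;
    double total = 0.0;
    if (stride < 1) stride = 1;
    for (int k = 0; k < oz; k += stride) {
        for (int j = 0; j < oy; j += stride) {
            double xj = m01*j + m03 + m02*k;
            double yj = m11*j + m13 + m12*k;
            double zj = m21*j + m23 + m22*k;
            size_t row = (size_t)j * ox + (size_t)k * ox * oy;
            for (int i = 0; i < ox; i += stride) {
                double x = m00*i + xj, y = m10*i + yj, z = m20*i + zj;
                bool ok;
                double v = trilinear(s, nx, ny, nz, x, y, z, &ok);
                if (!ok) continue;
                int bf = (int)((f[row + i] - flo) * fr);
                if (bf < 0) bf = 0; if (bf >= nbins) bf = nbins - 1;
                double bm = (v - mlo) * mr;
                if (bm < 0) bm = 0; if (bm > nbins - 1) bm = nbins - 1;
                int b0 = (int)bm;
                double w = bm - b0;
                int b1 = b0 + 1 < nbins ? b0 + 1 : b0;
                H[(size_t)bf * nbins + b0] += 1.0 - w;
                H[(size_t)bf * nbins + b1] += w;
                total += 1.0;
            }
        }
    }
    if (total < 27) return 2.0;
    std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
    for (int a = 0; a < nbins; ++a)
        for (int b = 0; b < nbins; ++b) {
            double p = H[(size_t)a * nbins + b] / total;
            pf[a] += p; pm[b] += p;
        }
    double hj = 0.0, hf = 0.0, hm = 0.0;
    for (int a = 0; a < nbins; ++a) {
        if (pf[a] > 0) hf -= pf[a] * std::log(pf[a]);
        if (pm[a] > 0) hm -= pm[a] * std::log(pm[a]);
        for (int b = 0; b < nbins; ++b) {
            double p = H[(size_t)a * nbins + b] / total;
            if (p > 0) hj -= p * std::log(p);
        }
    }
    if (normalized) {
        // Studholme's overlap-invariant NMI = (H(F) + H(M)) / H(F, M)
        if (hj <= 0) return 2.0;
        return -(hf + hm) / hj;
    }
    return -(hf + hm - hj);
}

// 1 - correlation ratio eta^2 (Roche): how far the interpolated moving
// intensity is a function of the fixed intensity, binned over the fixed
// image only -- smooth in the transform since the moving value is never
// binned.
// [[Rcpp::export]]
double cpp_cost_cr(NumericVector mov, IntegerVector mdim,
                   NumericVector fix, IntegerVector fdim, NumericMatrix M,
                   int nbins, double flo, double fhi, int stride) {
    int nx = mdim[0], ny = mdim[1], nz = mdim[2];
    int ox = fdim[0], oy = fdim[1], oz = fdim[2];
    const double *s = mov.begin();
    const double *f = fix.begin();
    double m00=M(0,0), m01=M(0,1), m02=M(0,2), m03=M(0,3);
    double m10=M(1,0), m11=M(1,1), m12=M(1,2), m13=M(1,3);
    double m20=M(2,0), m21=M(2,1), m22=M(2,2), m23=M(2,3);
    if (stride < 1) stride = 1;
    std::vector<double> nb(nbins, 0.0), sb(nbins, 0.0);
    double fr = (fhi > flo) ? (nbins - 1e-9) / (fhi - flo) : 0.0;
    double sv = 0, svv = 0, total = 0;
    for (int k = 0; k < oz; k += stride) {
        for (int j = 0; j < oy; j += stride) {
            double xj = m01*j + m03 + m02*k;
            double yj = m11*j + m13 + m12*k;
            double zj = m21*j + m23 + m22*k;
            size_t row = (size_t)j * ox + (size_t)k * ox * oy;
            for (int i = 0; i < ox; i += stride) {
                double x = m00*i + xj, y = m10*i + yj, z = m20*i + zj;
                bool ok;
                double v = trilinear(s, nx, ny, nz, x, y, z, &ok);
                if (!ok) continue;
                int bf = (int)((f[row + i] - flo) * fr);
                if (bf < 0) bf = 0; if (bf >= nbins) bf = nbins - 1;
                nb[bf] += 1.0; sb[bf] += v;
                sv += v; svv += v * v;
                total += 1.0;
            }
        }
    }
    if (total < 27) return 2.0;
    double var_tot = svv - sv * sv / total;
    if (var_tot <= 0) return 2.0;
    double between = 0.0;
    for (int b = 0; b < nbins; ++b)
        if (nb[b] > 0) between += sb[b] * sb[b] / nb[b];
    between -= sv * sv / total;
    return 1.0 - between / var_tot;
}

// Separable Gaussian blur, sigma in voxels per axis, truncated at 3 sigma.
// [[Rcpp::export]]
NumericVector cpp_blur3d(NumericVector src, IntegerVector dim,
                         NumericVector sigma) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    size_t n = (size_t)nx * ny * nz, sxy = (size_t)nx * ny;
    std::vector<double> a(src.begin(), src.end()), b(n);
    int strides[3] = {1, nx, (int)sxy};
    int dims[3] = {nx, ny, nz};
    for (int ax = 0; ax < 3; ++ax) {
        double sg = sigma[ax];
        if (sg <= 0) continue;
        int r = (int)std::ceil(3.0 * sg);
        std::vector<double> kern(2 * r + 1);
        double ks = 0;
        for (int t = -r; t <= r; ++t) {
            kern[t + r] = std::exp(-0.5 * t * t / (sg * sg));
            ks += kern[t + r];
        }
        for (double &kk : kern) kk /= ks;
        int d = dims[ax], st = strides[ax];
        // iterate over all lines along axis ax
        for (int k = 0; k < (ax == 2 ? 1 : nz); ++k) {
            for (int j = 0; j < (ax == 1 ? 1 : ny); ++j) {
                for (int i = 0; i < (ax == 0 ? 1 : nx); ++i) {
                    size_t base = (size_t)i + (size_t)j * nx + (size_t)k * sxy;
                    for (int t = 0; t < d; ++t) {
                        double acc = 0, wacc = 0;
                        for (int u = -r; u <= r; ++u) {
                            int tu = t + u;
                            if (tu < 0 || tu >= d) continue;  // renormalized edge
                            double w = kern[u + r];
                            acc += w * a[base + (size_t)tu * st];
                            wacc += w;
                        }
                        b[base + (size_t)t * st] = acc / wacc;
                    }
                }
            }
        }
        std::swap(a, b);
    }
    return NumericVector(a.begin(), a.end());
}

// Block-mean downsampling by an integer factor per axis (trailing partial
// blocks averaged over the voxels present).
// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector src, IntegerVector dim,
                             IntegerVector fac) {
    int nx = dim[0], ny = dim[1], nz = dim[2];
    int fx = fac[0], fy = fac[1], fz = fac[2];
    int ox = (nx + fx - 1) / fx, oy = (ny + fy - 1) / fy, oz = (nz + fz - 1) / fz;
    NumericVector out((size_t)ox * oy * oz);
    const double *s = src.begin();
    size_t sxy = (size_t)nx * ny;
    size_t idx = 0;
    for (int k = 0; k < oz; ++k) {
        int z0 = k * fz, z1 = std::min(z0 + fz, nz);
        for (int j = 0; j < oy; ++j) {
            int y0 = j * fy, y1 = std::min(y0 + fy, ny);
            for (int i = 0; i < ox; ++i, ++idx) {
                int x0 = i * fx, x1 = std::min(x0 + fx, nx);
                double acc = 0; int cnt = 0;
                for (int z = z0; z < z1; ++z)
                    for (int y = y0; y < y1; ++y)
                        for (int x = x0; x < x1; ++x) {
                            acc += s[(size_t)x + (size_t)y*nx + (size_t)z*sxy];
                            ++cnt;
                        }
                out[idx] = acc / cnt;
            }
        }
    }
    out.attr("odim") = IntegerVector::create(ox, oy, oz);
    return out;
}
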