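#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Matrix-free 7-point finite-volume operator for div(sigma grad phi) on a
// regular voxel grid. Face conductance between two conducting voxels is
// g = h * harm(sigma_i, sigma_j)  [S]  with h the voxel edge in metres and
// harm the harmonic mean (exact for layered media normal to the face).
// Voxels with sigma <= 0 are outside the conduction domain; all outer
// boundaries are insulating (Neumann) by construction of the stencil.

static inline double harm(double a, double b) { return 2.0 * a * b / (a + b); }

// precompute +x/+y/+z face conductances (0 across non-conducting faces)
static void face_conductances(const double* sig,
                              double* gx, double* gy, double* gz,
                              const int nx, const int ny, const int nz,
                              const double h)
{
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    const R_xlen_t n   = nxy * nz;
    for (R_xlen_t i = 0; i < n; ++i) { gx[i] = gy[i] = gz[i] = 0.0; }
    for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy) {
            const R_xlen_t base = (R_xlen_t)iy * nx + (R_xlen_t)iz * nxy;
            for (int ix = 0; ix < nx; ++ix) {
                const R_xlen_t i = base + ix;
                const double si = sig[i];
                if (si <= 0.0) continue;
                if (ix + 1 < nx && sig[i + 1] > 0.0)
                    gx[i] = h * harm(si, sig[i + 1]);
                if (iy + 1 < ny && sig[i + nx] > 0.0)
                    gy[i] = h * harm(si, sig[i + nx]);
                if (iz + 1 < nz && sig[i + nxy] > 0.0)
                    gz[i] = h * harm(si, sig[i + nxy]);
            }
        }
}

// y = A x using precomputed face conductances
static void apply_A(const double* gx, const double* gy, const double* gz,
                    const double* x, double* y,
                    const int nx, const int ny, const int nz)
{
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    const R_xlen_t n   = nxy * nz;
    for (R_xlen_t i = 0; i < n; ++i) y[i] = 0.0;
    for (int iz = 0; iz < nz; ++iz)
        for (int iy = 0; iy < ny; ++iy) {
            const R_xlen_t base = (R_xlen_t)iy * nx + (R_xlen_t)iz * nxy;
            for (int ix = 0; ix < nx; ++ix) {
                const R_xlen_t i = base + ix;
                const double cx = gx[i], cy = gy[i], cz = gz[i];
                if (cx != 0.0) {
                    const double d = cx * (x[i] - x[i + 1]);
                    y[i] += d; y[i + 1] -= d;
                }
                if (cy != 0.0) {
                    const double d = cy * (x[i] - x[i + nx]);
                    y[i] += d; y[i + nx] -= d;
                }
                if (cz != 0.0) {
                    const double d = cz * (x[i] - x[i + nxy]);
                    y[i] += d; y[i + nxy] -= d;
                }
            }
        }
}

// [[Rcpp::export(name = ".stencil_apply")]]
NumericVector stencil_apply(NumericVector sigma, NumericVector x,
                            IntegerVector dims, double h)
{
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = sigma.size();
    std::vector<double> gx(n), gy(n), gz(n);
    face_conductances(REAL(sigma), gx.data(), gy.data(), gz.data(),
                      nx, ny, nz, h);
    NumericVector y(n);
    apply_A(gx.data(), gy.data(), gz.data(), REAL(x), REAL(y), nx, ny, nz);
    return y;
}

// Jacobi-preconditioned conjugate gradients on the (consistent, singular)
// pure-Neumann system A phi = b. The constant vector spans the null space;
// A * const == 0 exactly in floating point and sum(b) == 0 is enforced by
// the caller, so CG stays on the range of A. The gauge (zero mean over the
// conduction domain) is applied to the returned potential.
// [[Rcpp::export(name = ".pcg_solve")]]
List pcg_solve(NumericVector sigma, NumericVector b, IntegerVector dims,
               double h, double tol, int maxit)
{
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    const double* sig = REAL(sigma);
    const double* bp  = REAL(b);

    NumericVector phi(n);
    double* x = REAL(phi);
    std::vector<double> gx(n), gy(n), gz(n);
    face_conductances(sig, gx.data(), gy.data(), gz.data(), nx, ny, nz, h);

    std::vector<double> r(n), z(n), p(n), Ap(n), dinv(n);
    {   // diagonal of A (sum of incident face conductances)
        std::vector<double>& dia = Ap;  // reuse scratch
        std::fill(dia.begin(), dia.end(), 0.0);
        const R_xlen_t nxy = (R_xlen_t)nx * ny;
        for (R_xlen_t i = 0; i < n; ++i) {
            if (gx[i] != 0.0) { dia[i] += gx[i]; dia[i + 1]   += gx[i]; }
            if (gy[i] != 0.0) { dia[i] += gy[i]; dia[i + nx]  += gy[i]; }
            if (gz[i] != 0.0) { dia[i] += gz[i]; dia[i + nxy] += gz[i]; }
        }
        for (R_xlen_t i = 0; i < n; ++i)
            dinv[i] = (dia[i] > 0.0) ? 1.0 / dia[i] : 0.0;
    }

    double normb2 = 0.0;
    R_xlen_t nact = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        r[i] = bp[i];
        normb2 += bp[i] * bp[i];
        if (sig[i] > 0.0) ++nact;
    }
    if (nact == 0) stop("conduction domain is empty");
    const double normb = std::sqrt(normb2);
    if (normb == 0.0)
        return List::create(_["phi"] = phi, _["iterations"] = 0,
                            _["relres"] = 0.0, _["converged"] = true);

    double rz = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
        z[i] = r[i] * dinv[i];
        p[i] = z[i];
        rz += r[i] * z[i];
    }

    double relres = 1.0;
    int it = 0;
    bool converged = false;
    for (it = 1; it <= maxit; ++it) {
        apply_A(gx.data(), gy.data(), gz.data(), p.data(), Ap.data(),
                nx, ny, nz);
        double pAp = 0.0;
        for (R_xlen_t i = 0; i < n; ++i) pAp += p[i] * Ap[i];
        if (pAp <= 0.0) break;  // breakdown (null-space drift)
        const double alpha = rz / pAp;
        double rr = 0.0;
        for (R_xlen_t i = 0; i < n; ++i) {
            x[i] += alpha * p[i];
            r[i] -= alpha * Ap[i];
            rr   += r[i] * r[i];
        }
        relres = std::sqrt(rr) / normb;
        if (relres <= tol) { converged = true; break; }
        double rz_new = 0.0;
        for (R_xlen_t i = 0; i < n; ++i) {
            z[i] = r[i] * dinv[i];
            rz_new += r[i] * z[i];
        }
        const double beta = rz_new / rz;
        rz = rz_new;
        for (R_xlen_t i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
        if (it % 256 == 0) Rcpp::checkUserInterrupt();
    }

    // gauge: zero mean over the conduction domain
    double mean = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) if (sig[i] > 0.0) mean += x[i];
    mean /= (double)nact;
    for (R_xlen_t i = 0; i < n; ++i) x[i] = (sig[i] > 0.0) ? x[i] - mean : NA_REAL;

    return List::create(_["phi"] = phi, _["iterations"] = it,
                        _["relres"] = relres, _["converged"] = converged);
}
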