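/* Void-map kernel: mark voxels whose center lies within reach of any bead.
 *
 * Voxel centers sit at origin + (i + 0.5) * voxel_size on each axis.
 * A voxel is blocked by bead j when the center-to-center distance is
 * strictly smaller than reach[j] = probe_radius + bead_radius[j].
 * Each bead only touches a bounded sub-block of the grid, so the loop is
 * O(n_beads * reach^3) instead of O(n_beads * n_voxels) while remaining
 * exactly equivalent to the all-pairs check.
 */
#include <math.h>
#include <R.h>
#include <Rinternals.h>

SEXP C_void_stamp(SEXP avail, SEXP dims, SEXP origin, SEXP voxel_size,
                  SEXP bx, SEXP by, SEXP bz, SEXP reach)
{
    const int nx = INTEGER(dims)[0];
    const int ny = INTEGER(dims)[1];
    const int nz = INTEGER(dims)[2];
    const double ox = REAL(origin)[0];
    const double oy = REAL(origin)[1];
    const double oz = REAL(origin)[2];
    const double h = REAL(voxel_size)[0];
    const R_xlen_t nb = XLENGTH(bx);
    const double *x = REAL(bx), *y = REAL(by), *z = REAL(bz), *rr = REAL(reach);

    SEXP out = PROTECT(duplicate(avail));
    int *a = LOGICAL(out);

    for (R_xlen_t j = 0; j < nb; j++) {
        const double r = rr[j];
        const double r2 = r * r;
        /* voxel-center index range potentially within reach */
        int i0 = (int) ceil((x[j] - r - ox) / h - 0.5);
        int i1 = (int) floor((x[j] + r - ox) / h - 0.5);
        int j0 = (int) ceil((y[j] - r - oy) / h - 0.5);
        int j1 = (int) floor((y[j] + r - oy) / h - 0.5);
        int k0 = (int) ceil((z[j] - r - oz) / h - 0.5);
        int k1 = (int) floor((z[j] + r - oz) / h - 0.5);
        if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
        if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
        if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
        for (int kk = k0; kk <= k1; kk++) {
            const double dz = oz + (kk + 0.5) * h - z[j];
            const double dz2 = dz * dz;
            if (dz2 >= r2) continue;
            for (int jj = j0; jj <= j1; jj++) {
                const double dy = oy + (jj + 0.5) * h - y[j];
                const double dyz2 = dz2 + dy * dy;
                if (dyz2 >= r2) continue;
                const R_xlen_t base = (R_xlen_t) kk * nx * ny
                                    + (R_xlen_t) jj * nx;
                for (int ii = i0; ii <= i1; ii++) {
                    const double dx = ox + (ii + 0.5) * h - x[j];
                    if (dx * dx + dyz2 < r2) a[base + ii] = 0;
                }
            }
        }
    }
    UNPROTECT(1);
    return out;
}
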