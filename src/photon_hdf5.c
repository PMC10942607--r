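/* Minimal Photon-HDF5 reader/writer backed by libhdf5.
 *
 * Covers the subset of the layout the pipeline uses:
 *   /description                     (string scalar)
 *   /acquisition_duration            (double scalar, seconds)
 *   /photon_data/timestamps          (int64, ticks)
 *   /photon_data/timestamps_specs/timestamps_unit (double scalar, s/tick)
 *   /photon_data/detectors           (uint8)
 *   /photon_data/nanotimes           (uint16 TCSPC bins, optional)
 *   /photon_data/nanotimes_specs/tcspc_unit (double scalar, s/bin, optional)
 *
 * Timestamps cross the R boundary as doubles; exact for ticks < 2^53.
 */
#include <hdf5.h>
#include <stdlib.h>
#include <string.h>
#include <R.h>
#include <Rinternals.h>

static void write_scalar_double(hid_t loc, const char *name, double value)
{
    hid_t sp = H5Screate(H5S_SCALAR);
    hid_t ds = H5Dcreate2(loc, name, H5T_NATIVE_DOUBLE, sp,
                          H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    if (ds < 0) { H5Sclose(sp); error("HDF5: cannot create dataset '%s'", name); }
    H5Dwrite(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, &value);
    H5Dclose(ds);
    H5Sclose(sp);
}

static void write_scalar_string(hid_t loc, const char *name, const char *value)
{
    hid_t st = H5Tcopy(H5T_C_S1);
    H5Tset_size(st, strlen(value) + 1);
    hid_t sp = H5Screate(H5S_SCALAR);
    hid_t ds = H5Dcreate2(loc, name, st, sp,
                          H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    if (ds >= 0) {
        H5Dwrite(ds, st, H5S_ALL, H5S_ALL, H5P_DEFAULT, value);
        H5Dclose(ds);
    }
    H5Sclose(sp);
    H5Tclose(st);
}

SEXP C_phdf5_write(SEXP path, SEXP timestamps, SEXP detectors, SEXP nanotimes,
                   SEXP timestamps_unit, SEXP tcspc_unit,
                   SEXP acquisition_duration, SEXP description)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    R_xlen_t n = XLENGTH(timestamps);
    hid_t file = H5Fcreate(fname, H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
    if (file < 0) error("HDF5: cannot create file '%s'", fname);

    write_scalar_string(file, "description", CHAR(STRING_ELT(description, 0)));
    write_scalar_double(file, "acquisition_duration",
                        REAL(acquisition_duration)[0]);

    hid_t pd = H5Gcreate2(file, "photon_data", H5P_DEFAULT, H5P_DEFAULT,
                          H5P_DEFAULT);
    hsize_t dims[1] = { (hsize_t) n };
    hid_t sp = H5Screate_simple(1, dims, NULL);

    /* timestamps as int64 ticks */
    long long *ts = (long long *) R_alloc(n, sizeof(long long));
    const double *tsd = REAL(timestamps);
    for (R_xlen_t i = 0; i < n; i++) ts[i] = (long long) tsd[i];
    hid_t ds = H5Dcreate2(pd, "timestamps", H5T_STD_I64LE, sp,
                          H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    H5Dwrite(ds, H5T_NATIVE_LLONG, H5S_ALL, H5S_ALL, H5P_DEFAULT, ts);
    H5Dclose(ds);

    /* detectors as uint8 */
    unsigned char *det = (unsigned char *) R_alloc(n, sizeof(unsigned char));
    const int *deti = INTEGER(detectors);
    for (R_xlen_t i = 0; i < n; i++) det[i] = (unsigned char) deti[i];
    ds = H5Dcreate2(pd, "detectors", H5T_STD_U8LE, sp,
                    H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    H5Dwrite(ds, H5T_NATIVE_UCHAR, H5S_ALL, H5S_ALL, H5P_DEFAULT, det);
    H5Dclose(ds);

    hid_t specs = H5Gcreate2(pd, "timestamps_specs", H5P_DEFAULT, H5P_DEFAULT,
                             H5P_DEFAULT);
    write_scalar_double(specs, "timestamps_unit", REAL(timestamps_unit)[0]);
    H5Gclose(specs);

    if (!isNull(nanotimes) && XLENGTH(nanotimes) == n) {
        unsigned short *nt = (unsigned short *) R_alloc(n, sizeof(unsigned short));
        const double *ntd = REAL(nanotimes);
        for (R_xlen_t i = 0; i < n; i++) nt[i] = (unsigned short) ntd[i];
        ds = H5Dcreate2(pd, "nanotimes", H5T_STD_U16LE, sp,
                        H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
        H5Dwrite(ds, H5T_NATIVE_USHORT, H5S_ALL, H5S_ALL, H5P_DEFAULT, nt);
        H5Dclose(ds);
        hid_t nspecs = H5Gcreate2(pd, "nanotimes_specs", H5P_DEFAULT,
                                  H5P_DEFAULT, H5P_DEFAULT);
        write_scalar_double(nspecs, "tcspc_unit", REAL(tcspc_unit)[0]);
        H5Gclose(nspecs);
    }

    H5Sclose(sp);
    H5Gclose(pd);
    H5Fclose(file);
    return R_NilValue;
}

static int link_exists(hid_t file, const char *path)
{
    /* H5Lexists on a nested path requires each ancestor to exist */
    char buf[256];
    size_t len = strlen(path);
    if (len >= sizeof(buf)) return 0;
    strcpy(buf, path);
    for (size_t i = 1; i < len; i++) {
        if (buf[i] == '/') {
            buf[i] = '\0';
            if (H5Lexists(file, buf, H5P_DEFAULT) <= 0) return 0;
            buf[i] = '/';
        }
    }
    return H5Lexists(file, path, H5P_DEFAULT) > 0;
}

static SEXP read_dataset_double(hid_t file, const char *path)
{
    hid_t ds = H5Dopen2(file, path, H5P_DEFAULT);
    if (ds < 0) error("HDF5: cannot open dataset '%s'", path);
    hid_t sp = H5Dget_space(ds);
    hssize_t n = H5Sget_simple_extent_npoints(sp);
    SEXP out = PROTECT(allocVector(REALSXP, (R_xlen_t) n));
    H5Dread(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(out));
    H5Sclose(sp);
    H5Dclose(ds);
    UNPROTECT(1);
    return out;
}

SEXP C_phdf5_read(SEXP path)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    hid_t file = H5Fopen(fname, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) error("HDF5: cannot open file '%s'", fname);

    static const char *mandatory[] = {
        "/photon_data",
        "/photon_data/timestamps",
        "/photon_data/timestamps_specs/timestamps_unit",
        "/acquisition_duration"
    };
    for (int i = 0; i < 4; i++) {
        if (!link_exists(file, mandatory[i])) {
            H5Fclose(file);
            error("Photon-HDF5: mandatory group or dataset '%s' is missing",
                  mandatory[i]);
        }
    }

    SEXP out = PROTECT(allocVector(VECSXP, 6));
    SEXP names = PROTECT(allocVector(STRSXP, 6));
    const char *nm[] = { "timestamps", "detectors", "nanotimes",
                         "timestamps_unit", "tcspc_unit",
                         "acquisition_duration" };
    for (int i = 0; i < 6; i++) SET_STRING_ELT(names, i, mkChar(nm[i]));
    setAttrib(out, R_NamesSymbol, names);

    SET_VECTOR_ELT(out, 0, read_dataset_double(file, "/photon_data/timestamps"));
    if (link_exists(file, "/photon_data/detectors"))
        SET_VECTOR_ELT(out, 1, read_dataset_double(file, "/photon_data/detectors"));
    else
        SET_VECTOR_ELT(out, 1, R_NilValue);
    if (link_exists(file, "/photon_data/nanotimes"))
        SET_VECTOR_ELT(out, 2, read_dataset_double(file, "/photon_data/nanotimes"));
    else
        SET_VECTOR_ELT(out, 2, R_NilValue);
    SET_VECTOR_ELT(out, 3,
        read_dataset_double(file, "/photon_data/timestamps_specs/timestamps_unit"));
    if (link_exists(file, "/photon_data/nanotimes_specs/tcspc_unit"))
        SET_VECTOR_ELT(out, 4,
            read_dataset_double(file, "/photon_data/nanotimes_specs/tcspc_unit"));
    else
        SET_VECTOR_ELT(out, 4, R_NilValue);
    SET_VECTOR_ELT(out, 5, read_dataset_double(file, "/acquisition_duration"));

    H5Fclose(file);
    UNPROTECT(2);
    return out;
}
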