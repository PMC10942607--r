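#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_phdf5_write(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_phdf5_read(SEXP);
SEXP C_void_stamp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"C_phdf5_write", (DL_FUNC) &C_phdf5_write, 8},
    {"C_phdf5_read",  (DL_FUNC) &C_phdf5_read,  1},
    {"C_void_stamp",  (DL_FUNC) &C_void_stamp,  8},
    {NULL, NULL, 0}
};

void R_init_npcmimic(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
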