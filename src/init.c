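#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_h5_write(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_h5_ls(SEXP);
SEXP C_h5_read(SEXP, SEXP);
SEXP C_h5_read_attrs(SEXP);

static const R_CallMethodDef call_entries[] = {
    {"C_h5_write",      (DL_FUNC) &C_h5_write,      6},
    {"C_h5_ls",         (DL_FUNC) &C_h5_ls,         1},
    {"C_h5_read",       (DL_FUNC) &C_h5_read,       2},
    {"C_h5_read_attrs", (DL_FUNC) &C_h5_read_attrs, 1},
    {NULL, NULL, 0}
};

void R_init_msivae(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
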