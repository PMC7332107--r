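#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void mxpol_initmod(void (*odeparms)(int *, double *));
void mxpol_rhs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip);
SEXP mxpol_ks2d_d(SEXP xa, SEXP ya, SEXP xb, SEXP yb);

static const R_CMethodDef CEntries[] = {
    {"mxpol_initmod", (DL_FUNC) &mxpol_initmod, 1},
    {"mxpol_rhs",     (DL_FUNC) &mxpol_rhs,     6},
    {NULL, NULL, 0}
};

static const R_CallMethodDef CallEntries[] = {
    {"mxpol_ks2d_d", (DL_FUNC) &mxpol_ks2d_d, 4},
    {NULL, NULL, 0}
};

void R_init_mxpolarity(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
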