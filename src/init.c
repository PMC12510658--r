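#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void ppi_initmod(void (*odeparms)(int *, double *));
void ppi_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);
SEXP C_ppi_rhs(SEXP t, SEXP y, SEXP p);

static const R_CallMethodDef CallEntries[] = {
    {"C_ppi_rhs", (DL_FUNC) &C_ppi_rhs, 3},
    {NULL, NULL, 0}
};

/* registered so deSolve can resolve them by name via getNativeSymbolInfo */
static const R_CMethodDef CEntries[] = {
    {"ppi_initmod", (DL_FUNC) &ppi_initmod, 1},
    {"ppi_derivs",  (DL_FUNC) &ppi_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_ppikin(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, FALSE);
}
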