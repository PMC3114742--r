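#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP c_cond_density(SEXP, SEXP, SEXP, SEXP);
SEXP c_cond_matrix(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

void tnf_initmod(void (*odeparms)(int *, double *));
void tnf_derivs(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
    {"c_cond_density", (DL_FUNC) &c_cond_density, 4},
    {"c_cond_matrix",  (DL_FUNC) &c_cond_matrix,  8},
    {NULL, NULL, 0}
};

/* registered as C routines so deSolve can resolve them by name */
static const R_CMethodDef CEntries[] = {
    {"tnf_initmod", (DL_FUNC) &tnf_initmod, 1},
    {"tnf_derivs",  (DL_FUNC) &tnf_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_popsnap(DllInfo *dll) {
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
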