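// Registration of the .Call entry points (generated names from
// RcppExports.cpp) and of the deSolve-callable model routines
// (bgct_initmod / bgct_derivs / bgct_jac), which deSolve looks up by
// name at run time.
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP _bgctdyn_bgct_drift_c(SEXP, SEXP);
extern SEXP _bgctdyn_bgct_jac_c(SEXP, SEXP);
extern SEXP _bgctdyn_bgct_newton_multistart_c(SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _bgctdyn_bgct_newton_polish_c(SEXP, SEXP, SEXP, SEXP);
extern SEXP _bgctdyn_bgct_em_c(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

void bgct_initmod(void (*odeparms)(int*, double*));
void bgct_derivs(int*, double*, double*, double*, double*, int*);
void bgct_jac(int*, double*, double*, int*, int*, double*, int*, double*, int*);

static const R_CallMethodDef CallEntries[] = {
    {"_bgctdyn_bgct_drift_c",             (DL_FUNC) &_bgctdyn_bgct_drift_c,             2},
    {"_bgctdyn_bgct_jac_c",               (DL_FUNC) &_bgctdyn_bgct_jac_c,               2},
    {"_bgctdyn_bgct_newton_multistart_c", (DL_FUNC) &_bgctdyn_bgct_newton_multistart_c, 5},
    {"_bgctdyn_bgct_newton_polish_c",     (DL_FUNC) &_bgctdyn_bgct_newton_polish_c,     4},
    {"_bgctdyn_bgct_em_c",                (DL_FUNC) &_bgctdyn_bgct_em_c,                9},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"bgct_initmod", (DL_FUNC) &bgct_initmod, 1},
    {"bgct_derivs",  (DL_FUNC) &bgct_derivs,  6},
    {"bgct_jac",     (DL_FUNC) &bgct_jac,     9},
    {NULL, NULL, 0}
};

void R_init_bgctdyn(DllInfo *dll) {
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
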