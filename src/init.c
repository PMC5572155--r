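#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void ord_init(void (*odeparms)(int *, double *));
void ord_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);
void ord_rhs_call(double *t, double *y, double *pars, double *ydot,
                  double *currents);

static const R_CMethodDef CEntries[] = {
    {"ord_rhs_call", (DL_FUNC) &ord_rhs_call, 5},
    {NULL, NULL, 0}
};

void R_init_cipaord(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    /* deSolve looks the model functions up by name */
    R_useDynamicSymbols(dll, TRUE);
}
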