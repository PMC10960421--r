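#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void kmsub_init(void (*odeparms)(int *, double *));
void kmsub_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

SEXP mlp_train(SEXP X, SEXP Y, SEXP hidden, SEXP epochs, SEXP batch,
               SEXP lr, SEXP seed, SEXP Xval, SEXP Yval, SEXP patience);
SEXP mlp_predict(SEXP weights, SEXP X);

static const R_CMethodDef c_entries[] = {
    {"kmsub_init",   (DL_FUNC) &kmsub_init,   1},
    {"kmsub_derivs", (DL_FUNC) &kmsub_derivs, 6},
    {NULL, NULL, 0}
};

static const R_CallMethodDef call_entries[] = {
    {"mlp_train",   (DL_FUNC) &mlp_train,   10},
    {"mlp_predict", (DL_FUNC) &mlp_predict, 2},
    {NULL, NULL, 0}
};

void R_init_kincompass(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
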