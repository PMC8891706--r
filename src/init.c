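#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* The ODE entry points are looked up by deSolve via the package DLL; no
 * .Call routines are exported. */
void R_init_mossreactor(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
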