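#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* deSolve looks the model routines up by name through the package DLL, so
 * dynamic symbol lookup must stay enabled. */
void R_init_tfanet(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
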