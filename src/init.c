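#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#ifdef __GLIBC__
#include <malloc.h>
#endif

/*
 * The CNN training loop allocates and frees ~100 MB matrices every batch
 * (im2col buffers). With glibc's default mmap threshold those buffers are
 * mmap'd and munmap'd each time, so every batch pays full page-fault and
 * page-zeroing cost (~100x slowdown observed). Keeping large blocks on
 * the heap lets the allocator reuse them.
 */
void R_init_entofield(DllInfo *info)
{
#ifdef __GLIBC__
    mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
    R_registerRoutines(info, NULL, NULL, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
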