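# Single-threaded BLAS: linear-algebra reductions are then bit-reproducible
# across machines, so seeded experiments give identical results everywhere.
# (Takes effect because no BLAS call has happened yet in the test process.)
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")
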