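.onLoad <- function(libname, pkgname) {
  # The package's linear algebra is many small dense operations; OpenBLAS
  # thread fan-out is counterproductive there (and containers often report
  # host cores). Cap threads unless the user has chosen a setting.
  if (!nzchar(Sys.getenv("OPENBLAS_NUM_THREADS")))
    Sys.setenv(OPENBLAS_NUM_THREADS = "1")
  if (!nzchar(Sys.getenv("OMP_NUM_THREADS")))
    Sys.setenv(OMP_NUM_THREADS = "1")
  invisible(NULL)
}
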