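.onLoad <- function(libname, pkgname) {
  mem_release_cpp()   # glibc tuning: keep big vectors mmap-backed
  invisible()
}

# full garbage collection plus glibc heap trim; called between the large
# factorization phases
.release_memory <- function() {
  gc(FALSE)
  mem_release_cpp()
  invisible()
}
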