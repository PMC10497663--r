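# temp files/dirs cleaned up when the test exits
withr_local_tempfile <- function(env = parent.frame()) {
  f <- tempfile(fileext = ".csv")
  withr::defer(unlink(f), envir = env)
  f
}

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("dir")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
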