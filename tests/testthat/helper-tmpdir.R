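# Fresh scratch directory per call, cleaned up by R's tempdir lifecycle.
withr_like_tempdir <- function() {
  d <- tempfile("mutevol-test-")
  dir.create(d)
  d
}
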