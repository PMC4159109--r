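# Per-session memoisation of deterministic scaffolding that depends only on
# the record geometry (sample count, sampling rate) and filter settings:
# the synthesis frequency grid / band masks and the analog chain's
# zero-phase magnitude response. Purely a performance cache; every value is
# a pure function of its key.
.pcd_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  val <- .pcd_cache[[key]]
  if (is.null(val)) {
    val <- compute()
    assign(key, val, envir = .pcd_cache)
  }
  val
}
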