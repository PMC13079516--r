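.onLoad <- function(libname, pkgname) {
  # default comparator: weighted cerebellar gain times a partial cancellation
  # of the cortico-basal-ganglia deviation, strength g
  if (!"default" %in% ls(comparator_registry)) {
    register_comparator("default", function(kappa_cbl, kappa_bgctx, g,
                                            weights) {
      kappa_cbl^weights$w_cbl * kappa_bgctx^(-g)
    })
  }
}
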