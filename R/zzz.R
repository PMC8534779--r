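.onLoad <- function(libname, pkgname) {
  .etx$backbones <- new.env(parent = emptyenv())
  .etx$cache <- new.env(parent = emptyenv())
  register_backbone("pooled-stats", input_side = 32L, output_dim = 16L,
                    extract = pooled_stats_extract)
  register_backbone("vgg19-penultimate", input_side = 224L,
                    output_dim = 4096L, extract = vgg19_unavailable)
}
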