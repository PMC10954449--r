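# Shared fixtures: the 12-mer reference panel and annotated duplexes.
hk_test_panel <- local({
  pan <- NULL
  function() {
    if (is.null(pan)) pan <<- t12_panel(seed = 1)
    pan
  }
})

# annotated duplex for a named panel variant ("t12" for the perfect duplex)
hk_test_duplex <- function(name, pan = hk_test_panel()) {
  if (name == "t12") return(duplex(pan$target, pan$probe))
  v <- c(pan$single_mismatch, pan$double_mismatch, pan$bulge)[[name]]
  duplex(v, pan$probe, pan$defects[[name]])
}

hk_test_panel_duplexes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pan <- hk_test_panel()
      nms <- c("t12", names(pan$defects))
      cache <<- setNames(lapply(nms, hk_test_duplex), nms)
    }
    cache
  }
})

R_KCAL <- 0.0019872
RT25 <- R_KCAL * 298.15
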