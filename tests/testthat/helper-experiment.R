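# The desk-scale experiment grid is shared between the few-shot improvement
# check and the ablation-ordering check; it is computed once per test run.

.desk_cache <- new.env(parent = emptyenv())

desk_grid <- function(seeds = 1:5, variants = c("alloc", "multiscale", "adversarial")) {
  key <- paste(c(seeds, variants), collapse = "_")
  if (is.null(.desk_cache[[key]])) {
    rows <- list()
    for (v in variants) {
      for (s in seeds) {
        r <- desk_experiment(seed = s, variant = v)
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v, seed = s,
          dsc_trained = r$dsc_trained, dsc_untrained = r$dsc_untrained)
      }
    }
    .desk_cache[[key]] <- do.call(rbind, rows)
  }
  .desk_cache[[key]]
}
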