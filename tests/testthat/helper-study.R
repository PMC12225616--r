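# One shared reduced-replication run of the full factorial design, computed
# lazily and reused by every acceptance check (it is the expensive step).
acceptance_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_study(design_grid(), reps = 50, seed = 42)
    }
    cache
  }
})

cell_mean <- function(study, col, m) {
  cm <- study$cell_metrics
  mean(cm[[col]][cm$method == m], na.rm = TRUE)
}
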