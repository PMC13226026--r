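# Shared fixtures. The replicated default-calibration study is expensive
# (200 full simulate-measure-metrics passes), so it is computed once per
# test run and shared by the calibration-recovery and temporal-ordering
# checks.
.pd_test_cache <- new.env(parent = emptyenv())

cached_default_study <- function(replicates = 200) {
  key <- paste0("study", replicates)
  if (is.null(.pd_test_cache[[key]])) {
    .pd_test_cache[[key]] <- suppressWarnings(
      run_study(seed = 1, replicates = replicates))
  }
  .pd_test_cache[[key]]
}

# small balanced mixed-design fixture: a groups x n subjects x b times
make_rm_data <- function(a = 3, n = 4, b = 3, seed = 11, effects = NULL) {
  set.seed(seed)
  g <- rep(paste0("g", seq_len(a)), each = n * b)
  s <- rep(sprintf("s%02d", seq_len(a * n)), each = b)
  tt <- rep(seq_len(b), times = a * n)
  y <- rnorm(a * n * b)
  if (!is.null(effects$group_shift)) {
    y <- y + effects$group_shift[match(g, unique(g))]
  }
  data.frame(subject = s, group = g, time = tt, value = y)
}
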