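# The 20-seed synthetic study is the most expensive computation in the
# suite; several tests consume different columns of its table, so it is
# computed once per session and cached.

.study_cache <- new.env(parent = emptyenv())

study_config <- function() {
  analysis_config(seed = 1L, n_randomizations = 100L)
}

get_study_20 <- function() {
  if (!exists("s20", envir = .study_cache)) {
    rep <- full_study(study_config(), n_seeds = 20L)
    assign("s20", rep, envir = .study_cache)
  }
  get("s20", envir = .study_cache)
}
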