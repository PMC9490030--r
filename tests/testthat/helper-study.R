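# The default synthetic study session is expensive (~1 min), and several
# end-to-end checks look at different aspects of the same run; build it
# once on first use and cache it for the rest of the suite.
.study_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (!exists("st", envir = .study_cache)) {
    assign("st", run_study(default_study_config(seed = 1), seed = 11),
           envir = .study_cache)
  }
  get("st", envir = .study_cache)
}
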