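# Shared fixtures. The full-study runs take ~10 s each, so the reports are
# computed once per session and reused across test files.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

sp_table <- function() cached("table", stopping_power_table())

noisy_report <- function() {
  cached("noisy", run_full_study(default_study_config(seed = 1)))
}

noiseless_report <- function() {
  cached("noiseless",
         run_full_study(default_study_config(seed = 1), noise = FALSE,
                        cv = 0))
}

raw_ratio_report <- function() {
  cached("raw", run_full_study(default_study_config(seed = 1),
                               use_reference = FALSE))
}

f2_field <- function() {
  cached("f2", proton_field("f2", 73:112, sobp_width = 4, table = sp_table()))
}
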