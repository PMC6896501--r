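# Shared fixtures: loaded once per test run.

dp <- default_parameters()
dp_ext <- local({
  p <- dp
  p$mortality$life_table <- extrapolate_mortality(p$mortality$life_table, 110)
  p
})
strategies <- default_strategies()

# bundle whose tests can detect nothing and never false-positive
zero_sens_params <- function(params = dp) {
  for (tn in c("FIT", "gFOBT", "colonoscopy")) {
    params$tests[[tn]]$sensitivity_adenoma <- 0
    params$tests[[tn]]$sensitivity_advanced_adenoma <- 0
    params$tests[[tn]]$sensitivity_crc <- 0
    params$tests[[tn]]$specificity <- 1
  }
  params
}

# bundle with no cancer risk at all: pure life-table survival
no_crc_params <- function(params = dp) {
  params$natural_history$onset_base <- 0
  params$natural_history$onset_cap <- 0
  params
}
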