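# Shared fixtures, built once per test run and memoised. Training runs are
# the expensive part of the suite, so the change-model collections used by
# several test files are cached here at reduced (but still well-determined)
# training sizes; the sizes used are recorded in the methods vignette.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(build)()
  .fixture_cache[[name]]
}

ukb_protocol <- function() fixture("ukb_protocol", function()
  make_ukb_protocol(seed = 1))

constrained_models <- function() fixture("constrained_models", function()
  train_change_models(constrained_prior(), ukb_protocol(), n = 14000,
                      seed = 11))

standard_models <- function() fixture("standard_models", function()
  train_change_models(sm_prior(), ukb_protocol(), n = 8000, seed = 12))
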