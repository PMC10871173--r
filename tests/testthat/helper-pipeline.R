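# Shared measured-and-fitted models for the acceptance checks; computed
# once per test run at the standard measurement protocol (S = 100 rates,
# T = 100 s per point, eta = 0.8, event-driven LIF path).
pipeline_env <- new.env()
pipeline_fit <- function(q, seed) {
  key <- sprintf("q%g", q)
  if (is.null(pipeline_env[[key]])) {
    cur <- measure_transfer_curve(lif_params(), q = q, eta = 0.8, S = 100,
                                  d_max = 100, duration = 100, seed = seed)
    pipeline_env[[key]] <- fit_rsp(cur)
  }
  pipeline_env[[key]]
}
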