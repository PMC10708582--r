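# The desk-scale behavioral block reports one expectation per architecture
# variant; keep the progress reporter from aborting the session before the
# remaining files have run.
options(testthat.progress.max_fails = 1000L)
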