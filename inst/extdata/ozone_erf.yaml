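# Example log-linear ozone exposure-response configuration: relative risk
# of respiratory mortality per 10 ppbv of annual daily-maximum-8-h ozone
# above the counterfactual threshold (TMREL). The TMREL is a file-level
# choice; edit it here for sensitivity analyses.
rr_per_10ppb: 1.12
rr_low: 1.08
rr_high: 1.16
tmrel_ppbv: 26.7
cause: resp
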