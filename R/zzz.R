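# data.table is used through :: only; this flag opts the package into
# data.table [] semantics (see data.table FAQ on non-Depends usage)
.datatable.aware <- TRUE
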