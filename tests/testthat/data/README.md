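# Optional local data for integration tests

Place the deposited experiment export here as `osf_gamelog.csv` (long
format: `session, day, game, round, player, partner, action`, actions
`C`/`D`; use `log_dialect()` + a small conversion script if the export
uses different column names). The integration test in `test-acceptance.R`
runs only when this file exists; everything else in the suite is
self-contained.
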