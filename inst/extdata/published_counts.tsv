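# Published summary counts for the curated SCN5A electrophysiology
# literature database (variant tallies and report statistics). The full
# per-variant database is not publicly deposited; these marginal counts
# are the published totals and drive the summary-statistics reporting.
key	value
protein_length	2016
total_found_variants	610
total_found_positions	482
ep_variants	243
ep_positions	199
ep_changed	175
ep_unchanged	68
activation_changed	69
inactivation_changed	125
late_changed	40
zero_current	30
possible_with_duplicates	13357
possible_unique	11923
ep_reports	378
multireport_variants	74
multireport_conflicting	43
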