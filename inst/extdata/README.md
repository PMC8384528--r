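# Bundled fixtures

## `transaminase_t50.csv`

Thermostability panel of the (R)-selective omega-transaminase from
*Aspergillus terreus* (325 residues): 13 labeled records (wild type + 12
mutants built from the six point mutations I77L, Q97E, H210N, N245D, G292D,
I295V), with the half-life `T_1/2` at 40 degrees C in minutes (`activity`,
the mean over replicate assays) and its replicate SD (`activity_sd`).
`activity_sd` is stored for completeness but never used in fitting.

Provenance note: the published study's data table, which this file
transcribes verbatim, lists P7 as the double mutant `I77L_H210N`
(T_1/2 = 42.2 min), while the study's prose calls P7 the combination of all
six mutations. The table is followed literally here; no attempt is made to
resolve the discrepancy. The wild-type protein sequence was not published
with the panel, so this fixture supports parsing/enumeration tests and
user-supplied-sequence analyses, not a standalone re-fit.

## `aaindex_synthetic.aaindex1`

A small synthetic AAindex1-format file (values invented for testing, not
taken from any AAindex release): three complete entries plus one entry with
`NA` values that a conforming parser must exclude.
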