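# Optional external fixtures

`bodyfat.csv` (not bundled): the public 250-row body-fat dataset
(outcome column `Pct.BF`, 13 anthropometric predictors) available from
https://dasl.datadescription.com/datafile/bodyfat/. Place it here to enable
the body-fat application checks in the test suite; everything else in the
package runs without it.
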