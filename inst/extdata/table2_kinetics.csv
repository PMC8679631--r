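# Baseline dynamic PET two-tissue-compartment parameters for the 14 subjects with
# physiologically interpretable fits. Values transcribed as printed; vb is kept
# verbatim (three entries use scientific notation, one of which, patient 1's
# "5.0E-0" = 5.0, lies outside the physical range of a blood-volume fraction and
# is flagged by the loader rather than corrected).
# Columns: patient_id; k1 (mL/min/g); k2, k3, k4 (1/min); vb (fraction, verbatim
# string); ki_printed (mL/min/g) as printed in the source table.
patient_id,k1,k2,k3,k4,vb,ki_printed
1,0.16,0.10,0.10,0.11,5.0E-0,0.08
2,0.17,0.076,0.074,0.07,0.015,0.09
3,0.31,0.40,0.24,0.04,0.019,0.11
4,0.21,0.28,0.13,0.06,0.034,0.07
5,0.34,0.17,0.097,0.04,0.03,0.13
6,0.43,0.28,0.086,0.01,0.058,0.10
8,0.282,0.28,0.13,0.02,0.04,0.09
9,0.29,0.53,0.32,0.04,0.05,0.11
11,0.41,0.51,0.17,0.02,0.07,0.10
13,0.11,0.16,0.04,0.001,0.10,0.02
14,0.46,0.42,0.13,0.03,2.9E-04,0.11
15,0.58,0.69,0.13,0.02,0.07,0.09
16,0.26,0.18,0.08,0.02,0.07,0.08
18,0.23,0.19,0.09,0.02,8.0E-06,0.07
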