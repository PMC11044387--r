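Packaged cohort tables (plain-text CSV transcriptions of the published
elderly-cohort tables; degrees unless noted):

table1_baseline.csv  baseline characteristics: sex, age (years), Neck
                     Disability Index (points and %), Kellgren grade per
                     analysed segment (0-4), and the presence (+/-) of the
                     normal extension sequence at sessions T1 and T2.
table2_rom.csv       segmental (sROM) and total C4-C7 (tROM) ranges of
                     motion per individual at T1 and T2.
table4_external.csv  the three external-validation individuals; their
                     recordings start from neutral posture, so values cover
                     only the second half of extension.

Column dictionary: id = individual; trom_* = total C4-C7 range of motion;
srom_c45/c56/c67_* = segmental range of C4-C5/C5-C6/C6-C7; *_t1/_t2 =
recording session; ks_* = Kellgren grade; ndi_points/ndi_pct = Neck
Disability Index score; seq_t1/seq_t2 = normal-sequence classification.
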