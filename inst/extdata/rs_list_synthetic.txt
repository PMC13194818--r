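# Synthetic stand-in rs list (30 ids).
# The benchmark requires a user-supplied list of 30 distinct rs numbers;
# the specific ids used in the published evaluation are not enumerated
# anywhere, so this packaged default is a synthetic set that merely has the
# right shape (valid, distinct dbSNP-style identifiers). Replace with a real
# list for any substantive analysis.
rs34637584
rs1000113
rs1042522
rs113488022
rs121913529
rs12913832
rs1333049
rs1421085
rs16969968
rs1800562
rs1801133
rs199472709
rs2032582
rs2187668
rs2241880
rs28897696
rs3184504
rs334
rs3745274
rs4149056
rs429358
rs4988235
rs5030858
rs58542926
rs6025
rs671
rs699
rs7412
rs762551
rs9939609
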