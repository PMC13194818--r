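# Fixture HGVS -> GRCh38 allele lookup table (recoder contract stand-in).
# allele format: chrom:pos:ref:alt
hgvs	allele
ENST00000298910.12:c.6055G>A	12:40340400:G:A
ENSP00000298910.7:p.Gly2019Ser	12:40340400:G:A
NC_000012.12:g.40340400G>A	12:40340400:G:A
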