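# X-chromosome region boundaries, GRCh37/hg19 (1-based inclusive)
par1:
  start: 60001
  end: 2699520
par2:
  start: 154931044
  end: 155260560
# genes starting below this coordinate are nonPAR_Xp, above it nonPAR_Xq
# (start of the chrX centromeric assembly gap)
xp_xq_split: 58632012
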