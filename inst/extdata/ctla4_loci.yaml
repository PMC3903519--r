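# Six CTLA-4 SNP loci: cycle order CT318-AG49-CT60-JO30-JO27-JO31,
# report order AG49,CT60,CT318,JO27,JO30,JO31. Positions are 0-based.
- name: AG49
  rsid: rs231775
  major: A
  minor: G
  cycle_position: 1
  report_position: 0
- name: CT60
  rsid: rs3087243
  major: A
  minor: G
  cycle_position: 2
  report_position: 1
- name: CT318
  rsid: rs5742909
  major: C
  minor: T
  cycle_position: 0
  report_position: 2
- name: JO27
  rsid: rs11571297
  major: C
  minor: T
  cycle_position: 4
  report_position: 3
- name: JO30
  rsid: rs7565213
  major: A
  minor: G
  cycle_position: 3
  report_position: 4
- name: JO31
  rsid: rs11571302
  major: T
  minor: G
  cycle_position: 5
  report_position: 5
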