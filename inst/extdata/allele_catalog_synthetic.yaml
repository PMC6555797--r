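# Synthetic placeholder allele catalogue for the 7-site protector-gene SNP
# panel. Patterns are states at sites 1-7 on the forward strand of the
# reference layout in s1_snp_panel(). These entries are illustrative only:
# substitute the authoritative published pattern table for real analyses.
# Naming convention: family 1-x = truncated-protector (TP) alleles (site 7 = A),
# family 2-x = full-length protector (TPR) alleles (site 7 = C).
alleles:
  - allele: "2-1"
    structure: "A4-TPR-A6"
    pattern: "AGCTGAC"
  - allele: "2-2"
    structure: "A4-TPR-A6"
    pattern: "AACTGAC"
  - allele: "2-3"
    structure: "A4-TPR-A6"
    pattern: "AGCTAAC"
  - allele: "2-4"
    structure: "A4-TPR-A6"
    pattern: "AACTAAC"
  - allele: "1-1"
    structure: "TP"
    pattern: "AGCTGAA"
  - allele: "1-2"
    structure: "TP"
    pattern: "GGCTGAA"
  - allele: "1-3"
    structure: "TP"
    pattern: "AGTTGAA"
  - allele: "1-4"
    structure: "A4-TP"
    pattern: "AGCCGAA"
  - allele: "1-5"
    structure: "TP-A6"
    pattern: "AGCTGGA"
  - allele: "1-6"
    structure: "A4-TP-A6"
    pattern: "GGTTGAA"
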