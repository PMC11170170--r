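# Hand-curated subset of HLA-A P-group assignments in the IMGT/HLA
# hla_nom_p.txt dialect: locus*;allele1/allele2/...;group
# Covers the A*02 alleles relevant to MAGE-A4 TCR T cell eligibility screening
# plus common non-A*02 alleles. Records with an empty group field denote
# alleles outside any multi-allele P group (two-field singletons). Null
# alleles (suffix N) encode no surface protein and are kept out of P groups.
A*;02:01:01:01/02:01:01:02L/02:09/02:66/02:75/02:89/02:97:01/02:97:02/02:132/02:134/02:140/02:642;02:01P
A*;02:02:01:01/02:02:01:02;02:02P
A*;02:03:01/02:03:03/02:03:04;02:03P
A*;02:05:01:01/02:05:01:02/02:05:02/02:05:03;02:05P
A*;02:06:01:01/02:06:01:02/02:06:09;02:06P
A*;02:07:01/02:07:02/02:07:03;02:07P
A*;02:11:01;02:11P
A*;02:43N;
A*;02:135;
A*;01:01:01:01/01:01:02;01:01P
A*;01:04N;
A*;03:01:01:01/03:01:01:03;03:01P
A*;11:01:01/11:01:02;11:01P
A*;23:01:01;23:01P
A*;24:02:01:01/24:02:01:02L/24:02:10;24:02P
A*;26:01:01;26:01P
A*;29:02:01:01/29:02:01:02;29:02P
A*;30:01:01;30:01P
A*;31:01:02;31:01P
A*;32:01:01;32:01P
A*;33:01:01;33:01P
A*;33:03:01;33:03P
A*;34:02:01;34:02P
A*;36:01;
A*;68:01:01/68:01:02;68:01P
A*;68:02:01:01/68:02:01:02;68:02P
A*;69:01;
A*;69:02;
A*;74:01/74:02;74:01P
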