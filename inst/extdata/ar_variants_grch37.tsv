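# AR splice-variant definition template, GRCh37.
# Schema: name, chrom, donor, acceptor, strand, genome_build, role
#   role in {defining-primary, defining-alternate, none}
#   donor = first intronic base, acceptor = last intronic base (1-based).
# The 'reference' row is the canonical AR exon 1 - exon 2 junction derived
# from RefSeq NM_000044 exon bounds on GRCh37 (exon 1 ends 66766604, exon 2
# starts 66863098); verify against your annotation before use.
# The cryptic-exon junctions of the named AR-Vs are deliberately left as
# editable placeholders (NA coordinates): fill them in from the cryptic-exon
# compendium of your choice for the matching genome build. With the
# placeholders in place every variant is non-quantifiable, so an edited copy
# is required for real analyses. AR-V11 has no distinctive splice junction
# and stays role=none permanently.
name	chrom	donor	acceptor	strand	genome_build	role
reference	chrX	66766605	66863097	+	GRCh37	defining-primary
AR-V1	NA	NA	NA	NA	GRCh37	none
AR-V3	NA	NA	NA	NA	GRCh37	none
AR-V7	NA	NA	NA	NA	GRCh37	none
AR-V9	NA	NA	NA	NA	GRCh37	none
AR23	NA	NA	NA	NA	GRCh37	none
AR45	NA	NA	NA	NA	GRCh37	none
AR-V11	NA	NA	NA	NA	GRCh37	none
AR-V2	NA	NA	NA	NA	GRCh37	none
AR-V4	NA	NA	NA	NA	GRCh37	none
AR-V5	NA	NA	NA	NA	GRCh37	none
AR-V6	NA	NA	NA	NA	GRCh37	none
AR-V8	NA	NA	NA	NA	GRCh37	none
AR-V10	NA	NA	NA	NA	GRCh37	none
AR-V12	NA	NA	NA	NA	GRCh37	none
AR-V13	NA	NA	NA	NA	GRCh37	none
AR-V14	NA	NA	NA	NA	GRCh37	none
AR-V15	NA	NA	NA	NA	GRCh37	none
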