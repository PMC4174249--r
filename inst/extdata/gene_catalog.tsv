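# Default functional gene catalog: perchlorate reduction (pcrABCD),
# chlorite dismutation (cld) and nitrate reduction (narG/narH/napA).
# accessions: comma-separated member accessions.  The shipped values are
# synthetic placeholders — replace them with the GenBank accessions of
# your reference genes, or rely on gene2accession/gene_info maps, which
# the pipeline also resolves symbols through.
# Member accessions must be unique across entries — the first catalog
# match wins during annotation.
gene_symbol	category	accessions
pcrA	perchlorate reduction	PCRA001
pcrB	perchlorate reduction	PCRB001
pcrC	perchlorate reduction	PCRC001
pcrD	perchlorate reduction	PCRD001
cld	chlorite dismutation	CLD001
narG	nitrate reduction	NARG001
narH	nitrate reduction	NARH001
napA	nitrate reduction	NAPA001
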