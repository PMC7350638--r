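# IUPAC consensus motif registry bundled with oriScan.
# Columns: name, pattern (IUPAC), source.
# EACS: 17 bp extended ARS consensus sequence, S. cerevisiae.
name	pattern	source
EACS	WWWWTTTAYRTTTWGTT	Extended ARS consensus (17 bp), S. cerevisiae; Theis & Newlon, PNAS 94:10786-10791 (1997)
ACS	WTTTAYRTTTW	ARS consensus sequence core (11 bp), S. cerevisiae; Newlon & Theis, Curr Opin Genet Dev 3:752-758 (1993)
AATAAA	AATAAA	Hexamer shared by DNA unwinding elements flanking plant/yeast origins; also the canonical eukaryotic polyadenylation signal
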