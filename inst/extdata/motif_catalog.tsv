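motif_id	iupac	name
motif1	TGTCTC	ARF binding site
motif2	TACACAT	auxin response element
motif3	TATTCT	root tip meristem element
motif4	ATATT	root-specific element (RSE)
motif5	TTGAC	W-box (TTGAC)
motif6	TGACT	W-box (TGACT)
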