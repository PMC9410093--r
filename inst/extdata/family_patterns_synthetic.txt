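# Neuropeptide family pattern library.
# One '>name' line, then one whitespace-separated token per alignment
# column: a fixed residue, a residue class (X/Y), or '.' for any residue.
#
# The two orcokinin-B entries encode the conserved hexapeptide domain:
# the strict DS(L/I)GGG form and the class form D(S/T)(L/I)GGG that also
# covers the Thr variant carried by PYY-type family members.
# The orcokinin-C core and the FCAN consensus are SYNTHETIC stand-ins
# written at fixture-preparation time (the published consensus blocks are
# graphical); family calls against them are only asserted on sequences
# whose family is stated in the text.
>orcokinin_B_hexapeptide
D S (L/I) G G G
>orcokinin_B_class
D (S/T) (L/I) G G G
>orcokinin_C_core
(S/A) (L/I) G G G (Y/F)
>FCAN_consensus
A V D N S M P E W L Q S N P M A F R E
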