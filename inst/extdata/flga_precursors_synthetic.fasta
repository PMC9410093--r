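; Synthetic reconstruction of the FLGamide A/B prohormone precursors.
; Built from printed facts only (peptide sequences, copy counts, PTM flags);
; the signal peptide, spacer, and FLGa 4/5/6 sequences are invented.
>FLGaA signal_end=17 is_partial=no
MLSLVALLLVLLAVSSAEDAKRGAESGEAHVFDSLGGGHVPYYKRVFDTLGGGHVPYYKR
FDSLGGGSFLGGKRFDSLGGGSFLGGKRFDSLGGGSFLGGKRFDSLGGGSFLGGKRFDSL
GGGSFLGGKRFDSLGGGSFLGGKRFDSLGGGSFLGGKRDSIGGGSHFLGGKRNEDSLGGG
TFLGGKRRSGDSLGGGHAFYE*
>FLGaB signal_end=17 is_partial=no
MLSLVALLLVLLAVSSAEDAKRGAESGEAHVFDSLGGGHVPYYKRVFDTLGGGHVPYYKR
FDSLGGGSFLGGKRFDSLGGGSFLGGKRFDSLGGGSFLGGKRFDSLGGGSFLGGKRFDSL
GGGSFLGGKRFDSLGGGSFLGGKRFDSLGGGSFLGGKRFDSLGGGSFLGGKRDSIGGGSH
FLGGKRNEDSLGGGTFLGGKRRSGDSLGGGHAFYE*
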