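name,formula,rt_min,labelled
mono-methyl phthalate,C9H8O4,5.88,FALSE
mono-ethyl phthalate,C10H10O4,6.78,FALSE
mono-n-propyl phthalate,C11H12O4,7.68,FALSE
mono-isopropyl phthalate,C11H12O4,7.45,FALSE
mono-n-butyl phthalate,C12H14O4,8.58,FALSE
mono-isobutyl phthalate,C12H14O4,8.35,FALSE
mono-n-pentyl phthalate,C13H16O4,9.48,FALSE
mono-3-methylbutyl phthalate,C13H16O4,9.3,FALSE
mono-n-hexyl phthalate,C14H18O4,10.38,FALSE
mono-cyclohexyl phthalate,C14H16O4,9.9,FALSE
mono-benzyl phthalate,C15H12O4,10.55,FALSE
mono-phenyl phthalate,C14H10O4,10.2,FALSE
mono-n-heptyl phthalate,C15H20O4,11.28,FALSE
mono-n-octyl phthalate,C16H22O4,12.4,FALSE
mono-2-ethylhexyl phthalate,C16H22O4,12.55,FALSE
mono-n-nonyl phthalate,C17H24O4,13.08,FALSE
mono-isononyl phthalate,C17H24O4,13.5,FALSE
mono-n-decyl phthalate,C18H26O4,13.98,FALSE
mono-n-undecyl phthalate,C19H28O4,14.88,FALSE
mono-n-dodecyl phthalate,C20H30O4,15.78,FALSE
mono-2-methoxyethyl phthalate,C11H12O5,6.6,FALSE
mono-3-carboxypropyl phthalate,C12H12O6,6.42,FALSE
mono-5-carboxypentyl phthalate,C14H16O6,8.6,FALSE
mono-2-ethyl-5-carboxypentyl phthalate,C16H20O6,9.7,FALSE
[13C4]-mono-methyl phthalate,C5[13C]4H8O4,5.88,TRUE
[13C4]-mono-ethyl phthalate,C6[13C]4H10O4,6.78,TRUE
[13C4]-mono-n-propyl phthalate,C7[13C]4H12O4,7.68,TRUE
[13C4]-mono-n-butyl phthalate,C8[13C]4H14O4,8.58,TRUE
[13C4]-mono-n-pentyl phthalate,C9[13C]4H16O4,9.48,TRUE
[13C4]-mono-n-hexyl phthalate,C10[13C]4H18O4,10.38,TRUE
[13C4]-mono-n-heptyl phthalate,C11[13C]4H20O4,11.28,TRUE
[13C4]-mono-n-octyl phthalate,C12[13C]4H22O4,12.4,TRUE
[13C4]-mono-benzyl phthalate,C11[13C]4H12O4,10.55,TRUE
[13C4]-mono-cyclohexyl phthalate,C10[13C]4H16O4,9.9,TRUE
[13C4]-mono-2-ethylhexyl phthalate,C12[13C]4H22O4,12.55,TRUE
[13C4]-mono-isononyl phthalate,C13[13C]4H24O4,13.5,TRUE
[13C4]-mono-2-ethyl-5-carboxypentyl phthalate,C12[13C]4H20O6,9.7,TRUE
[13C4]-mono-5-carboxypentyl phthalate,C10[13C]4H16O6,8.6,TRUE
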