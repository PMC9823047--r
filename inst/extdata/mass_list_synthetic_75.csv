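name,formula
mono-methyl phthalate,C9H8O4
mono-ethyl phthalate,C10H10O4
mono-n-propyl phthalate,C11H12O4
mono-n-butyl phthalate,C12H14O4
mono-n-pentyl phthalate,C13H16O4
mono-n-hexyl phthalate,C14H18O4
mono-n-heptyl phthalate,C15H20O4
mono-n-octyl phthalate,C16H22O4
mono-n-nonyl phthalate,C17H24O4
mono-n-decyl phthalate,C18H26O4
mono-n-undecyl phthalate,C19H28O4
mono-n-dodecyl phthalate,C20H30O4
mono-n-tridecyl phthalate,C21H32O4
mono-isopropyl phthalate,C11H12O4
mono-isobutyl phthalate,C12H14O4
mono-3-methylbutyl phthalate,C13H16O4
mono-4-methylpentyl phthalate,C14H18O4
mono-5-methylhexyl phthalate,C15H20O4
mono-2-ethylhexyl phthalate,C16H22O4
mono-isononyl phthalate,C17H24O4
mono-2-propylheptyl phthalate,C18H26O4
mono-9-methyldecyl phthalate,C19H28O4
mono-benzyl phthalate,C15H12O4
mono-phenyl phthalate,C14H10O4
mono-cyclohexyl phthalate,C14H16O4
mono-2-methoxyethyl phthalate,C11H12O5
mono-3-hydroxypropyl phthalate,C11H12O5
mono-4-hydroxybutyl phthalate,C12H14O5
mono-5-hydroxypentyl phthalate,C13H16O5
mono-5-hydroxyhexyl phthalate,C14H18O5
mono-7-hydroxyheptyl phthalate,C15H20O5
mono-2-ethyl-5-hydroxyhexyl phthalate,C16H22O5
mono-7-hydroxynonyl phthalate,C17H24O5
mono-2-propyl-6-hydroxyheptyl phthalate,C18H26O5
mono-10-hydroxyundecyl phthalate,C19H28O5
mono-11-hydroxydodecyl phthalate,C20H30O5
mono-12-hydroxytridecyl phthalate,C21H32O5
mono-3-oxopropyl phthalate,C11H10O5
mono-4-oxobutyl phthalate,C12H12O5
mono-5-oxopentyl phthalate,C13H14O5
mono-5-oxohexyl phthalate,C14H16O5
mono-6-oxoheptyl phthalate,C15H18O5
mono-2-ethyl-5-oxohexyl phthalate,C16H20O5
mono-3-propyl-4-oxohexyl phthalate,C17H22O5
mono-9-oxodecyl phthalate,C18H24O5
mono-10-oxoundecyl phthalate,C19H26O5
mono-11-oxododecyl phthalate,C20H28O5
mono-12-oxotridecyl phthalate,C21H30O5
mono-2-carboxyethyl phthalate,C11H10O6
mono-3-carboxypropyl phthalate,C12H12O6
mono-4-carboxybutyl phthalate,C13H14O6
mono-5-carboxypentyl phthalate,C14H16O6
mono-6-carboxyhexyl phthalate,C15H18O6
mono-2-ethyl-5-carboxypentyl phthalate,C16H20O6
mono-8-carboxyoctyl phthalate,C17H22O6
mono-9-carboxynonyl phthalate,C18H24O6
mono-10-carboxydecyl phthalate,C19H26O6
mono-11-carboxyundecyl phthalate,C20H28O6
mono-12-carboxydodecyl phthalate,C21H30O6
mono-1-hydroxy-2-oxobutyl phthalate,C12H12O6
mono-1-hydroxy-4-oxopentyl phthalate,C13H14O6
mono-2-hydroxy-5-oxohexyl phthalate,C14H16O6
mono-1-hydroxy-6-oxoheptyl phthalate,C15H18O6
mono-1-hydroxy-2-oxo-5-ethylhexyl phthalate,C16H20O6
mono-2-hydroxy-8-oxononyl phthalate,C17H22O6
mono-3-hydroxy-9-oxodecyl phthalate,C18H24O6
mono-2-hydroxy-10-oxoundecyl phthalate,C19H26O6
mono-3-hydroxy-11-oxododecyl phthalate,C20H28O6
mono-4-hydroxy-12-oxotridecyl phthalate,C21H30O6
phthalic acid,C8H6O4
mono-2-hydroxyethyl phthalate,C10H10O5
mono-carboxymethyl phthalate,C10H8O6
mono-2-3-dihydroxypropyl phthalate,C11H12O6
mono-vinyl phthalate,C10H8O4
mono-allyl phthalate,C11H10O4
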