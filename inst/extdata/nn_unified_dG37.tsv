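# Unified DNA nearest-neighbor stack free energies, dG37 in kcal/mol.
# Key is the 5'->3' top-strand dinucleotide of an antiparallel Watson-Crick
# stack; symmetric steps are listed under both keys. "initiation" is a single
# constant duplex-initiation penalty applied once per duplex.
# version: 1.0
step	dG_kcal_mol
AA	-1.00
TT	-1.00
AT	-0.88
TA	-0.58
CA	-1.45
TG	-1.45
GT	-1.44
AC	-1.44
CT	-1.28
AG	-1.28
GA	-1.30
TC	-1.30
CG	-2.17
GC	-2.24
GG	-1.84
CC	-1.84
initiation	1.96
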