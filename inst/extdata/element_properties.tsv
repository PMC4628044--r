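# Atomic property constants for descriptor weighting (carbon-scaled at run time).
# mass: IUPAC 2021 standard atomic weights (abridged).
# sanderson_en: Sanderson electronegativity scale (Sanderson 1976/1983).
# vdw_volume: volume (A^3) of a sphere with the Bondi (1964) van der Waals
#   radius, V = 4/3 pi r^3 (B radius from Mantina 2009).
# Users may edit a copy of this file and pass it through the `table`
# arguments to override the defaults.
element	mass	sanderson_en	vdw_volume
H	1.008	2.592	7.236
B	10.81	2.275	29.648
C	12.011	2.746	20.579
N	14.007	3.194	15.597
O	15.999	3.654	14.711
F	18.998	4.000	13.305
P	30.974	2.515	24.429
S	32.06	2.957	24.429
Cl	35.45	3.475	22.449
Br	79.904	3.219	26.520
I	126.904	2.778	32.515
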