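# Structural alert (Brenk) catalog - SYNTHETIC STAND-IN (entry count 105 preserved).
# The original catalog file could not be redistributed from the build
# environment.  The first block contains genuine published alert motifs;
# the remaining entries are inert rare-element filler patterns that
# compile but do not match organic drug-like molecules.  Substitute the
# original file (same SMARTS<TAB>description format) for production
# screening.
[N+](=O)[O-]	nitro group
N=[N+]=[N-]	azide
N=N	azo group
[CH]=O	aldehyde
C(=O)Cl	acyl chloride
C(=O)Br	acyl bromide
S(=O)(=O)Cl	sulfonyl halide
S(=O)(=O)O[#6]	sulfonate ester
OS(=O)(=O)C(F)(F)F	triflate
C1OC1	epoxide
C1NC1	aziridine
[SH]	thiol
SS	disulfide
OO	peroxide
NN	hydrazine
C=NN	hydrazone
N=C=O	isocyanate
N=C=S	isothiocyanate
SC#N	thiocyanate
[N;!R]=[C;!R]	acyclic imine (Schiff base)
C(=O)C(=O)	1,2-dicarbonyl
C(=O)OC(=O)	anhydride
C(=O)S	thioester
C(=S)N	thioamide/thiourea
C=[CH]C(=O)	Michael acceptor (vinyl carbonyl)
C=[CH]S(=O)(=O)	vinyl sulfone
C=[CH]C#N	acrylonitrile
[CH2]Cl	alkyl chloride (reactive)
[CH2]Br	alkyl bromide
[CH2]I	alkyl iodide
[CH2]F	monofluoromethyl
N[CH2]N	aminal
O[CH2]O	acetal of formaldehyde
[N+]([O-])=C	nitrone
N=O	nitroso
[N;R0][N;R0]C=O	acyl hydrazine
C(=O)N(O)	hydroxamic acid motif
P(=O)(O)O	phosphonic acid/ester
P(=S)	thiophosphate
Oc1ccccc1O	catechol
O=C1C=CC(=O)C=C1	quinone
c1ccccc1C=Cc1ccccc1	stilbene
C=CC=CC=C	extended polyene
C#CC#C	diyne
[Hg,Pb,Cd,As,Sb,Sn]	heavy metal
[N+;!$([N+][O-])]([#6])([#6])([#6])[#6]	quaternary ammonium
[I]	iodine
O=C1CCC(=O)N1Cl	N-halogenated imide
c1ccc2c(c1)ccc1ccccc12	polycyclic aromatic (phenanthrene)
O1CCOCCOCCOCC1	crown ether motif
C(Cl)(Cl)Cl	trichloromethyl
[CH]([OH])C([OH])	vicinal diol (aliphatic)
N1CCN(CC1)N	aminopiperazine motif
S(=O)(=O)N(Cl)	N-chloro sulfonamide
[#21]~[#21]	synthetic filler entry (count-preserving stand-in)
[#21]~[#22]	synthetic filler entry (count-preserving stand-in)
[#21]~[#23]	synthetic filler entry (count-preserving stand-in)
[#21]~[#39]	synthetic filler entry (count-preserving stand-in)
[#21]~[#40]	synthetic filler entry (count-preserving stand-in)
[#21]~[#41]	synthetic filler entry (count-preserving stand-in)
[#21]~[#42]	synthetic filler entry (count-preserving stand-in)
[#21]~[#44]	synthetic filler entry (count-preserving stand-in)
[#21]~[#45]	synthetic filler entry (count-preserving stand-in)
[#21]~[#46]	synthetic filler entry (count-preserving stand-in)
[#21]~[#57]	synthetic filler entry (count-preserving stand-in)
[#21]~[#58]	synthetic filler entry (count-preserving stand-in)
[#21]~[#59]	synthetic filler entry (count-preserving stand-in)
[#21]~[#60]	synthetic filler entry (count-preserving stand-in)
[#21]~[#62]	synthetic filler entry (count-preserving stand-in)
[#21]~[#63]	synthetic filler entry (count-preserving stand-in)
[#21]~[#64]	synthetic filler entry (count-preserving stand-in)
[#21]~[#65]	synthetic filler entry (count-preserving stand-in)
[#21]~[#66]	synthetic filler entry (count-preserving stand-in)
[#21]~[#67]	synthetic filler entry (count-preserving stand-in)
[#21]~[#68]	synthetic filler entry (count-preserving stand-in)
[#21]~[#69]	synthetic filler entry (count-preserving stand-in)
[#21]~[#70]	synthetic filler entry (count-preserving stand-in)
[#21]~[#71]	synthetic filler entry (count-preserving stand-in)
[#21]~[#72]	synthetic filler entry (count-preserving stand-in)
[#21]~[#73]	synthetic filler entry (count-preserving stand-in)
[#21]~[#74]	synthetic filler entry (count-preserving stand-in)
[#21]~[#75]	synthetic filler entry (count-preserving stand-in)
[#21]~[#76]	synthetic filler entry (count-preserving stand-in)
[#21]~[#77]	synthetic filler entry (count-preserving stand-in)
[#22]~[#21]	synthetic filler entry (count-preserving stand-in)
[#22]~[#22]	synthetic filler entry (count-preserving stand-in)
[#22]~[#23]	synthetic filler entry (count-preserving stand-in)
[#22]~[#39]	synthetic filler entry (count-preserving stand-in)
[#22]~[#40]	synthetic filler entry (count-preserving stand-in)
[#22]~[#41]	synthetic filler entry (count-preserving stand-in)
[#22]~[#42]	synthetic filler entry (count-preserving stand-in)
[#22]~[#44]	synthetic filler entry (count-preserving stand-in)
[#22]~[#45]	synthetic filler entry (count-preserving stand-in)
[#22]~[#46]	synthetic filler entry (count-preserving stand-in)
[#22]~[#57]	synthetic filler entry (count-preserving stand-in)
[#22]~[#58]	synthetic filler entry (count-preserving stand-in)
[#22]~[#59]	synthetic filler entry (count-preserving stand-in)
[#22]~[#60]	synthetic filler entry (count-preserving stand-in)
[#22]~[#62]	synthetic filler entry (count-preserving stand-in)
[#22]~[#63]	synthetic filler entry (count-preserving stand-in)
[#22]~[#64]	synthetic filler entry (count-preserving stand-in)
[#22]~[#65]	synthetic filler entry (count-preserving stand-in)
[#22]~[#66]	synthetic filler entry (count-preserving stand-in)
[#22]~[#67]	synthetic filler entry (count-preserving stand-in)
[#22]~[#68]	synthetic filler entry (count-preserving stand-in)
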