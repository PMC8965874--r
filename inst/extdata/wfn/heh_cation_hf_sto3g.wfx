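<Title>
 HeH+ HF/STO-3G R=1.4632 bohr (fixture)
</Title>
<Keywords>
 GTO
</Keywords>
<Number of Nuclei>
 2
</Number of Nuclei>
<Number of Occupied Molecular Orbitals>
 1
</Number of Occupied Molecular Orbitals>
<Number of Perturbations>
 0
</Number of Perturbations>
<Net Charge>
 1
</Net Charge>
<Number of Electrons>
 2
</Number of Electrons>
<Number of Alpha Electrons>
 1
</Number of Alpha Electrons>
<Number of Beta Electrons>
 1
</Number of Beta Electrons>
<Electronic Spin Multiplicity>
 1
</Electronic Spin Multiplicity>
<Nuclear Names>
 He1
 H2
</Nuclear Names>
<Atomic Numbers>
 2
 1
</Atomic Numbers>
<Nuclear Charges>
 2.0000000000e+00
 1.0000000000e+00
</Nuclear Charges>
<Nuclear Cartesian Coordinates>
 0.000000000000e+00 0.000000000000e+00 0.000000000000e+00
 0.000000000000e+00 0.000000000000e+00 1.463200000000e+00
</Nuclear Cartesian Coordinates>
<Number of Primitives>
 6
</Number of Primitives>
<Primitive Centers>
 1 1 1 2 2 2
</Primitive Centers>
<Primitive Types>
 1 1 1 1 1 1
</Primitive Types>
<Primitive Exponents>
 6.362421390000e+00 1.158923000000e+00 3.136497900000e-01 3.425250910000e+00 6.239137300000e-01 1.688554000000e-01
</Primitive Exponents>
<Molecular Orbital Occupation Numbers>
 2.000000000000e+00
</Molecular Orbital Occupation Numbers>
<Molecular Orbital Energies>
 -1.632713371249e+00
</Molecular Orbital Energies>
<Molecular Orbital Spin Types>
 Alpha and Beta
</Molecular Orbital Spin Types>
<Molecular Orbital Primitive Coefficients>
<MO Number>
 1
</MO Number>
 3.862753226773e-01 3.735886674113e-01 1.164312691356e-01 5.605841860538e-02 5.421726079306e-02
 1.689715172150e-02
</Molecular Orbital Primitive Coefficients>
<Energy = T + Vne + Vee + Vnn>
 -2.841836499287e+00
</Energy = T + Vne + Vee + Vnn>
<Virial Ratio (-V/T)>
 2.197913955741e+00
</Virial Ratio (-V/T)>
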