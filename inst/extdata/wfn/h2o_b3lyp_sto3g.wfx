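<Title>
 H2O B3LYP/STO-3G TIP3P geometry (fixture)
</Title>
<Keywords>
 GTO
</Keywords>
<Number of Nuclei>
 3
</Number of Nuclei>
<Number of Occupied Molecular Orbitals>
 5
</Number of Occupied Molecular Orbitals>
<Number of Perturbations>
 0
</Number of Perturbations>
<Net Charge>
 0
</Net Charge>
<Number of Electrons>
 10
</Number of Electrons>
<Number of Alpha Electrons>
 5
</Number of Alpha Electrons>
<Number of Beta Electrons>
 5
</Number of Beta Electrons>
<Electronic Spin Multiplicity>
 1
</Electronic Spin Multiplicity>
<Nuclear Names>
 O1
 H2
 H3
</Nuclear Names>
<Atomic Numbers>
 8
 1
 1
</Atomic Numbers>
<Nuclear Charges>
 8.0000000000e+00
 1.0000000000e+00
 1.0000000000e+00
</Nuclear Charges>
<Nuclear Cartesian Coordinates>
 0.000000000000e+00 0.000000000000e+00 0.000000000000e+00
 1.430428809104e+00 0.000000000000e+00 1.107157044568e+00
 -1.430428809104e+00 0.000000000000e+00 1.107157044568e+00
</Nuclear Cartesian Coordinates>
<Number of Primitives>
 21
</Number of Primitives>
<Primitive Centers>
 1 1 1 1 1 1 1 1 1 1 1 1 1 1 1 2 2 2 3 3 3
</Primitive Centers>
<Primitive Types>
 1 1 1 1 1 1 2 2 2 3 3 3 4 4 4 1 1 1 1 1 1
</Primitive Types>
<Primitive Exponents>
 1.307093200000e+02 2.380886100000e+01 6.443608300000e+00 5.033151300000e+00 1.169596100000e+00 3.803890000000e-01 5.033151300000e+00 1.169596100000e+00 3.803890000000e-01 5.033151300000e+00 1.169596100000e+00 3.803890000000e-01 5.033151300000e+00 1.169596100000e+00 3.803890000000e-01 3.425250910000e+00 6.239137300000e-01 1.688554000000e-01 3.425250910000e+00 6.239137300000e-01 1.688554000000e-01
</Primitive Exponents>
<Molecular Orbital Occupation Numbers>
 2.000000000000e+00
 2.000000000000e+00
 2.000000000000e+00
 2.000000000000e+00
 2.000000000000e+00
</Molecular Orbital Occupation Numbers>
<Molecular Orbital Energies>
 -1.883117795704e+01
 -9.320063523949e-01
 -4.402234982375e-01
 -2.266981843381e-01
 -1.404975058036e-01
</Molecular Orbital Energies>
<Molecular Orbital Spin Types>
 Alpha and Beta
 Alpha and Beta
 Alpha and Beta
 Alpha and Beta
 Alpha and Beta
</Molecular Orbital Spin Types>
<Molecular Orbital Primitive Coefficients>
<MO Number>
 1
</MO Number>
 -4.223859029617e+00 -4.085131855994e+00 -1.273157365132e+00 7.180723545506e-03 -9.604797736369e-03
 -7.248884759015e-03 -5.284858078765e-14 -3.323260620165e-14 -5.264603939732e-15 -3.329793093799e-14
 -2.093863278256e-14 -3.317031711891e-15 -8.118963685149e-03 -5.105422300708e-03 -8.087847879042e-04
 1.997978586725e-03 1.932357865069e-03 6.022315319641e-04 1.997978586720e-03 1.932357865063e-03
 6.022315319623e-04
<MO Number>
 2
</MO Number>
 -9.663004789374e-01 -9.345635925088e-01 -2.912626967576e-01 -1.910876112681e-01 2.555951144094e-01
 1.929014623916e-01 7.579025560259e-13 4.765894714342e-13 7.549979058888e-14 -8.488032969962e-13
 -5.337502973841e-13 -8.455502711377e-14 3.188009745298e-01 2.004706102861e-01 3.175791745939e-02
 4.797365225987e-02 4.639802692399e-02 1.446023810582e-02 4.797365225981e-02 4.639802692393e-02
 1.446023810580e-02
<MO Number>
 3
</MO Number>
 -6.072716435088e-13 -5.873265937014e-13 -1.830440741862e-13 -1.306465964942e-13 1.747503752678e-13
 1.318867264757e-13 -1.018003448595e+00 -6.401478945108e-01 -1.014101965703e-01 -1.039493546784e-13
 -6.536614451058e-14 -1.035509703414e-14 -1.187984110719e-12 -7.470362976062e-13 -1.183431179498e-13
 -1.229647496744e-01 -1.189261500290e-01 -3.706408570442e-02 1.229647496745e-01 1.189261500290e-01
 3.706408570445e-02
<MO Number>
 4
</MO Number>
 5.217623937388e-01 5.046257843779e-01 1.572698401580e-01 1.453836819877e-01 -1.944624174446e-01
 -1.467637000493e-01 -1.323902472432e-13 -8.325054118765e-14 -1.318828636135e-14 7.209865298911e-12
 4.533756832722e-12 7.182233598685e-13 1.265832351031e+00 7.959893607768e-01 1.260981067601e-01
 7.645858535029e-02 7.394741351849e-02 2.304617841915e-02 7.645858535064e-02 7.394741351883e-02
 2.304617841925e-02
<MO Number>
 5
</MO Number>
 -2.635391953842e-12 -2.548835921886e-12 -7.943609510918e-13 -6.534608464761e-13 8.740566628509e-13
 6.596636593256e-13 1.896706086622e-13 1.192699700116e-13 1.889436989097e-14 1.675450118114e+00
 1.053568007995e+00 1.669028980757e-01 -5.701464246830e-12 -3.585233761508e-12 -5.679613470929e-13
 -2.752913556208e-13 -2.662498085583e-13 -8.297843427025e-14 -1.888948966808e-13 -1.826909165582e-13
 -5.693677788345e-14
</Molecular Orbital Primitive Coefficients>
<Energy = T + Vne + Vee + Vnn>
 -7.527506699591e+01
</Energy = T + Vne + Vee + Vnn>
<Virial Ratio (-V/T)>
 2.009099529343e+00
</Virial Ratio (-V/T)>
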