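<Title>
 H2O HF/STO-3G TIP3P geometry (fixture)
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
 -2.024173908106e+01
 -1.268409041054e+00
 -6.179342964561e-01
 -4.529944726004e-01
 -3.912446557045e-01
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
 -4.226982071072e+00 -4.088152325201e+00 -1.274098713601e+00 6.359384374281e-03 -8.506190254466e-03
 -6.419749232136e-03 1.707701050107e-16 1.073848259736e-16 1.701156311539e-17 4.482585265905e-17
 2.818769940213e-17 4.465405825351e-18 -7.282177219310e-03 -4.579228509321e-03 -7.254268384737e-04
 1.653871998789e-03 1.599552961133e-03 4.985107819076e-04 1.653871998789e-03 1.599552961133e-03
 4.985107819076e-04
<MO Number>
 2
</MO Number>
 -9.897918676014e-01 -9.572834369685e-01 -2.983434810084e-01 -1.995486288843e-01 2.669124088760e-01
 2.014427940910e-01 -2.445581576704e-17 -1.537847341619e-17 -2.436208922125e-18 2.100166732276e-16
 1.320641215551e-16 2.092117874889e-17 2.171377350508e-01 1.365420363786e-01 2.163055579499e-02
 4.395546192257e-02 4.251180824617e-02 1.324907351245e-02 4.395546192257e-02 4.251180824617e-02
 1.324907351245e-02
<MO Number>
 3
</MO Number>
 5.739054947103e-16 5.550563128011e-16 1.729868355826e-16 2.177889666934e-16 -2.913103339861e-16
 -2.198562737224e-16 -1.016065804743e+00 -6.389294520446e-01 -1.012171747841e-01 2.094886708754e-15
 1.317320995029e-15 2.086858086977e-16 7.155040633139e-16 4.499281611238e-16 7.127619047619e-17
 -1.232360908079e-01 -1.191885793547e-01 -3.714587346111e-02 1.232360908079e-01 1.191885793547e-01
 3.714587346111e-02
<MO Number>
 4
</MO Number>
 -4.386982730820e-01 -4.242897970720e-01 -1.322326179754e-01 -1.285315995358e-01 1.719213960056e-01
 1.297516534403e-01 -2.785402007009e-15 -1.751535549917e-15 -2.774726995747e-16 -4.737907696983e-15
 -2.979323538437e-15 -4.719749737056e-16 -1.301396507383e+00 -8.183530569318e-01 -1.296408924859e-01
 -7.693992778151e-02 -7.441294695260e-02 -2.319126485385e-02 -7.693992778151e-02 -7.441294695260e-02
 -2.319126485385e-02
<MO Number>
 5
</MO Number>
 -1.059182445846e-15 -1.024394971635e-15 -3.192592182865e-16 -3.102417375994e-16 4.149733825760e-16
 3.131866293198e-16 6.220807879442e-16 3.911810978318e-16 6.196966726888e-17 1.675450118114e+00
 1.053568007995e+00 1.669028980757e-01 -3.234159654878e-15 -2.033726404796e-15 -3.221764786685e-16
 -5.473281479560e-17 -5.293519452627e-17 -1.649758767289e-17 -3.029118025684e-16 -2.929631018091e-16
 -9.130380081288e-17
</Molecular Orbital Primitive Coefficients>
<Energy = T + Vne + Vee + Vnn>
 -7.496292824650e+01
</Energy = T + Vne + Vee + Vnn>
<Virial Ratio (-V/T)>
 2.005014385011e+00
</Virial Ratio (-V/T)>
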