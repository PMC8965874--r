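[Molden Format]
[Title]
 H2O HF/STO-3G TIP3P geometry (fixture)
[Atoms] AU
 O     1    8       0.0000000000       0.0000000000       0.0000000000
 H     2    1       1.4304288091       0.0000000000       1.1071570446
 H     3    1      -1.4304288091       0.0000000000       1.1071570446
[GTO]
 1 0
 s    3 1.00
     1.3070932000e+02   1.5432897000e-01
     2.3808861000e+01   5.3532814000e-01
     6.4436083000e+00   4.4463454000e-01
 s    3 1.00
     5.0331513000e+00  -9.9967230000e-02
     1.1695961000e+00   3.9951283000e-01
     3.8038900000e-01   7.0011547000e-01
 p    3 1.00
     5.0331513000e+00   1.5591627000e-01
     1.1695961000e+00   6.0768372000e-01
     3.8038900000e-01   3.9195739000e-01

 2 0
 s    3 1.00
     3.4252509100e+00   1.5432897000e-01
     6.2391373000e-01   5.3532814000e-01
     1.6885540000e-01   4.4463454000e-01

 3 0
 s    3 1.00
     3.4252509100e+00   1.5432897000e-01
     6.2391373000e-01   5.3532814000e-01
     1.6885540000e-01   4.4463454000e-01

[MO]
 Sym= A
 Ene= -20.2417390811
 Spin= Alpha
 Occup= 2.00000000
    1   -9.941294579417e-01
    2   -2.656240176908e-02
    3    1.019249114995e-16
    4    2.675451341369e-17
    5   -4.346400492965e-03
    6    5.972072201874e-03
    7    5.972072201874e-03
 Sym= A
 Ene= -1.2684090411
 Spin= Alpha
 Occup= 2.00000000
    1   -2.327857644696e-01
    2    8.334911904885e-01
    3   -1.459656453071e-17
    4    1.253494036958e-16
    5    1.295996417340e-01
    6    1.587215893736e-01
    7    1.587215893736e-01
 Sym= A
 Ene= -0.6179342965
 Spin= Alpha
 Occup= 2.00000000
    1    1.349748706697e-16
    2   -9.096789396122e-16
    3   -6.064434827141e-01
    4    1.250342630977e-15
    5    4.270518445033e-16
    6   -4.450010839535e-01
    7    4.450010839535e-01
 Sym= A
 Ene= -0.4529944726
 Spin= Alpha
 Occup= 2.00000000
    1   -1.031759465941e-01
    2    5.368613982039e-01
    3   -1.662479817749e-15
    4   -2.827841692068e-15
    5   -7.767444063618e-01
    6   -2.778273072249e-01
    7   -2.778273072249e-01
 Sym= A
 Ene= -0.3912446557
 Spin= Alpha
 Occup= 2.00000000
    1   -2.491054972664e-16
    2    1.295843307252e-15
    3    3.712917389892e-16
    4    1.000000000000e+00
    5   -1.930322854683e-15
    6   -1.976382223113e-16
    7   -1.093803605758e-15
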