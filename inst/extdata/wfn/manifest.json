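{
 "h2_hf_sto3g": {
  "files": [
   "h2_hf_sto3g.wfx"
  ],
  "method": "HF",
  "basis": "STO-3G",
  "charge": 0,
  "nelec": 2,
  "scf_energy": -1.1167143250625706,
  "kinetic_energy": 1.2010794986302844,
  "dipole_au": [
   0.0,
   0.0,
   2.220446049250313e-15
  ],
  "dipole_D": 5.643809863897786e-15,
  "nuclei": [
   {
    "symbol": "H",
    "Z": 1,
    "xyz_bohr": [
     0.0,
     0.0,
     0.0
    ]
   },
   {
    "symbol": "H",
    "Z": 1,
    "xyz_bohr": [
     0.0,
     0.0,
     1.4
    ]
   }
  ],
  "components": {
   "T": 1.2010794986302844,
   "Ven": -3.7066736223019374,
   "Vee_coul": 1.3491881686467364,
   "Vee_xc": -0.6745940843233682,
   "Vnn": 0.714285714285714
  }
 },
 "he_hf_sto3g": {
  "files": [
   "he_hf_sto3g.wfx"
  ],
  "method": "HF",
  "basis": "STO-3G",
  "charge": 0,
  "nelec": 2,
  "scf_energy": -2.807783957539976,
  "kinetic_energy": 2.8235263652369675,
  "dipole_au": [
   0.0,
   0.0,
   0.0
  ],
  "dipole_D": 0.0,
  "nuclei": [
   {
    "symbol": "He",
    "Z": 2,
    "xyz_bohr": [
     0.0,
     0.0,
     0.0
    ]
   }
  ],
  "components": {
   "T": 2.8235263652369675,
   "Ven": -6.687023265512017,
   "Vee_coul": 2.111425885470146,
   "Vee_xc": -1.055712942735073,
   "Vnn": -2.220446049250313e-16
  }
 },
 "heh_cation_hf_sto3g": {
  "files": [
   "heh_cation_hf_sto3g.wfx"
  ],
  "method": "HF",
  "basis": "STO-3G",
  "charge": 1,
  "nelec": 2,
  "scf_energy": -2.8418364992870995,
  "kinetic_energy": 2.372321055004621,
  "dipole_au": [
   0.0,
   0.0,
   1.116717632591646
  ],
  "dipole_D": 2.8384125757692855,
  "nuclei": [
   {
    "symbol": "He",
    "Z": 2,
    "xyz_bohr": [
     0.0,
     0.0,
     0.0
    ]
   },
   {
    "symbol": "H",
    "Z": 1,
    "xyz_bohr": [
     0.0,
     0.0,
     1.4632
    ]
   }
  ],
  "components": {
   "T": 2.372321055004621,
   "Ven": -7.524156787379696,
   "Vee_coul": 1.8862641967453073,
   "Vee_xc": -0.9431320983726538,
   "Vnn": 1.3668671347153225
  }
 },
 "h2o_hf_sto3g": {
  "files": [
   "h2o_hf_sto3g.wfx",
   "h2o_hf_sto3g.molden"
  ],
  "method": "HF",
  "basis": "STO-3G",
  "charge": 0,
  "nelec": 10,
  "scf_energy": -74.96292824649854,
  "kinetic_energy": 74.58891073054859,
  "dipole_au": [
   5.551115123125783e-15,
   -8.383498711730633e-17,
   0.6789807918230268
  ],
  "dipole_D": 1.725796711693011,
  "nuclei": [
   {
    "symbol": "O",
    "Z": 8,
    "xyz_bohr": [
     0.0,
     0.0,
     0.0
    ]
   },
   {
    "symbol": "H",
    "Z": 1,
    "xyz_bohr": [
     1.4304288091039934,
     0.0,
     1.1071570445683019
    ]
   },
   {
    "symbol": "H",
    "Z": 1,
    "xyz_bohr": [
     -1.4304288091039934,
     0.0,
     1.1071570445683019
    ]
   }
  ],
  "components": {
   "T": 74.58891073054859,
   "Ven": -196.9600538301266,
   "Vee_coul": 47.3180635185282,
   "Vee_xc": -9.104813515610767,
   "Vnn": 9.194964850162068
  }
 },
 "h2o_b3lyp_sto3g": {
  "files": [
   "h2o_b3lyp_sto3g.wfx"
  ],
  "method": "B3LYP",
  "basis": "STO-3G",
  "charge": 0,
  "nelec": 10,
  "scf_energy": -75.27506699590799,
  "kinetic_energy": 74.59627599366142,
  "dipole_au": [
   2.2220003614847883e-12,
   8.872189226846937e-14,
   0.6602331714211189
  ],
  "dipole_D": 1.6781450225269432,
  "nuclei": [
   {
    "symbol": "O",
    "Z": 8,
    "xyz_bohr": [
     0.0,
     0.0,
     0.0
    ]
   },
   {
    "symbol": "H",
    "Z": 1,
    "xyz_bohr": [
     1.4304288091039934,
     0.0,
     1.1071570445683019
    ]
   },
   {
    "symbol": "H",
    "Z": 1,
    "xyz_bohr": [
     -1.4304288091039934,
     0.0,
     1.1071570445683019
    ]
   }
  ]
 },
 "h2o_b3lyp_ccpvtz": {
  "files": [
   "h2o_b3lyp_ccpvtz.wfx",
   "h2o_b3lyp_ccpvtz.molden"
  ],
  "method": "B3LYP",
  "basis": "cc-pVTZ (reconstructed contractions)",
  "charge": 0,
  "nelec": 10,
  "scf_energy": -76.42444220357925,
  "kinetic_energy": 76.24109455919037,
  "dipole_au": [
   5.643485678774596e-12,
   1.893382327840115e-12,
   0.7553815772659345
  ],
  "dipole_D": 1.9199881024893797,
  "nuclei": [
   {
    "symbol": "O",
    "Z": 8,
    "xyz_bohr": [
     0.0,
     0.0,
     0.0
    ]
   },
   {
    "symbol": "H",
    "Z": 1,
    "xyz_bohr": [
     1.4304288091039934,
     0.0,
     1.1071570445683019
    ]
   },
   {
    "symbol": "H",
    "Z": 1,
    "xyz_bohr": [
     -1.4304288091039934,
     0.0,
     1.1071570445683019
    ]
   }
  ],
  "hf_check_energy": -76.05770675912629,
  "hf_check_dipole_D": 2.027719581587296
 }
}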