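"""Validation anchors for the SCF engine (run manually)."""
import numpy as np
from mdscf import Basis, scf, becke_grid, ao_values

STO3G_H = [(3.42525091, 0.15432897), (0.62391373, 0.53532814),
           (0.16885540, 0.44463454)]
STO3G_HE = [(6.36242139, 0.15432897), (1.15892300, 0.53532814),
            (0.31364979, 0.44463454)]

# H2, R = 1.4 bohr (Szabo & Ostlund: E_HF = -1.1167 hartree)
atoms = [(1, np.array([0.0, 0.0, 0.0])), (1, np.array([0.0, 0.0, 1.4]))]
shells = [(0, 0, [e for e, c in STO3G_H], [c for e, c in STO3G_H]),
          (1, 0, [e for e, c in STO3G_H], [c for e, c in STO3G_H])]
b = Basis(atoms, shells)
res = scf(b, 2, 'hf', verbose=False)
print('H2/STO-3G  E =', res['E'], ' (expect about -1.1167)')
print('           T =', res['Ekin'], ' virial -V/T =', -(res['E'] - res['Ekin']) / res['Ekin'])

# He atom
atoms = [(2, np.array([0.0, 0.0, 0.0]))]
shells = [(0, 0, [e for e, c in STO3G_HE], [c for e, c in STO3G_HE])]
b = Basis(atoms, shells)
res = scf(b, 2, 'hf', verbose=False)
print('He/STO-3G  E =', res['E'], ' (expect about -2.8078)')

# grid sanity: integrate the He density on a Becke grid
pts, wts = becke_grid(atoms, 60, 16)
val, _ = ao_values(b, pts, deriv=0)
rho = np.einsum('pi,ij,pj->p', val, res['Dm'], val)
print('He grid N =', np.sum(wts * rho), ' (expect 2)')
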