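"""Append exact SCF energy components to the fixture manifest (HF fixtures)."""
import json
import os
import numpy as np
from mdscf import Basis, scf, eri_tensor
from make_fixtures import STO3G, make_basis, water_geom

OUT = os.path.join('..', '..', 'inst', 'extdata', 'wfn')

cases = {
    'h2_hf_sto3g': ([('H', 1, (0.0, 0.0, 0.0)), ('H', 1, (0.0, 0.0, 1.4))], 2),
    'he_hf_sto3g': ([('He', 2, (0.0, 0.0, 0.0))], 2),
    'heh_cation_hf_sto3g': ([('He', 2, (0.0, 0.0, 0.0)),
                             ('H', 1, (0.0, 0.0, 1.4632))], 2),
    'h2o_hf_sto3g': (water_geom(), 10),
}

with open(os.path.join(OUT, 'manifest.json')) as fh:
    manifest = json.load(fh)

for name, (geom, nelec) in cases.items():
    b = make_basis(geom, STO3G)
    res = scf(b, nelec, 'hf', verbose=False)
    S, T, V, _ = b.one_electron(with_scale=True)
    G = eri_tensor(b)
    D = res['Dm']
    J = np.einsum('ijkl,kl->ij', G, D)
    K = np.einsum('ikjl,kl->ij', G, D)
    comp = dict(T=float(np.sum(D*T)), Ven=float(np.sum(D*V)),
                Vee_coul=float(0.5*np.sum(D*J)),
                Vee_xc=float(-0.25*np.sum(D*K)))
    Enuc = res['E'] - comp['T'] - comp['Ven'] - comp['Vee_coul'] - comp['Vee_xc']
    comp['Vnn'] = float(Enuc)
    manifest[name]['components'] = comp
    print(name, comp)

with open(os.path.join(OUT, 'manifest.json'), 'w') as fh:
    json.dump(manifest, fh, indent=1)
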