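#!/usr/bin/env python
"""Generate the embedded per-element photon cross-section grids.

Writes inst/extdata/xsec/elements.csv with columns
  element, Z, A, energy_keV, photo_cm2_g, incoh_cm2_g
over 15-700 keV for every element appearing in the shipped material
compositions (plus lead).

Photoelectric mass coefficients are derived from Cromer-Liberman anomalous
scattering factors (f'') as implemented in gemmi, via
  sigma_pe = 2 * r_e * lambda * f''  [cm^2/atom].
Incoherent (Compton) mass coefficients use the free-electron Klein-Nishina
total cross section times Z/A electrons per gram. Coherent (Rayleigh)
scattering and binding corrections to incoherent scattering are omitted;
this is synthetic, approximate fixture data adequate for a simplified
transport model, not a reference attenuation library.
"""
import math
import gemmi

RE_CM = 2.8179403262e-13      # classical electron radius, cm
HC_KEV_CM = 1.23984193e-7     # h*c, keV*cm
NA = 6.02214076e23
MEC2 = 510.99895              # electron rest energy, keV

ELEMENTS = {
    # symbol: (Z, A)
    "H": (1, 1.008), "B": (5, 10.81), "C": (6, 12.011), "N": (7, 14.007),
    "O": (8, 15.999), "Na": (11, 22.990), "Mg": (12, 24.305),
    "Al": (13, 26.982), "Si": (14, 28.085), "P": (15, 30.974),
    "S": (16, 32.06), "Cl": (17, 35.45), "Ar": (18, 39.948),
    "K": (19, 39.098), "Ca": (20, 40.078), "Cr": (24, 51.996),
    "Mn": (25, 54.938), "Fe": (26, 55.845), "Zr": (40, 91.224),
    "Mo": (42, 95.95), "Pb": (82, 207.2),
}

# absorption edges (keV) inside or near the 15-700 keV window that need
# grid refinement so log-log interpolation does not smear the step
EDGES = {"Zr": [17.998], "Mo": [20.000], "Pb": [15.200, 15.861, 88.005]}

E_MIN, E_MAX, N_LOG = 15.0, 700.0, 64


def kn_sigma_cm2(e_kev):
    """Total Klein-Nishina cross section per free electron, cm^2."""
    k = e_kev / MEC2
    st = 6.6524587e-25  # Thomson cross section, cm^2
    t1 = (1 + k) / k**2 * (2 * (1 + k) / (1 + 2 * k) - math.log(1 + 2 * k) / k)
    t2 = math.log(1 + 2 * k) / (2 * k)
    t3 = -(1 + 3 * k) / (1 + 2 * k) ** 2
    return 0.75 * st * (t1 + t2 + t3)


def photo_cm2_g(z, a, e_kev):
    _, fpp = gemmi.cromer_liberman(z=z, energy=e_kev * 1000.0)
    fpp = max(fpp, 0.0)
    lam = HC_KEV_CM / e_kev
    return 2 * RE_CM * lam * fpp * NA / a


def grid_for(sym):
    es = [E_MIN * (E_MAX / E_MIN) ** (i / (N_LOG - 1)) for i in range(N_LOG)]
    for edge in EDGES.get(sym, []):
        if E_MIN < edge < E_MAX:
            es += [edge * (1 - 5e-4), edge * (1 + 5e-4)]
    return sorted(set(round(e, 6) for e in es))


def main():
    rows = []
    for sym, (z, a) in sorted(ELEMENTS.items(), key=lambda kv: kv[1][0]):
        incoh_per_g = NA * z / a
        for e in grid_for(sym):
            pe = photo_cm2_g(z, a, e)
            ic = kn_sigma_cm2(e) * incoh_per_g
            rows.append((sym, z, a, e, pe, ic))
    out = "inst/extdata/xsec/elements.csv"
    with open(out, "w") as fh:
        fh.write("# Synthetic photon cross-section grids, 15-700 keV.\n")
        fh.write("# photo_cm2_g: Cromer-Liberman f'' (gemmi) -> 2*r_e*lambda*f''*NA/A\n")
        fh.write("# incoh_cm2_g: free-electron Klein-Nishina * NA*Z/A\n")
        fh.write("# Coherent scattering and incoherent binding effects omitted.\n")
        fh.write("element,Z,A,energy_keV,photo_cm2_g,incoh_cm2_g\n")
        for sym, z, a, e, pe, ic in rows:
            fh.write(f"{sym},{z},{a},{e:.6g},{pe:.5g},{ic:.5g}\n")
    print(f"wrote {out}: {len(rows)} rows")


if __name__ == "__main__":
    main()
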