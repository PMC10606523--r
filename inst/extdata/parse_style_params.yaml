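# Solvation-style partial-charge and radius table, version 1.
#
# Charges are concentrated on polar and ionizable groups with apolar carbons
# neutral, and radii are Pauling van der Waals radii by element -- the
# conventions of solvation-calibrated continuum parameter sets. Every residue
# variant sums exactly to its integer formal charge, and each titratable
# residue carries both protonation forms whose sums differ by exactly +1 e.
# The table is a package-authored set in this style; swap in any published
# set by pointing assignParse() at another YAML of the same layout.
version: 1
radii:
  H: 1.0
  C: 1.7
  "N": 1.5
  O: 1.4
  S: 1.85
backbone:
  charges:
    "N": -0.40
    HN: 0.40
    CA: 0.0
    C: 0.55
    O: -0.55
  parents:
    HN: "N"
residues:
  GLY: {formal: 0, charges: {}}
  ALA: {formal: 0, charges: {CB: 0.0}}
  VAL: {formal: 0, charges: {CB: 0.0, CG1: 0.0, CG2: 0.0}}
  LEU: {formal: 0, charges: {CB: 0.0, CG: 0.0, CD1: 0.0, CD2: 0.0}}
  ILE: {formal: 0, charges: {CB: 0.0, CG1: 0.0, CG2: 0.0, CD1: 0.0}}
  PHE: {formal: 0, charges: {CB: 0.0, CG: 0.0, CD1: 0.0, CD2: 0.0, CE1: 0.0,
                             CE2: 0.0, CZ: 0.0}}
  MET: {formal: 0, charges: {CB: 0.0, CG: 0.0, SD: 0.0, CE: 0.0}}
  PRO: {formal: 0, charges: {CB: 0.0, CG: 0.0, CD: 0.40}}
  SER:
    formal: 0
    charges: {CB: 0.0, OG: -0.45, HG: 0.45}
    parents: {HG: OG}
  THR:
    formal: 0
    charges: {CB: 0.0, OG1: -0.45, HG1: 0.45, CG2: 0.0}
    parents: {HG1: OG1}
  ASN:
    formal: 0
    charges: {CB: 0.0, CG: 0.55, OD1: -0.55, ND2: -0.60, HD21: 0.30,
              HD22: 0.30}
    parents: {HD21: ND2, HD22: ND2}
  GLN:
    formal: 0
    charges: {CB: 0.0, CG: 0.0, CD: 0.55, OE1: -0.55, NE2: -0.60, HE21: 0.30,
              HE22: 0.30}
    parents: {HE21: NE2, HE22: NE2}
  TRP:
    formal: 0
    charges: {CB: 0.0, CG: 0.0, CD1: 0.0, CD2: 0.0, NE1: -0.35, HE1: 0.35,
              CE2: 0.0, CE3: 0.0, CZ2: 0.0, CZ3: 0.0, CH2: 0.0}
    parents: {HE1: NE1}
titratable:
  ASP:
    class: acid
    modelPka: 4.0
    deprotonated: {CB: 0.0, CG: 0.10, OD1: -0.55, OD2: -0.55}
    protonated: {CB: 0.0, CG: 0.10, OD1: -0.55, OD2: -0.10, HD2: 0.55}
    parents: {HD2: OD2}
  GLU:
    class: acid
    modelPka: 4.4
    deprotonated: {CB: 0.0, CG: 0.0, CD: 0.10, OE1: -0.55, OE2: -0.55}
    protonated: {CB: 0.0, CG: 0.0, CD: 0.10, OE1: -0.55, OE2: -0.10,
                 HE2: 0.55}
    parents: {HE2: OE2}
  TYR:
    class: acid
    modelPka: 9.6
    deprotonated: {CB: 0.0, CG: 0.0, CD1: 0.0, CD2: 0.0, CE1: 0.0, CE2: 0.0,
                   CZ: 0.25, OH: -1.25}
    protonated: {CB: 0.0, CG: 0.0, CD1: 0.0, CD2: 0.0, CE1: 0.0, CE2: 0.0,
                 CZ: 0.25, OH: -0.70, HH: 0.45}
    parents: {HH: OH}
  CYS:
    class: acid
    modelPka: 8.3
    deprotonated: {CB: 0.0, SG: -1.0}
    protonated: {CB: 0.0, SG: -0.45, HG: 0.45}
    parents: {HG: SG}
  LYS:
    class: base
    modelPka: 10.4
    deprotonated: {CB: 0.0, CG: 0.0, CD: 0.0, CE: 0.0, NZ: -0.70, HZ1: 0.35,
                   HZ2: 0.35}
    protonated: {CB: 0.0, CG: 0.0, CD: 0.0, CE: 0.25, NZ: -0.30, HZ1: 0.35,
                 HZ2: 0.35, HZ3: 0.35}
    parents: {HZ1: NZ, HZ2: NZ, HZ3: NZ}
  ARG:
    class: base
    modelPka: 12.0
    deprotonated: {CB: 0.0, CG: 0.0, CD: 0.10, NE: -0.40, HE: 0.35, CZ: 0.45,
                   NH1: -1.10, HH11: 0.35, NH2: -0.45, HH21: 0.35, HH22: 0.35}
    protonated: {CB: 0.0, CG: 0.0, CD: 0.10, NE: -0.40, HE: 0.35, CZ: 0.45,
                 NH1: -0.45, HH11: 0.35, HH12: 0.35, NH2: -0.45, HH21: 0.35,
                 HH22: 0.35}
    parents: {HE: NE, HH11: NH1, HH12: NH1, HH21: NH2, HH22: NH2}
  HIS:
    class: base
    modelPka: 6.3
    deprotonated: {CB: 0.0, CG: 0.10, ND1: -0.55, CD2: 0.10, CE1: 0.35,
                   NE2: -0.40, HE2: 0.40}
    protonated: {CB: 0.0, CG: 0.10, ND1: -0.40, HD1: 0.40, CD2: 0.10,
                 CE1: 0.80, NE2: -0.40, HE2: 0.40}
    parents: {HD1: ND1, HE2: NE2}
  NTER:
    class: base
    modelPka: 7.5
    deprotonated: {"N": -0.70, H1: 0.35, H2: 0.35}
    protonated: {"N": -0.30, H1: 0.45, H2: 0.45, H3: 0.40}
    parents: {H1: "N", H2: "N", H3: "N"}
  CTER:
    class: acid
    modelPka: 3.8
    deprotonated: {C: 0.10, O: -0.55, OXT: -0.55}
    protonated: {C: 0.10, O: -0.55, OXT: -0.10, HXT: 0.55}
    parents: {HXT: OXT}
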