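"""Batched RDKit back end for the kinoforge R package.

Reads SMILES (one per line) from an input file and writes a TSV to the
output file.  Modes:

  standardize   status, smiles          (largest organic fragment, canonical
                                         tautomer, stereo preserved)
  descriptors   status + 20 descriptor columns + element list
  validate      valid (0/1), smiles     (canonical form of parseable input)
  fingerprint   status, bits            (comma-separated Morgan on-bit indices)

Exit status is non-zero only on usage errors; per-molecule failures are
reported in the status column so the caller can keep row alignment.
"""
import sys
import os
import argparse

from rdkit import Chem, RDConfig, RDLogger
from rdkit.Chem import Descriptors, QED, rdMolDescriptors, AllChem
from rdkit.Chem.MolStandardize import rdMolStandardize

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

DESCRIPTOR_NAMES = [
    "aromatic_rings", "aromatic_carbocycles", "aromatic_heterocycles",
    "ring_count", "aliphatic_carbocycles", "aliphatic_heterocycles",
    "bridgehead_atoms", "molecular_weight", "logp", "qed", "sas",
    "labute_asa", "hall_kier_alpha", "hbd", "hba", "rotatable_bonds",
    "sp3_fraction", "stereocenters", "amide_bonds", "aromatic_atom_fraction",
]

AMIDE = Chem.MolFromSmarts("C(=O)N")
_TAUT = rdMolStandardize.TautomerEnumerator()
_UNCHARGER = rdMolStandardize.Uncharger()


def largest_organic_fragment(mol):
    """Largest fragment by heavy-atom count, ties broken by molecular
    weight; fragments without carbon are not eligible parents."""
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    best, best_key = None, None
    for f in frags:
        if not any(a.GetAtomicNum() == 6 for a in f.GetAtoms()):
            continue
        key = (f.GetNumHeavyAtoms(), Descriptors.MolWt(f))
        if best is None or key > best_key:
            best, best_key = f, key
    return best


def standardize_one(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return ("parse_error", "")
    parent = largest_organic_fragment(mol)
    if parent is None:
        return ("empty_parent", "")
    try:
        Chem.SanitizeMol(parent)
        parent = _UNCHARGER.uncharge(parent)
        parent = _TAUT.Canonicalize(parent)
        return ("ok", Chem.MolToSmiles(parent))
    except Exception:
        return ("standardize_error", "")


def descriptors_one(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return ("parse_error", None, "")
    try:
        heavy = mol.GetNumHeavyAtoms()
        n_aromatic = sum(1 for a in mol.GetAtoms() if a.GetIsAromatic())
        vals = [
            rdMolDescriptors.CalcNumAromaticRings(mol),
            rdMolDescriptors.CalcNumAromaticCarbocycles(mol),
            rdMolDescriptors.CalcNumAromaticHeterocycles(mol),
            rdMolDescriptors.CalcNumRings(mol),
            rdMolDescriptors.CalcNumAliphaticCarbocycles(mol),
            rdMolDescriptors.CalcNumAliphaticHeterocycles(mol),
            rdMolDescriptors.CalcNumBridgeheadAtoms(mol),
            Descriptors.MolWt(mol),
            Descriptors.MolLogP(mol),
            QED.qed(mol),
            sascorer.calculateScore(mol),
            rdMolDescriptors.CalcLabuteASA(mol),
            Descriptors.HallKierAlpha(mol),
            rdMolDescriptors.CalcNumHBD(mol),
            rdMolDescriptors.CalcNumHBA(mol),
            rdMolDescriptors.CalcNumRotatableBonds(mol),
            rdMolDescriptors.CalcFractionCSP3(mol),
            len(Chem.FindMolChiralCenters(mol, includeUnassigned=True,
                                          useLegacyImplementation=False)),
            len(mol.GetSubstructMatches(AMIDE)),
            (n_aromatic / heavy) if heavy else 0.0,
        ]
        elems = sorted({a.GetSymbol() for a in mol.GetAtoms()})
        return ("ok", vals, " ".join(elems))
    except Exception:
        return ("descriptor_error", None, "")


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("mode", choices=["standardize", "descriptors",
                                     "validate", "fingerprint"])
    ap.add_argument("infile")
    ap.add_argument("outfile")
    ap.add_argument("--radius", type=int, default=2)
    ap.add_argument("--nbits", type=int, default=2048)
    args = ap.parse_args()

    with open(args.infile) as fh:
        smiles = [line.rstrip("\n") for line in fh]

    out = open(args.outfile, "w")
    if args.mode == "standardize":
        out.write("status\tsmiles\n")
        for s in smiles:
            st, can = standardize_one(s)
            out.write(f"{st}\t{can}\n")
    elif args.mode == "descriptors":
        out.write("status\t" + "\t".join(DESCRIPTOR_NAMES) + "\telements\n")
        for s in smiles:
            st, vals, elems = descriptors_one(s)
            if vals is None:
                vals = [""] * len(DESCRIPTOR_NAMES)
            out.write(st + "\t" + "\t".join(repr(v) if isinstance(v, float)
                                            else str(v) for v in vals)
                      + "\t" + elems + "\n")
    elif args.mode == "validate":
        out.write("valid\tsmiles\n")
        for s in smiles:
            mol = Chem.MolFromSmiles(s) if s else None
            if mol is None:
                out.write("0\t\n")
            else:
                out.write("1\t" + Chem.MolToSmiles(mol) + "\n")
    elif args.mode == "fingerprint":
        out.write("status\tbits\n")
        gen = AllChem.GetMorganGenerator(radius=args.radius,
                                         fpSize=args.nbits)
        for s in smiles:
            mol = Chem.MolFromSmiles(s)
            if mol is None:
                out.write("parse_error\t\n")
            else:
                bits = list(gen.GetFingerprint(mol).GetOnBits())
                out.write("ok\t" + ",".join(str(b) for b in bits) + "\n")
    out.close()


if __name__ == "__main__":
    main()
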