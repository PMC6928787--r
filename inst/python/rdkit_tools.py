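"""RDKit helper for the lysoacc R package.

Reads a CSV with columns compound_id,smiles and writes a CSV back.
Two modes:
  standardize -- largest organic fragment, neutralize, canonical tautomer
  descriptors -- the fixed 97-descriptor panel, one row per compound

Rows that fail carry the message in an `error` column; the R side turns
non-empty error columns into a condition, so this script always exits 0
unless the invocation itself is malformed.
"""

import argparse
import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors
from rdkit.Chem.MolStandardize import rdMolStandardize
import rdkit

RDLogger.DisableLog("rdApp.*")

DESCRIPTOR_NAMES = [
    "Chi0", "Chi0n", "Chi0v", "Chi1", "Chi1n", "Chi1v", "Chi2n", "Chi2v",
    "Chi3n", "Chi3v", "Chi4n", "Chi4v", "EState_VSA1", "EState_VSA10",
    "EState_VSA11", "EState_VSA2", "EState_VSA3", "EState_VSA4",
    "EState_VSA5", "EState_VSA6", "EState_VSA7", "EState_VSA8",
    "EState_VSA9", "FractionCSP3", "HallKierAlpha", "HeavyAtomCount",
    "Ipc", "Kappa1", "Kappa2", "Kappa3", "LabuteASA", "MolLogP", "MolMR",
    "MolWt", "NHOHCount", "NOCount", "NumAliphaticCarbocycles",
    "NumAliphaticHeterocycles", "NumAliphaticRings",
    "NumAromaticCarbocycles", "NumAromaticHeterocycles",
    "NumAromaticRings", "NumHAcceptors", "NumHDonors", "NumHeteroatoms",
    "NumRotatableBonds", "NumSaturatedCarbocycles",
    "NumSaturatedHeterocycles", "NumSaturatedRings", "PEOE_VSA1",
    "PEOE_VSA10", "PEOE_VSA11", "PEOE_VSA12", "PEOE_VSA13", "PEOE_VSA14",
    "PEOE_VSA2", "PEOE_VSA3", "PEOE_VSA4", "PEOE_VSA5", "PEOE_VSA6",
    "PEOE_VSA7", "PEOE_VSA8", "PEOE_VSA9", "RingCount", "SMR_VSA1",
    "SMR_VSA10", "SMR_VSA2", "SMR_VSA3", "SMR_VSA4", "SMR_VSA5",
    "SMR_VSA6", "SMR_VSA7", "SMR_VSA8", "SMR_VSA9", "SlogP_VSA1",
    "SlogP_VSA10", "SlogP_VSA11", "SlogP_VSA12", "SlogP_VSA2",
    "SlogP_VSA3", "SlogP_VSA4", "SlogP_VSA5", "SlogP_VSA6", "SlogP_VSA7",
    "SlogP_VSA8", "SlogP_VSA9", "TPSA", "VSA_EState1", "VSA_EState10",
    "VSA_EState2", "VSA_EState3", "VSA_EState4", "VSA_EState5",
    "VSA_EState6", "VSA_EState7", "VSA_EState8", "VSA_EState9",
]

_FUNCS = dict(Descriptors.descList)


def _standardizers():
    return (
        rdMolStandardize.LargestFragmentChooser(),
        rdMolStandardize.Uncharger(),
        rdMolStandardize.TautomerEnumerator(),
    )


def run_standardize(rows, writer):
    frag, uncharge, taut = _standardizers()
    writer.writerow(["compound_id", "smiles", "error"])
    for cid, smi in rows:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            writer.writerow([cid, "", "unparseable structure"])
            continue
        try:
            mol = frag.choose(mol)
            mol = uncharge.uncharge(mol)
            mol = taut.Canonicalize(mol)
            writer.writerow([cid, Chem.MolToSmiles(mol), ""])
        except Exception as exc:  # pragma: no cover - defensive
            writer.writerow([cid, "", f"standardization failed: {exc}"])


def run_descriptors(rows, writer):
    writer.writerow(["compound_id"] + DESCRIPTOR_NAMES + ["error"])
    for cid, smi in rows:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            writer.writerow([cid] + [""] * len(DESCRIPTOR_NAMES)
                            + ["unparseable structure"])
            continue
        vals = []
        err = ""
        for name in DESCRIPTOR_NAMES:
            try:
                vals.append(repr(float(_FUNCS[name](mol))))
            except Exception as exc:
                vals.append("")
                err = f"descriptor {name} failed: {exc}"
                break
        if err:
            vals += [""] * (len(DESCRIPTOR_NAMES) - len(vals))
        writer.writerow([cid] + vals + [err])


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("mode", choices=["standardize", "descriptors", "version"])
    ap.add_argument("--infile")
    ap.add_argument("--outfile")
    args = ap.parse_args()

    if args.mode == "version":
        sys.stdout.write(rdkit.__version__ + "\n")
        return

    with open(args.infile, newline="") as fh:
        reader = csv.reader(fh)
        header = next(reader)
        idx_id = header.index("compound_id")
        idx_smi = header.index("smiles")
        rows = [(r[idx_id], r[idx_smi]) for r in reader]

    with open(args.outfile, "w", newline="") as fh:
        writer = csv.writer(fh)
        if args.mode == "standardize":
            run_standardize(rows, writer)
        else:
            run_descriptors(rows, writer)


if __name__ == "__main__":
    main()
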