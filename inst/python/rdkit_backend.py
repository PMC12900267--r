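"""Molecular perception backend.

Reads a JSON payload on stdin, writes a JSON payload on stdout. The R side
owns every scoring model; this script only exposes RDKit primitives:
parsing/canonicalization, per-atom tables, descriptor primitives, raw QED
properties, Morgan environment identifiers, conformer geometry and SMARTS
matching. Exit status is non-zero on malformed requests.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import (
    AllChem,
    Crippen,
    Descriptors,
    Lipinski,
    QED,
    rdMolDescriptors,
)

RDLogger.DisableLog("rdApp.*")

HYB_MAP = {
    Chem.HybridizationType.SP: "sp",
    Chem.HybridizationType.SP2: "sp2",
    Chem.HybridizationType.SP3: "sp3",
}


def _largest_fragment(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) == 1:
        return mol
    return max(frags, key=lambda m: m.GetNumHeavyAtoms())


def _parse_one(smi, keep_largest=True):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return None, "unparseable SMILES"
    if keep_largest:
        mol = _largest_fragment(mol)
        Chem.SanitizeMol(mol)
    return mol, None


def _stereocenter_indices(mol):
    centers = Chem.FindMolChiralCenters(
        mol, includeUnassigned=True, useLegacyImplementation=False
    )
    return {idx for idx, _ in centers}


def _atom_table(mol):
    stereo = _stereocenter_indices(mol)
    ri = mol.GetRingInfo()
    atoms = []
    for a in mol.GetAtoms():
        atoms.append(
            {
                "symbol": a.GetSymbol(),
                "hyb": HYB_MAP.get(a.GetHybridization(), "other"),
                "aromatic": a.GetIsAromatic(),
                "in_ring": ri.NumAtomRings(a.GetIdx()) > 0,
                "degree": a.GetDegree(),
                "stereocenter": a.GetIdx() in stereo,
            }
        )
    return atoms


def _ring_system_count(mol):
    ri = mol.GetRingInfo()
    rings = [set(r) for r in ri.AtomRings()]
    n = 0
    while rings:
        cur = rings.pop()
        merged = True
        while merged:
            merged = False
            for other in rings:
                if cur & other:
                    cur |= other
                    rings.remove(other)
                    merged = True
        n += 1
    return n


def _descriptors(mol):
    ri = mol.GetRingInfo()
    largest_ring = max((len(r) for r in ri.AtomRings()), default=0)
    return {
        "mw": Descriptors.MolWt(mol),
        "clogp": Crippen.MolLogP(mol),
        "tpsa": rdMolDescriptors.CalcTPSA(mol),
        "hbd_count": Lipinski.NumHDonors(mol),
        "hba_count": Lipinski.NumHAcceptors(mol),
        "rotatable_bonds": rdMolDescriptors.CalcNumRotatableBonds(mol),
        "ring_count": rdMolDescriptors.CalcNumRings(mol),
        "aromatic_ring_count": rdMolDescriptors.CalcNumAromaticRings(mol),
        "heavy_atom_count": mol.GetNumHeavyAtoms(),
        "fraction_csp3": rdMolDescriptors.CalcFractionCSP3(mol),
        "stereocenter_count": len(_stereocenter_indices(mol)),
        "heteroatom_count": rdMolDescriptors.CalcNumHeteroatoms(mol),
        "formal_charge": Chem.GetFormalCharge(mol),
        "ring_system_count": _ring_system_count(mol),
        "largest_ring_size": largest_ring,
        "nitrogen_count": sum(1 for a in mol.GetAtoms() if a.GetSymbol() == "N"),
        "oxygen_count": sum(1 for a in mol.GetAtoms() if a.GetSymbol() == "O"),
    }


def _qed_properties(mol):
    p = QED.properties(mol)
    return dict(p._asdict())


def _morgan_ids(mol, radius):
    fp = AllChem.GetMorganFingerprint(mol, radius)
    elems = fp.GetNonzeroElements()
    return {"ids": [str(k) for k in elems], "counts": list(elems.values())}


def cmd_parse(req):
    keep = req.get("keep_largest_fragment", True)
    out = []
    for smi in req["smiles"]:
        mol, err = _parse_one(smi, keep)
        if mol is None:
            out.append({"ok": False, "canonical": None, "error": err})
        else:
            out.append({"ok": True, "canonical": Chem.MolToSmiles(mol), "error": None})
    return {"results": out}


def cmd_mol(req):
    what = set(req.get("what", ["atoms"]))
    radius = int(req.get("radius", 2))
    out = []
    for smi in req["smiles"]:
        mol, err = _parse_one(smi)
        if mol is None:
            out.append({"ok": False, "error": err})
            continue
        rec = {"ok": True, "canonical": Chem.MolToSmiles(mol)}
        if "atoms" in what:
            rec["atoms"] = _atom_table(mol)
        if "descriptors" in what:
            rec["descriptors"] = _descriptors(mol)
        if "qed" in what:
            rec["qed"] = _qed_properties(mol)
        if "morgan" in what:
            rec["morgan"] = _morgan_ids(mol, radius)
        out.append(rec)
    return {"results": out}


def cmd_conformer(req):
    seed = int(req.get("seed", 1))
    n_confs = int(req.get("n_confs", 10))
    out = []
    for smi in req["smiles"]:
        mol, err = _parse_one(smi)
        if mol is None:
            out.append({"ok": False, "error": err})
            continue
        molh = Chem.AddHs(mol)
        params = AllChem.ETKDGv3()
        params.randomSeed = seed
        ids = AllChem.EmbedMultipleConfs(molh, numConfs=n_confs, params=params)
        if len(ids) == 0:
            out.append({"ok": False, "error": "3D embedding failed"})
            continue
        energies = []
        try:
            res = AllChem.MMFFOptimizeMoleculeConfs(molh, maxIters=500)
            energies = [e for _, e in res]
        except Exception:
            res = AllChem.UFFOptimizeMoleculeConfs(molh, maxIters=500)
            energies = [e for _, e in res]
        best = min(range(len(ids)), key=lambda i: energies[i])
        conf = molh.GetConformer(ids[best])
        coords = [
            [conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y, conf.GetAtomPosition(i).z]
            for i in range(molh.GetNumAtoms())
        ]
        masses = [a.GetMass() for a in molh.GetAtoms()]
        out.append({"ok": True, "coords": coords, "masses": masses})
    return {"results": out}


def cmd_smarts(req):
    pat = Chem.MolFromSmarts(req["pattern"])
    if pat is None:
        return {"ok_pattern": False, "matches": []}
    matches = []
    for smi in req["smiles"]:
        mol, err = _parse_one(smi)
        matches.append(bool(mol is not None and mol.HasSubstructMatch(pat)))
    return {"ok_pattern": True, "matches": matches}


def cmd_sdf(req):
    suppl = Chem.SDMolSupplier(req["path"], sanitize=True)
    out = []
    for mol in suppl:
        if mol is None:
            out.append({"ok": False, "canonical": None, "name": None})
            continue
        mol = _largest_fragment(mol)
        Chem.SanitizeMol(mol)
        name = mol.GetProp("_Name") if mol.HasProp("_Name") else ""
        out.append({"ok": True, "canonical": Chem.MolToSmiles(mol), "name": name})
    return {"results": out}


COMMANDS = {
    "parse": cmd_parse,
    "mol": cmd_mol,
    "conformer": cmd_conformer,
    "smarts": cmd_smarts,
    "sdf": cmd_sdf,
}


def main():
    if len(sys.argv) != 2 or sys.argv[1] not in COMMANDS:
        sys.stderr.write("usage: rdkit_backend.py {%s}\n" % "|".join(COMMANDS))
        return 2
    req = json.load(sys.stdin)
    res = COMMANDS[sys.argv[1]](req)
    json.dump(res, sys.stdout)
    return 0


if __name__ == "__main__":
    sys.exit(main())
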