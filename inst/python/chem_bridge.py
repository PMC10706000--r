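"""Batch RDKit worker for the moltwin R package.

Reads a JSON request {"op": ..., "smiles": [...], ...} from argv[1] and writes
a JSON response to argv[2].  One process call handles an arbitrary number of
molecules so the R side can batch and cache aggressively.
"""
import json
import sys
import os

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, QED, RDConfig
from rdkit.Chem import rdFingerprintGenerator
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402


def parse(smi):
    if not isinstance(smi, str) or smi == "":
        return None
    return Chem.MolFromSmiles(smi)


def properties(mol):
    return {
        "logP": Crippen.MolLogP(mol),
        "TPSA": Descriptors.TPSA(mol),
        "QED": QED.qed(mol),
        "SAS": sascorer.calculateScore(mol),
    }


def scaffold_smiles(mol):
    scaf = MurckoScaffold.GetScaffoldForMol(mol)
    if scaf is None or scaf.GetNumAtoms() == 0:
        return ""
    return Chem.MolToSmiles(scaf)


DESCRIPTOR_FNS = {
    "BertzCT": Descriptors.BertzCT,
    "MolWt": Descriptors.MolWt,
    "MolLogP": Crippen.MolLogP,
    "TPSA": Descriptors.TPSA,
    "NumHAcceptors": Descriptors.NumHAcceptors,
    "NumHDonors": Descriptors.NumHDonors,
    "NumRotatableBonds": Descriptors.NumRotatableBonds,
    "NumAromaticRings": Descriptors.NumAromaticRings,
    "NumAliphaticRings": Descriptors.NumAliphaticRings,
}


def op_canonicalize(req):
    out = {"canonical": [], "error": []}
    for smi in req["smiles"]:
        mol = parse(smi)
        if mol is None:
            out["canonical"].append(None)
            out["error"].append("could not parse SMILES %r" % smi)
        else:
            out["canonical"].append(Chem.MolToSmiles(mol))
            out["error"].append(None)
    return out


def op_record(req):
    """canonical SMILES + four conditioning properties + Bemis-Murcko scaffold."""
    recs = []
    for smi in req["smiles"]:
        mol = parse(smi)
        if mol is None:
            recs.append(None)
            continue
        rec = {"smiles": Chem.MolToSmiles(mol)}
        rec.update(properties(mol))
        rec["scaffold"] = scaffold_smiles(mol)
        recs.append(rec)
    return {"records": recs}


def op_graph(req):
    graphs = []
    for smi in req["smiles"]:
        mol = parse(smi)
        if mol is None:
            graphs.append(None)
            continue
        graphs.append({
            "symbols": [a.GetSymbol() for a in mol.GetAtoms()],
            "degree": [a.GetDegree() for a in mol.GetAtoms()],
            "numhs": [a.GetTotalNumHs() for a in mol.GetAtoms()],
            "impval": [a.GetImplicitValence() for a in mol.GetAtoms()],
            "bonds": [[b.GetBeginAtomIdx(), b.GetEndAtomIdx()]
                      for b in mol.GetBonds()],
        })
    return {"graphs": graphs}


def op_substructure(req):
    hits = []
    for smi, q in zip(req["smiles"], req["query"]):
        mol, query = parse(smi), parse(q)
        if mol is None or query is None:
            hits.append(None)
        else:
            hits.append(bool(mol.HasSubstructMatch(query)))
    return {"match": hits}


def op_morgan(req):
    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=int(req.get("radius", 2)), fpSize=int(req.get("nbits", 2048)))
    bits = []
    for smi in req["smiles"]:
        mol = parse(smi)
        if mol is None:
            bits.append(None)
        else:
            bits.append(list(gen.GetFingerprint(mol).GetOnBits()))
    return {"bits": bits}


def op_descriptors(req):
    names = req.get("names") or list(DESCRIPTOR_FNS)
    vals = []
    for smi in req["smiles"]:
        mol = parse(smi)
        if mol is None:
            vals.append(None)
        else:
            vals.append({k: float(DESCRIPTOR_FNS[k](mol)) for k in names})
    return {"descriptors": vals, "names": names}


OPS = {
    "canonicalize": op_canonicalize,
    "record": op_record,
    "graph": op_graph,
    "substructure": op_substructure,
    "morgan": op_morgan,
    "descriptors": op_descriptors,
}


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    res = OPS[req["op"]](req)
    with open(sys.argv[2], "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main()
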