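"""Chemistry worker behind the R bridge.

Reads one JSON request from argv[1], writes one JSON response to argv[2].
Each request is {"op": <name>, ...op-specific fields...}.  All operations are
batched: a single process invocation handles a whole vector of molecules so
the interpreter start-up cost is paid once per call, not per molecule.

Only RDKit and scikit-learn are used here; everything framework-level
(metrics, PCA, clustering, Markov model) lives on the R side.
"""

import json
import pickle
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def _largest_fragment(mol):
    """De-salt: keep the fragment with the most heavy atoms.

    Ties are broken by the lexicographically smallest canonical SMILES so the
    choice is deterministic.
    """
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) == 1:
        return frags[0]
    keyed = []
    for f in frags:
        try:
            Chem.SanitizeMol(f)
            smi = Chem.MolToSmiles(f, isomericSmiles=False)
        except Exception:
            continue
        keyed.append((-f.GetNumHeavyAtoms(), smi, f))
    if not keyed:
        return None
    keyed.sort(key=lambda t: (t[0], t[1]))
    return keyed[0][2]


def _standardize_one(smiles):
    """Canonical non-isomeric SMILES of the largest fragment, or None."""
    if not isinstance(smiles, str) or smiles.strip() == "":
        return None
    mol = Chem.MolFromSmiles(smiles)  # parse + sanitize
    if mol is None:
        return None
    mol = _largest_fragment(mol)
    if mol is None:
        return None
    Chem.RemoveStereochemistry(mol)
    return Chem.MolToSmiles(mol, isomericSmiles=False)


def op_standardize(req):
    return {"canonical": [_standardize_one(s) for s in req["smiles"]]}


def op_fingerprints(req):
    kind = req["kind"]
    nbits = int(req["nbits"])
    if kind == "morgan":
        gen = rdFingerprintGenerator.GetMorganGenerator(
            radius=int(req["radius"]), fpSize=nbits
        )

        def fp(mol):
            return list(gen.GetFingerprint(mol).GetOnBits())

    elif kind == "path":
        max_path = int(req["max_path"])

        def fp(mol):
            return list(
                Chem.RDKFingerprint(mol, maxPath=max_path, fpSize=nbits).GetOnBits()
            )

    else:
        raise ValueError("unknown fingerprint kind: %s" % kind)
    out = []
    for s in req["smiles"]:
        mol = Chem.MolFromSmiles(s) if isinstance(s, str) else None
        out.append(None if mol is None else fp(mol))
    return {"bits": out, "nbits": nbits}


def _dense(features, nbits):
    import numpy as np

    x = np.zeros((len(features), nbits), dtype=np.float64)
    for i, bits in enumerate(features):
        if bits:
            x[i, bits] = 1.0
    return x


def op_rf_train(req):
    import numpy as np
    from sklearn.ensemble import RandomForestClassifier
    from sklearn.metrics import balanced_accuracy_score
    from sklearn.model_selection import train_test_split

    x = _dense(req["features"], int(req["nbits"]))
    y = np.asarray(req["labels"], dtype=int)
    seed = int(req["seed"])
    test_fraction = float(req.get("test_fraction", 0.3))
    strat = y if req.get("stratify", True) else None
    x_tr, x_te, y_tr, y_te = train_test_split(
        x, y, test_size=test_fraction, random_state=seed, stratify=strat
    )
    if len(set(y_tr)) < 2 or len(set(y_te)) < 2:
        raise ValueError("class starvation after the train/test split")
    clf = RandomForestClassifier(
        n_estimators=int(req.get("n_estimators", 100)),
        max_depth=int(req.get("max_depth", 20)),
        random_state=seed,
    )
    clf.fit(x_tr, y_tr)
    bal = balanced_accuracy_score(y_te, clf.predict(x_te))
    with open(req["model_path"], "wb") as fh:
        pickle.dump({"clf": clf, "nbits": int(req["nbits"])}, fh)
    return {
        "balanced_accuracy": float(bal),
        "n_train": int(len(y_tr)),
        "n_test": int(len(y_te)),
    }


def op_rf_score(req):
    with open(req["model_path"], "rb") as fh:
        blob = pickle.load(fh)
    clf = blob["clf"]
    nbits = blob["nbits"]
    feats = req["features"]
    known = [i for i, f in enumerate(feats) if f is not None]
    proba = [None] * len(feats)
    if known:
        x = _dense([feats[i] for i in known], nbits)
        active_col = list(clf.classes_).index(1)
        p = clf.predict_proba(x)[:, active_col]
        for j, i in enumerate(known):
            proba[i] = float(p[j])
    return {"proba": proba}


OPS = {
    "standardize": op_standardize,
    "fingerprints": op_fingerprints,
    "rf_train": op_rf_train,
    "rf_score": op_rf_score,
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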