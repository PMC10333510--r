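"""2-D UMAP projection of a feature CSV (no header). Usage:
python umap_embed.py <in.csv> <out.csv> <seed> <n_neighbors> <min_dist>
"""
import sys

import numpy as np
import umap


def main():
    fin, fout, seed, n_neighbors, min_dist = sys.argv[1:6]
    X = np.loadtxt(fin, delimiter=",", ndmin=2)
    emb = umap.UMAP(
        n_components=2,
        n_neighbors=int(n_neighbors),
        min_dist=float(min_dist),
        random_state=int(seed),
    ).fit_transform(X)
    np.savetxt(fout, emb, delimiter=",")


if __name__ == "__main__":
    main()
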