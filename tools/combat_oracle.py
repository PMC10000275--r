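#!/usr/bin/env python
"""Independent numpy implementation of parametric empirical-Bayes
location/scale batch correction (Johnson, Li & Rabinovic 2007), used only
at development time to freeze expected outputs for the R implementation's
tests.

Usage: python tools/combat_oracle.py input.tsv batch.txt output.tsv
input.tsv: gene_id + one column per sample (values already on the
additive scale); batch.txt: one batch label per sample line.
"""
import sys

import numpy as np
import pandas as pd


def combat(Y, batch, tol=1e-4, max_iter=100):
    batches = sorted(set(batch))
    batch = np.asarray(batch)
    n = Y.shape[1]
    design = np.column_stack([(batch == b).astype(float) for b in batches])
    n_i = design.sum(axis=0)
    # per-gene OLS batch means
    B_hat = np.linalg.lstsq(design, Y.T, rcond=None)[0]  # nbatch x G
    alpha = (n_i / n) @ B_hat
    resid = Y - (design @ B_hat).T
    sigma2 = (resid ** 2).mean(axis=1)
    sig = np.sqrt(sigma2)
    Z = (Y - alpha[:, None]) / sig[:, None]
    Ystar = Y.copy()
    for j, b in enumerate(batches):
        cols = batch == b
        ni = cols.sum()
        Zi = Z[:, cols]
        g_hat = Zi.mean(axis=1)
        d_hat = Zi.var(axis=1, ddof=1)
        g_bar, t2 = g_hat.mean(), g_hat.var(ddof=1)
        m, s2 = d_hat.mean(), d_hat.var(ddof=1)
        a_prior = (2 * s2 + m ** 2) / s2
        b_prior = (m * s2 + m ** 3) / s2
        g_old, d_old = g_hat.copy(), d_hat.copy()
        sse0 = (Zi ** 2).sum(axis=1)
        sum_z = Zi.sum(axis=1)
        for _ in range(max_iter):
            g_new = (ni * t2 * g_hat + d_old * g_bar) / (ni * t2 + d_old)
            sse = sse0 - 2 * g_new * sum_z + ni * g_new ** 2
            d_new = (b_prior + 0.5 * sse) / (ni / 2 + a_prior - 1)
            change = max(
                np.max(np.abs(g_new - g_old) / np.maximum(np.abs(g_old), 1e-8)),
                np.max(np.abs(d_new - d_old) / np.maximum(np.abs(d_old), 1e-8)),
            )
            g_old, d_old = g_new, d_new
            if change <= tol:
                break
        Ystar[:, cols] = ((Zi - g_old[:, None]) / np.sqrt(d_old)[:, None]
                          * sig[:, None] + alpha[:, None])
    return Ystar


def main():
    inp, batchf, outp = sys.argv[1:4]
    df = pd.read_csv(inp, sep="\t")
    genes = df["gene_id"]
    Y = df.drop(columns="gene_id").to_numpy(float)
    batch = [line.strip() for line in open(batchf)]
    Ystar = combat(Y, batch)
    out = pd.DataFrame(Ystar, columns=df.columns[1:])
    out.insert(0, "gene_id", genes)
    out.to_csv(outp, sep="\t", index=False, float_format="%.10g")


if __name__ == "__main__":
    main()
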