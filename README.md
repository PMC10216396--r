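# fodm — fuzzy-oil-drop analysis of hydrophobicity distributions

`fodm` asks a simple structural question of a protein — or of an amyloid
fibril and its parts: *is hydrophobicity organized like a micelle, with a
centric hydrophobic core and a polar shell, and if not, how strong an
external (non-aqueous) field would it take to explain the organization
that is there?*

It is aimed at structural bioinformaticians working on protein folding,
amyloid polymorphism and membrane proteins, who want the per-residue
hydrophobicity profiles and the two summary parameters of the
fuzzy-oil-drop family of models, computed reproducibly from PDB/mmCIF
files or from seeded synthetic fixtures.

## The model in brief

Each residue becomes an *effective atom* (mean heavy-atom position). Over
a structural unit (single chain, proto-fibril, or super-fibril) four
unit-sum per-residue distributions are compared:

* **T** — a 3D Gaussian spanned over the unit (center = mean position,
  principal axes, σ = half-extent/3 per axis): the idealized micelle;
* **O** — observed hydrophobicity from pairwise interactions,
  `(H_i + H_j) · [1 − ½(7u² − 9u⁴ + 5u⁶ − u⁸)]` with `u = r_ij/c`,
  summed over pairs within the cutoff `c` (Levitt's attenuation);
* **R** — uniform `1/N`: no core at all;
* **M** — `T + K·(T_max − T)_n`, renormalized: the micelle field blended
  with its membrane-like complement.

Kullback–Leibler divergences (bits) give the relative-distance statistic

```
RD = D_KL(O|T) / ( D_KL(O|T) + D_KL(O|R) )
```

with `RD < 0.5` indicating a centric hydrophobic core, and the
environment parameter `K = argmin_K D_KL(O | M(K))`, with `K = 0` meaning
purely water-like ordering. A stepwise elimination procedure identifies
the residues responsible when `RD ≥ 0.5`.

## Worked example

Generate a seeded synthetic globule with a planted centric core, then
analyze it (the same works on any PDB/mmCIF file):

```r
library(fodm)
u   <- generate_unit(synthetic_spec("micelle", n_residues = 40, seed = 3))
res <- analyze_unit(u)
res
#> FOD result (chain, N = 40): RD = 0.142, K = 0.1
#>   DKL(O|T) = 0.0808  DKL(O|R) = 0.4878  DKL(O|M) = 0.0482 bits
#>   core status: micelle-like hydrophobic core (RD < 0.5)
```

`RD = 0.142` says the observed distribution is far closer to the Gaussian
micelle target than to uniform dispersion — the planted core is detected —
and `K = 0.1` says essentially no external-field modification is needed.
An `inverted` fixture (hydrophobicity forced to the surface) gives the
mirror image: `RD = 0.978, K = 10.0` under the same seed conventions.

Per-residue output and plots:

```r
profile_table(res$profile)          # chain, seq_id, aa, T, O, M, O−T
discordant_residues(res$profile)    # residues ranked by O−T excess
plot_profile(res)                   # T/O/M along the sequence
```

The same pipeline from the shell, via the thin CLI:

```sh
Rscript inst/cli/fod.R simulate --kind micelle --n 40 --seed 3 --out-prefix mic
Rscript inst/cli/fod.R analyze  --structure mic.pdb --chains A --out-prefix mic --plot
Rscript inst/cli/fod.R batch    --catalog inst/extdata/catalog_table1.tsv --structure-dir pdb/
Rscript inst/cli/fod.R eliminate --structure mic.pdb --chains A --segment 1-3
```

`batch` consumes a tab-separated catalog (accession / chain groups /
fragment / levels — one is shipped in `inst/extdata/catalog_table1.tsv`
covering a published α-synuclein amyloid structure list), writes a
summary table ordered by ascending single-chain RD, and isolates per-row
failures.

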