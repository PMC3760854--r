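# SLiMBind

Short linear motifs (SLiMs) are 3–12-residue patterns inside intrinsically
disordered protein regions that bind structured domains and mediate a large
share of transient protein–protein interactions. Given the structure of a
peptide-binding domain with a bound peptide, SLiMBind predicts, residue by
residue, which positions of a 50-residue disordered candidate window are the
ones doing the binding. It is aimed at structural bioinformaticians who have
(or suspect) a domain–peptide interaction and want to refine *where* in a
disordered region the binding residues sit.

## Method

The pipeline combines fragment docking with a recurrent sequence labeller:

1. **Window extraction.** A 50-residue window is cut around the candidate
   motif (motif centred, unless it falls within 25 residues of either
   terminus, in which case the terminal 50 residues are used); windows must
   be disordered (mean disorder > 0.5).
2. **Fragment docking.** All overlapping tripeptides (L − k + 1 = 48 of them
   for a 50-residue window, k = 3) are docked into a search box derived from
   the bound peptide chain of the receptor structure (bounding box, padded,
   clamped to a maximum edge; the peptide chain is then stripped). Only each
   fragment's best pose (minimum affinity, kcal/mol) is kept.
3. **Residue track.** Each residue takes the best score over the fragments
   covering it, and the track is normalised per region to [0, 1]:
   `v_i = clamp(−s_i, 0, |s_min|) / |s_min|`, so the most favourable residue
   scores 1 and anything at or above 0 kcal/mol scores 0.
4. **BRNN.** A bidirectional recurrent neural network reads 26 channels per
   residue — a 20-way amino-acid one-hot, a sequence-length channel, three
   secondary-structure probabilities, disorder, and the normalised docking
   score — through forward/backward hidden chains
   `h^f_j = N_fwd(i_j, h^f_{j−1})`, `h^b_j = N_bwd(i_j, h^b_{j+1})` (zero
   boundary states) and a windowed output network
   `o_j = N_out(i_{j−w..j+w}, h^f_j, h^b_j)` squashed to (0, 1). Training is
   full-batch gradient descent on per-residue cross-entropy with the
   learning rate halved after 50 stagnant epochs; evaluation is ten-fold
   cross-validation with a 3-model ensemble per fold (input windows 7/9/11).
5. **Evaluation.** Residue-level ROC curves (positive call: score ≥
   threshold, thresholds descending from 1 to 0) and the trapezoidal AUC,
   which equals the Mann–Whitney probability that a random binding residue
   outranks a random non-binding one.

A deterministic mock docking engine and synthetic-fixture generators (planted
binding spans, coil-tilted secondary-structure tracks, toy receptor+peptide
PDB files) make the whole pipeline runnable and testable offline; an adapter
for an external AutoDock Vina binary is provided for real docking.

## Worked example

```r
library(SLiMBind)
dir.create("demo")
# toy receptor with a bound peptide chain B, query with a CORNR-box motif
genToyPDB("demo/receptor.pdb", peptideLength = 4, seed = 42)
writeFasta(c(demo = paste0(strrep("A", 60), "LADHICQII", strrep("G", 60))),
           "demo/query.fasta")

res <- runDock("demo/query.fasta", motifStart = 61, motifEnd = 69,
               receptorPdb = "demo/receptor.pdb", peptideChain = "B",
               engine = "mock", outDir = "demo", seed = 42)
paste(regionSpan(res$region), collapse = "-")   # "41-90": the 50-residue window
nrow(res$fragments)                             # 48 tripeptides (L - k + 1)
round(res$normalized[21:29], 2)
#> 0.98 1.00 1.00 1.00 0.97 0.98 0.98 0.98 0.98

corpus <- syntheticCorpus(n = 20, effect = 2, sigma = 0.1, seed = 42)
ds <- lapply(corpus, function(d) list(x = d$x, y = d$y))
cv <- crossValidate(ds, folds = 5, windows = 9L, epochs = 150, lr = 0.2,
                    seed = 42)
aucFromScores(unlist(cv$predictions), unlist(lapply(ds, `[[`, "y")))
#> 0.945
```

The normalised docking track peaks (≈ 1) over the planted motif residues
41–49 of the window, and the cross-validated BRNN ranks binding residues
above non-binding ones with an out-of-fold AUC of 0.945 on this small
synthetic corpus — scores close to 1 mean confident binding calls; 0.5 would
be random. `runPredict()` additionally averages per-residue scores over the
nine residues of each motif match (default decision threshold 0.4), and
`cornrInstances()` ships the CORNR-box proteome-scan table used by the motif
workflow. A command-line front-end with `dock`, `train`, `predict`,
`simulate` and `evaluate` subcommands lives at `inst/scripts/slimbind.R`.

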