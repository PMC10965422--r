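# flexcdr

Sequence–structure co-design of antibody CDR loops at C-alpha
resolution, with flexible-CDR anchor augmentation and an
E(3)-equivariant graph neural network.

## What this is for

The complementarity determining regions (CDRs) — six hypervariable
loops, three per antibody chain — do most of the work of antigen
binding, and designing them means solving sequence and backbone
geometry *together*: a loop conformation constrains which residues
fit, and vice versa. `flexcdr` is aimed at structural bioinformatics
work on this co-design problem: it implements the full pipeline —
data preparation from antibody–antigen complex structures, masked
graph encoding, an equivariant network that inpaints the masked loop,
the complete training objective, evaluation metrics, and design-time
sequence sampling — as an ordinary, fully tested R package that runs
end to end on synthetic antibody-like complexes in minutes on one
CPU.

## The method in brief

**Flexible-CDR augmentation.** CDR boundaries are a convention of the
numbering scheme (Chothia, IMGT, ...). For a located CDR with anchors
at its two flanks, every anchor shift $(\delta_s,\delta_e)\in[-k,k]^2$
that keeps a non-empty window and both anchors on the chain defines
an augmented training CDR: up to $(2k+1)^2$ variants per loop (49 at
$k=3$, 121 at the study default $k=5$).

**Masked complex graph.** One sample = the design chain, its partner
antibody chain, and antigen residues within 16 Å. Each residue node
carries its C-alpha coordinate and a learnable amino-acid + chain-type
embedding (256 + 2 wide by default). The CDR's tokens become MASK and
its coordinates are initialised on evenly spaced points of the
anchor–anchor line, $x_i = a + (b-a)\,i/(n+1)$. Nodes connect to
their 64 nearest neighbours.

**Equivariant stack with coordinate masking.** $N = 16$ EGNN layers
(messages $\phi_e(f_i, f_j, \lVert x_i - x_j\rVert^2)$, coordinate
updates along difference vectors, residual feature updates) followed
by a feed-forward head producing 20-way amino-acid logits. After
every layer,

$$\tilde{x}^k = x^k \odot M + x^{\mathrm{input}} \odot (1-M),$$

so non-CDR coordinates stay *exactly* at their input values at every
depth; only the loop moves.

**Local loss suite.** With structure weight 10:

$$L = 10\,(L_{\mathrm{RMSD}} + L_{\mathrm{repulsion}} +
L_{\mathrm{neighbor}}) + (L_{\mathrm{CE,CDR}} +
L_{\mathrm{CE,nonCDR}})$$

where $L_{\mathrm{RMSD}}$ averages the CDR C-alpha RMSD over **all**
layers; the clash hinge $\max(\tau - d_{ij}, 0)$ with $\tau = 4.2$ Å
and the consecutive-distance deviation along the anchor–loop–anchor
path act on layers 5..N; and label-smoothed (0.1) cross-entropy on
the shared head applies to all layers for non-CDR residues and to the
last four layers for the CDR. Training is Adam, one CDR–antigen pair
per step, with validation checkpointing (best Top-1 AAR, RMSD
tie-break). The forward *and* analytic backward passes are written in
plain R and verified against finite differences — no deep-learning
framework is involved.

**Metrics.** Fixed-frame CDR C-alpha RMSD (no superposition — the
mask pins the frame) and Top-1 / Top-3 amino-acid recovery (AAR),
pooled over residues.

## Worked example

Generate synthetic antibody-like complexes (helix framework, arc
loops whose geometry and sequence are selected by the flanking
"flank-code" residues), train a small model, evaluate, and design:

```r
library(flexcdr)

ds    <- make_toy_dataset(toy_spec(n_complexes = 60, seed = 7))
pairs <- build_pair_dataset(ds$complexes, k = 0, cdr_names = "HCDR3")

cfg <- model_config(n_layers = 4, aa_embed_dim = 32, chain_embed_dim = 2,
                    hidden_dim = 32, k_neighbors = 16)
fit <- train(pairs[1:50], cfg,
             train_config(learning_rate = 2e-3, max_steps = 800,
                          val_every = 200, seed = 5),
             val_pairs = pairs[51:55], verbose = TRUE)
#> step 0: val top1 0.0%, rmsd 7.539
#> step 200: val top1 28.2%, rmsd 4.171
#> step 400: val top1 33.3%, rmsd 4.379
#> step 600: val top1 35.9%, rmsd 3.793
#> step 800: val top1 30.8%, rmsd 3.527

evaluate(fit, pairs[56:60])
#>   cdr_name n mean_rmsd top1_aar top3_aar
#> 1    HCDR3 5  2.829667 23.25581 48.83721
```

The validation lines show the loop moving off its straight-line
initialisation (RMSD 7.5 Å → 3.5 Å) while sequence recovery climbs
from 0% towards the deterministic optimum; the held-out report gives
the same metrics per CDR type. For comparison, the anchor-line
baseline here is 7.89 Å — the model has recovered most of the loop
geometry even in this 800-step run (the longer experiment in the test
suite reaches >60% Top-1 AAR). Designing a CDR with the fitted model:

```r
cx  <- ds$complexes[[56]]
res <- design_cdr(fit, cx, locate_cdr(cx$chains$H, "HCDR3"),
                  n_samples = 3, seed = 42)
res
#> <design_result> HCDR3 on chain H: 9 residues, 3 samples
#>   EGEPIIQEN
#>   AMRKGSLLI
#>   LNPGQYISS
```

Each sampled sequence is drawn position-wise from the predicted
20-way distributions; `assemble_design_chain()` installs a chosen
sequence and the predicted loop coordinates back into the complex,
and `write_complex_pdb()` / `full_atom_adapter()` hand the result to
external full-atom tools.

A thin command-line front end with `fixtures` / `train` / `design`
subcommands is installed at `inst/cli/flexcdr`.

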