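# spotgat

Spot-level gene expression from tissue images via graph attention.

Spatial transcriptomics measures gene expression in small tissue spots
together with their positions on an H&E section, but most large cohorts
(e.g. TCGA-style studies) provide only a whole-slide image (WSI) and one
bulk RNA-seq vector per sample. `spotgat` implements a three-stage transfer
framework that brings spot-level resolution to such bulk-only cohorts:

1. **SEG — spot embedding generator.** A CNN encodes each 224×224 spot
   patch; a dual-coefficient multi-head graph-attention layer mixes
   information over the spatial neighbor graph. For spot *j* with neighbor
   set *N(j)*, per head:

   score(j,k) = ReLU(aₛᵀ Wₛ E2ⱼ + aₙᵀ Wₙ E2ₖ),
   αₙ(j,·) = softmax over k ∈ N(j),
   αₛ(j) = 1 / (1 + Σₖ αₙ(j,k)),
   E3ⱼ = ‖ₗ f(αₛ W′ₛ E2ⱼ + Σₖ αₙ(j,k) W′ₙ E2ₖ).

   Two FC layers map E3 to expression; training minimizes MSE against the
   measured spot expression.
2. **GEP — gene expression predictor.** For a bulk-only sample, the frozen
   SEG embeds the WSI spots; the bulk vector is encoded by two FC layers;
   alignment matrices W_spots / W_bulk plus z-score normalization make the
   two embeddings commensurate; the normalized bulk embedding is broadcast
   onto every spot and three FC layers decode per-spot expression. The
   training loss is MSE between the predicted spot-average and the true
   bulk profile.
3. **SLP — spot label predictor.** A CNN softmax classifier of spot patches
   into tumor / non-tumor; the decision threshold maximizes Youden's
   J = sensitivity + specificity − 1 on a validation split, and epochs are
   selected by validation F1. Downstream profiles are then computed from
   predicted-tumor spots only (`tumor_average_expression`).

Supporting modules: patch extraction from coordinate-anchored spots and
coordinate-free WSIs (512-tile scan, mean-RGB < 220 foreground rule),
row-normalized spatial adjacency, evaluation metrics (flattened Pearson r,
MSE, Mann–Whitney AUROC, Welch-t marker ranking) and a seeded
synthetic-tissue generator so the whole pipeline trains and tests in
minutes without any external data. The neural-network core (im2col
convolution, max-pool, manual backprop, Adam) is implemented in vectorized
R over BLAS and validated against finite differences and loop oracles.

## Worked example

```r
library(spotgat)

cfg <- sim_config(grid = c(8, 8), n_genes = 20, spot_spacing = 16,
                  margin = 24, seed = 7)
cohort <- simulate_cohort(3, cfg)
train <- lapply(cohort[1:2], function(s) list(
  patches = crop_spot_patches(s$image, s$spots, half_side = 12),
  adj     = build_adjacency(s$spots, threshold = 0.15),
  expr    = s$expr))

seg_cfg <- seg_config(n_genes = 20, patch_side = 24,
                      conv_channels = c(8, 16), pool = c(TRUE, TRUE),
                      embed_cnn = 32, embed_attn = 16, n_heads = 2,
                      head_hidden = 32, epochs = 60, seed = 1)
seg <- train_seg(train, seg_cfg)

held <- cohort[[3]]
pred <- seg_forward(crop_spot_patches(held$image, held$spots, half_side = 12),
                    build_adjacency(held$spots, threshold = 0.15), seg)
round(c(r = sample_correlation(pred, held$expr),
        mse = sample_mse(pred, held$expr)), 3)
#>      r    mse
#>  0.837 38.337
```

The held-out correlation of ~0.84 means the encoder has learned the
planted image-to-expression map (dark tumor texture drives the marker
genes) well beyond the ≈0 correlation of an untrained network; the MSE is
on the squared scale of the simulated expression values.

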