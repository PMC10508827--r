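# pbnrr — physics-based non-rigid registration for intra-operative brain shift

During a craniotomy the brain deforms by several millimetres (CSF
drainage, gravity, pressure changes, tumour resection), invalidating the
rigid alignment between the pre-operative MRI — which carries the fMRI
overlays, tractography and surgical plan — and the patient's
intra-operative anatomy. `pbnrr` registers the pre-operative (floating)
image to an intra-operative (fixed) MRI with the physics-based approach
used in image-guided neurosurgery, and is aimed at researchers working on
deformable registration methodology and its evaluation.

The method, in brief:

1. **Feature selection** — voxels whose surrounding block has high
   intensity variance become registration points.
2. **Block matching** — for each point, every integer displacement
   `|d_a| ≤ W_a` is scored by normalized cross-correlation between the
   floating block (half-extent `B`) and the displaced fixed block; the
   argmax gives a sparse displacement `D` with confidence weights `S`
   (`max(NCC, 0)² I₃` per match).
3. **Biomechanical solve** — a linear-elastic tetrahedral finite-element
   model of the brain (stiffness `K`, per-tissue `E`, `ν`) regularises
   the sparse field through

   `[K + HᵀSH] U = HᵀSD (+ F)`

   where `H` interpolates mesh displacements to the match points. Over
   `n_R` iterations the matches with the largest error
   `ξ_k = (H_k U − D_k)ᵀ S_k (H_k U − D_k)` are discarded (a fraction
   `f_R` in total), then the external force `F = KU` is iterated until
   convergence, relaxing the solution toward the weighted least-squares
   fit of the surviving matches — robust to outliers, asymptotically
   unbiased on clean data.

Extensions included: geometric resection-cavity handling (removal of the
maximal face-connected solid submesh of elements that land on intra-op
background), incremental adaptive registration (warp → re-mesh → repeat,
for shifts larger than the search window), registration-point-driven mesh
sizing metrics (isotropic k-th-nearest-point spacing and anisotropic
minimum-volume-enclosing-ellipsoid tensors with the point-reflection
trick and inflation constant), Canny/Hausdorff evaluation, and a
synthetic brain-shift phantom generator with known ground truth.

## Worked example

```r
library(pbnrr)

# a 64 mm cube phantom: ellipsoidal brain + tumour, textured, deformed by
# a smooth 4 mm brain-shift field with known ground truth
ph   <- makePhantom(phantomSpec(size = c(64, 64, 64), deformMax = 4, seed = 4))
mesh <- bccMesh(ph$labels, cellSize = 8)

reg <- registerImages(ph$preop, ph$intraop, mesh,
                      fraction = 0.9, mask = ph$labels, minSpacing = 3,
                      cfg = solverConfig(nR = 0, fR = 0))

truth <- sampleField(ph$truth, vertices(mesh))
err   <- sqrt(rowSums((fieldValues(reg$nodal) - truth)^2))
cat(sprintf("mean nodal error %.3f mm (zero-field baseline %.3f mm)\n",
            mean(err), mean(sqrt(rowSums(truth^2)))))
#> mean nodal error 0.832 mm (zero-field baseline 3.435 mm)

ev <- evaluateRegistration(ph$preop, ph$intraop, reg$field)
str(ev[c("hd", "nPre", "nIntra")])
```

The registration recovers the 4 mm deformation to well under a voxel at
the mesh nodes — about a quarter of the unregistered baseline error; the
residual is dominated by the integer-voxel quantisation of block
matching. `reg$warped` is the pre-op image resampled into the intra-op
space, `reg$field` the dense displacement field, and `reg$log` the
per-iteration rejection/relaxation record.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/scripts/pbnrr phantom  --out-dir ph --seed 4
Rscript inst/scripts/pbnrr register --floating ph/preop.nii.gz \
    --fixed ph/intraop.nii.gz --mask ph/labels.nii.gz --out-dir reg
Rscript inst/scripts/pbnrr evaluate --preop ph/preop.nii.gz \
    --intraop ph/intraop.nii.gz --field reg/field.nii.gz --out-dir ev
```

Every run writes a `manifest.json` echoing the full configuration, the
seed, versions and per-stage timings.

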