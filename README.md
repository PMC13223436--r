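# pneumonet

Four-class pneumonia screening on grayscale chest images (Normal, Bacterial,
Viral, Fungal pneumonia) with a compact hybrid neural network and an
adaptive dropout schedule, implemented end to end in R.

Accurate discrimination of pneumonia *types* — not just pneumonia versus
normal — matters clinically because bacterial, viral and fungal infections
call for different treatment, and the radiological differences are subtle.
`pneumonet` is aimed at researchers who want a fully inspectable,
desk-scale implementation of this classification pipeline: every layer's
forward and backward pass is in this package (base R over BLAS matrix
products plus small compiled im2col/GEMM kernels), with no deep-learning
framework dependency.

## The model

The classifier is a single sequential chain combining three standard
building blocks:

* **Fire modules** (SqueezeNet): a 1×1 squeeze convolution followed by
  parallel 1×1 and 3×3 expand convolutions, channel-concatenated —
  `F = [φ(ε₁ₓ₁ ∗ s), φ(ε₃ₓ₃ ∗ s)]` with `s = φ(w₁ₓ₁ ∗ x)`;
* **patch-token self-attention** (ViT style): the pooled feature map is cut
  into P×P patches, linearly embedded with learned position encodings, and
  mixed by multi-head scaled dot-product attention
  `softmax(QKᵀ/√d_h)V` with a residual connection;
* **a depthwise-separable residual block** (Xception style): per-channel
  3×3 depthwise convolution, 1×1 pointwise channel mix, plus the block
  input;

followed by global average pooling, an affine head and a softmax:
`C(x) = argmax_m softmax(w_FC v + b_FC)_m`.

During training, a single shared **dropout rate** is tuned online by a
population metaheuristic over [0.1, 0.6] that alternates water-strider-style
global exploration (attraction toward the incumbent plus decaying
surface-tension noise, with repulsion on failed moves) with genetic-style
local refinement (tournament selection, arithmetic crossover, Gaussian
mutation, elitist replacement).  Candidate rates are scored by cloning the
weights, training a few mini-batches at that rate, and evaluating
validation macro F1.  See `vignette("methods", package = "pneumonet")` for
the full account, including how the search stays robust to noisy fitness.

The package also ships a deterministic synthetic chest-image generator
with ground-truth lesion masks (so saliency can be validated against known
lesion support), the preprocessing chain, stratified k-fold
cross-validation, a complete metrics panel (confusion matrix, per-class
and macro precision/recall/specificity/F1, one-vs-rest AUC, error rate,
class-correlation grids, one-way ANOVA), and Grad-CAM saliency maps.

## A worked example

```r
library(pneumonet)

# 1. synthesize a labelled four-class dataset (X-ray-like, 64x64)
spec <- synth_spec(n_per_class = 200, modality = "xray", seed = 1)
ds <- synth_dataset(spec)
ds
#> pneumo_dataset: 800 images, 4 classes, 64x64 px, modality xray
#>      Normal Bacterial Pneumonia     Viral Pneumonia    Fungal Pneumonia
#>         200                 200                 200                 200

# 2. hold out a stratified test split, train the classifier
ti <- stratified_holdout(ds$labels, 0.15, hash_seed(1, "test"))
ctrl <- train_control(max_epochs = 30, learning_rate = 1e-3, seed = 1)
fit <- pneumonet(ds$images[-ti], ds$labels[-ti], net_config(), ctrl,
                 val = 0.15)
fit
#> Hybrid fire-module/attention pneumonia classifier
#>   classes: Normal, Bacterial Pneumonia, Viral Pneumonia, Fungal Pneumonia
#>   input: 64 x 64  fire modules: 2  attention blocks: 2
#>   parameters: 77,788
#>   epochs trained: 30  final val accuracy: 0.9615
#>   dropout: fixed 0.5 (final rate 0.5 )

# 3. evaluate on the held-out test set
probs <- predict(fit, ds$images[ti], type = "prob")
pred <- predict(fit, ds$images[ti], type = "class")
rep <- classification_report(confusion_matrix(ds$labels[ti], pred))
rep$accuracy                  # 0.975 held-out accuracy on this seed
auc_roc_ovr(ds$labels[ti], probs)$macro   # 1.0

# 4. explain one prediction against the known lesion mask
g <- synth_image("Bacterial Pneumonia", spec, index = 3)
sal <- grad_cam(fit, g$image, "Bacterial Pneumonia")
mean(sal[g$mask]) > mean(sal[!g$mask])   # saliency concentrates in the lesion
```

The interpretation: the network reaches validation accuracy ≈ 0.96 within
30 epochs on the synthetic task and scores 0.975 on the untouched test
split — the task is constructed to be separable — while Grad-CAM maps
place their mass inside the generator's ground-truth lesion masks for the
focal-lesion classes.

To tune the dropout rate online instead of fixing it:

```r
ctrl <- train_control(max_epochs = 20, learning_rate = 1e-3, seed = 1,
                      dropout_search = TRUE,
                      search_control = dropout_search_control(
                        pop_size = 10, max_iters = 6, eval_budget = 1))
fit2 <- pneumonet(ds$images[-ti], ds$labels[-ti], net_config(), ctrl)
fit2$dropout_trace            # every candidate evaluation, per round
plot(fit2)                    # loss curves + active dropout rate
```

A thin command-line front end (`inst/cli/pneumonet`) wraps the same
functions: `generate`, `train`, `evaluate`, `explain`, `tune-dropout`.

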