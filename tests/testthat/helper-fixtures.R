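# Shared fixtures, all built in code at test time.

# A small volume with reproducible pseudo-random integer HU values.
toy_volume <- function(dims = c(24, 24, 3), spacing = c(1, 1, 1),
                       fov = 24, seed = 42) {
  vox <- renalqct:::with_seed(seed, {
    array(as.numeric(sample(-1000:1500, prod(dims), replace = TRUE)), dims)
  })
  ct_volume(vox, spacing, fov)
}

# A square polygon ROI (vertices in mm, counter-clockwise).
square_roi <- function(label = "sq", lo = 2, hi = 12, slice = 0,
                       plane = "axial") {
  ct_roi(label, plane, slice,
         vertices_mm = cbind(c(lo, hi, hi, lo), c(lo, lo, hi, hi)))
}

# Tiny labelled-record table for diagnostics: one kidney per animal.
toy_labeled <- function(score, label) {
  data.frame(animal = sprintf("A%02d", seq_along(score)), side = "left",
             corrected_hu = score, fibrotic = as.logical(label))
}

# Mann-Whitney concordance probability (independent AUC oracle).
concordance_auc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
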