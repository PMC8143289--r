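# Independent reference implementations used as oracles. Deliberately
# naive: straight transcriptions of the definitions, no shared code with
# the package internals beyond local_first_order_stats (whose own oracle
# is a set of frozen hand-computed values).

# Double-loop patch sweep: per ROI voxel, extract the truncated in-slice
# window and compute the seven statistics.
naive_sweep <- function(volume, mask, side) {
  half <- (side - 1) / 2
  d <- dim(volume$voxels)
  idx <- which(mask$voxels == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(idx), 7)
  colnames(out) <- c("m", "M", "s", "k", "iqr", "cv", "e")
  for (i in seq_len(nrow(idx))) {
    sl <- idx[i, 1]; r <- idx[i, 2]; cc <- idx[i, 3]
    rr <- max(1, r - half):min(d[2], r + half)
    rc <- max(1, cc - half):min(d[3], cc + half)
    out[i, ] <- local_first_order_stats(as.vector(volume$voxels[sl, rr, rc]))
  }
  out
}

# AUC by brute-force Mann-Whitney pair counting (ties count one half).
auc_paircount <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Literal step-down Holm reference.
holm_reference <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  rej <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) rej[ord[i]] <- TRUE else break
  }
  rej
}

# Youden cutoff by exhaustive threshold scan (predict positive at
# score >= t), ties toward higher specificity then larger threshold.
youden_scan <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  best <- -Inf; best_fpr <- Inf; best_t <- NA
  for (t in th) {
    tpr <- mean(scores[labels == 1] >= t)
    fpr <- mean(scores[labels == 0] >= t)
    j <- tpr - fpr
    if (j > best || (j == best && fpr < best_fpr)) {
      best <- j; best_fpr <- fpr; best_t <- t
    }
  }
  best_t
}

# Small hand-made phantom: one elliptical lesion in a constant-noise
# volume, away from all borders.
toy_patient <- function(seed = 1, n_slices = 3, g = 24, spacing = 1.5) {
  set.seed(seed)
  vox <- array(rnorm(n_slices * g * g, 100, 10), dim = c(n_slices, g, g))
  msk <- array(0, dim = c(n_slices, g, g))
  for (sl in seq_len(n_slices)) {
    for (r in seq_len(g)) for (cc in seq_len(g)) {
      if (((r - g / 2) / 4)^2 + ((cc - g / 2) / 5)^2 <= 1) msk[sl, r, cc] <- 1
    }
  }
  list(volume = image_volume(vox, spacing), mask = lesion_mask(msk),
       label = 1L, patient_id = sprintf("T%03d", seed))
}
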