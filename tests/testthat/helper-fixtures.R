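# Shared fixtures and independent oracles used across test files.

# Tiny configs for fast network tests.
tiny_cae_cfg <- function(edge = 16L)
  cae_config(in_edge = edge, stage_channels = c(2L, 4L, 8L, 16L), latent_dim = 8L)

tiny_unet_cfg <- function(edge = 16L)
  unet_config(in_edge = edge, stage_channels = c(2L, 4L, 8L, 16L), width = 1)

tiny_phantom <- function(edge = 16L, seed = 1L, ...)
  phantom_params(cube_edge = edge, seed = seed, ...)

# Labelled stub volumes (no image content) for split/subsampling tests.
stub_volumes <- function(n_normal, n_anomalous, two_sided_patients = FALSE) {
  mk <- function(i, label, side = "left")
    ms_volume(array(0, c(2, 2, 2)), patient_id = sprintf("P%04d", i),
              side = side, label = label)
  vols <- c(lapply(seq_len(n_normal), mk, label = "normal"),
            lapply(n_normal + seq_len(n_anomalous), mk, label = "anomalous"))
  if (two_sided_patients) {
    extra <- lapply(seq_len(n_normal), function(i) {
      v <- mk(i, "normal", side = "right"); v
    })
    vols <- c(vols, extra)
  }
  vols
}

# Brute-force AUROC: count over all positive-negative pairs, ties 1/2.
bf_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Brute-force average precision by rank enumeration.
bf_auprc <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  ap <- 0; tp <- 0
  for (k in seq_along(lab)) {
    if (lab[k] == 1) {
      tp <- tp + 1
      ap <- ap + tp / k
    }
  }
  ap / sum(labels == 1)
}

# Brute-force 3D median filter with reflect padding (index -1 -> 0).
bf_median3d <- function(x, k) {
  d <- dim(x); r <- k %/% 2
  refl <- function(i, n) { i <- ifelse(i < 1, 1 - i, i); ifelse(i > n, 2 * n + 1 - i, i) }
  out <- array(0, d)
  for (a in seq_len(d[1])) for (b in seq_len(d[2])) for (cc in seq_len(d[3])) {
    vals <- numeric(0)
    for (da in -r:r) for (db in -r:r) for (dc in -r:r)
      vals <- c(vals, x[refl(a + da, d[1]), refl(b + db, d[2]), refl(cc + dc, d[3])])
    out[a, b, cc] <- sort(vals)[(k^3 + 1) / 2]
  }
  out
}

# 6-connected component count of a binary 3D mask.
n_components6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask > 0)
  if (length(idx) == 0) return(0L)
  comp <- 0L
  for (s in idx) {
    if (lab[s] > 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        nb <- co; nb[ax] <- nb[ax] + dd
        if (nb[ax] < 1 || nb[ax] > d[ax]) next
        li <- nb[1] + d[1] * (nb[2] - 1 + d[2] * (nb[3] - 1))
        if (mask[li] > 0 && lab[li] == 0L) { lab[li] <- comp; queue <- c(queue, li) }
      }
    }
  }
  comp
}
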