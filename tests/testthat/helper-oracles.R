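# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# full-sort thresholding oracle: top floor(f*N) |values|, ties by index
oracle_top_fraction <- function(zmap, fraction) {
  idx <- which(is.finite(zmap))
  m <- floor(fraction * length(idx))
  ord <- order(-abs(zmap[idx]), idx)
  sort(idx[ord[seq_len(m)]])
}

# per-voxel atlas lookup oracle
oracle_region_counts <- function(voxels, labelmap, codes) {
  counts <- integer(length(codes))
  for (v in voxels) {
    hit <- match(labelmap[v], codes)
    if (!is.na(hit)) counts[hit] <- counts[hit] + 1L
  }
  counts
}

# direct DFT-magnitude-squared oracle (no fft)
oracle_periodogram <- function(x, tr) {
  tt <- length(x)
  x <- x - mean(x)
  n_half <- floor(tt / 2)
  pw <- vapply(0:n_half, function(k) {
    w <- -2 * pi * k * (0:(tt - 1)) / tt
    Mod(sum(x * complex(real = cos(w), imaginary = sin(w))))^2
  }, 0)
  list(freq = (0:n_half) / (tt * tr), power = pw / sum(pw))
}

# exhaustive positive-negative pair-counting AUC (Mann-Whitney)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# exhaustive neighborhood-scan local maxima + iterative flood fill
oracle_peaks_clusters <- function(zmap, voxels, n_peaks = 10, grow_thresh = 2.5) {
  dm <- dim(zmap)
  az <- abs(zmap)
  in_set <- array(FALSE, dm)
  in_set[voxels] <- TRUE
  coords <- arrayInd(voxels, dm)
  peaks <- c()
  for (i in seq_along(voxels)) {
    v <- voxels[i]
    ijk <- coords[i, ]
    is_pk <- TRUE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      n <- ijk + c(dx, dy, dz)
      if (any(n < 1) || any(n > dm)) next
      nl <- n[1] + (n[2] - 1) * dm[1] + (n[3] - 1) * dm[1] * dm[2]
      if (in_set[nl] && az[v] <= az[nl]) { is_pk <- FALSE; break }
    }
    if (is_pk) peaks <- c(peaks, v)
  }
  peaks <- peaks[order(-az[peaks], peaks)]
  peaks <- peaks[seq_len(min(n_peaks, length(peaks)))]
  grow <- az >= grow_thresh & is.finite(az)
  sizes <- vapply(peaks, function(seed) {
    if (!grow[seed]) return(0L)
    comp <- array(FALSE, dm)
    comp[seed] <- TRUE
    repeat {
      grew <- FALSE
      for (v in which(comp)) {
        ijk <- arrayInd(v, dm)[1, ]
        for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
          n <- ijk + c(dx, dy, dz)
          if (any(n < 1) || any(n > dm)) next
          nl <- n[1] + (n[2] - 1) * dm[1] + (n[3] - 1) * dm[1] * dm[2]
          if (grow[nl] && !comp[nl]) { comp[nl] <- TRUE; grew <- TRUE }
        }
      }
      if (!grew) break
    }
    sum(comp)
  }, 0L)
  list(peaks = peaks, sizes = sizes)
}

# closed-form ridge (alpha = 0) solution of the centered problem
oracle_ridge <- function(X, y, lambda) {
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  beta <- solve(crossprod(Xc) / n + diag(lambda, ncol(X)), crossprod(Xc, yc) / n)
  list(beta = as.vector(beta),
       intercept = mean(y) - sum(colMeans(X) * beta))
}

# confusion-matrix oracle
oracle_confusion <- function(pred, labels) {
  c(TP = sum(pred == 1 & labels == 1), FP = sum(pred == 1 & labels == 0),
    TN = sum(pred == 0 & labels == 0), FN = sum(pred == 0 & labels == 1))
}
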