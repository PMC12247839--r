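# Independent reference implementations used as oracles. These deliberately
# avoid the package's C++ kernels: plain R array shifting and exhaustive
# window scans only.

# shift a 3D array by (dz, dy, dx), filling vacated voxels with `fill`
shift3 <- function(x, dz, dy, dx, fill = 0) {
  d <- dim(x)
  out <- array(fill, d)
  src <- list(z = seq_len(d[1]), y = seq_len(d[2]), x = seq_len(d[3]))
  sz <- src$z - dz; sy <- src$y - dy; sx <- src$x - dx
  okz <- sz >= 1 & sz <= d[1]; oky <- sy >= 1 & sy <= d[2]
  okx <- sx >= 1 & sx <= d[3]
  if (!any(okz) || !any(oky) || !any(okx)) return(out)
  out[src$z[okz], src$y[oky], src$x[okx]] <-
    x[sz[okz], sy[oky], sx[okx], drop = FALSE]
  out
}

# exhaustive grayscale dilation/erosion with a cubic SE cropped at borders
oracle_gray_dilate <- function(x, r) {
  acc <- array(-Inf, dim(x))
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r)
    acc <- pmax(acc, shift3(x, dz, dy, dx, fill = -Inf))
  acc
}
oracle_gray_erode <- function(x, r) {
  acc <- array(Inf, dim(x))
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r)
    acc <- pmin(acc, shift3(x, dz, dy, dx, fill = Inf))
  acc
}
oracle_black_top_hat <- function(x, r) {
  oracle_gray_erode(oracle_gray_dilate(x, r), r) - x
}

# binary cube dilation by shift-OR accumulation; cube structuring elements
# are separable, so one axis at a time
oracle_bin_dilate <- function(m, r) {
  acc <- m != 0
  for (ax in 1:3) {
    cur <- acc
    for (s in setdiff(-r:r, 0)) {
      sh <- if (ax == 1) shift3(cur * 1, s, 0, 0, 0)
            else if (ax == 2) shift3(cur * 1, 0, s, 0, 0)
            else shift3(cur * 1, 0, 0, s, 0)
      acc <- acc | (sh > 0)
    }
  }
  acc
}

# explicit double-dilation-intersection joint truth
oracle_joint_truth <- function(labels, d, include_surface = TRUE) {
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids > 0]
  if (length(ids) < 2) return(array(FALSE, dim(labels)))
  cover <- array(0L, dim(labels))
  for (id in ids) cover <- cover + oracle_bin_dilate(labels == id, d)
  interface <- cover >= 2L
  bg <- labels == 0L
  keep <- if (include_surface) bg | (!bg & oracle_bin_dilate(bg, 1L)) else bg
  oracle_bin_dilate(interface & keep, d)
}

# priority-flood watershed reference: pop the globally lowest (priority,
# label, insertion-order) claim, assign on pop
oracle_watershed <- function(topo, mask, markers, connectivity = 26L) {
  d <- dim(topo)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  out <- array(0L, d)
  done <- array(FALSE, d)
  qp <- numeric(0); ql <- integer(0); qs <- numeric(0); qi <- integer(0)
  seqc <- 0
  push <- function(idx, lab) {
    seqc <<- seqc + 1
    qp <<- c(qp, topo[idx]); ql <<- c(ql, lab)
    qs <<- c(qs, seqc); qi <<- c(qi, idx)
  }
  mk <- which(markers > 0)
  out[mk] <- markers[mk]
  for (i in mk) push(i, markers[i])
  co <- arrayInd(seq_len(prod(d)), d)
  while (length(qi) > 0) {
    best <- order(qp, ql, qs)[1]
    idx <- qi[best]; lab <- ql[best]
    qp <- qp[-best]; ql <- ql[-best]; qs <- qs[-best]; qi <- qi[-best]
    if (done[idx]) next
    done[idx] <- TRUE
    out[idx] <- lab
    z <- co[idx, 1]; y <- co[idx, 2]; x <- co[idx, 3]
    for (k in seq_len(nrow(offs))) {
      zz <- z + offs$dz[k]; yy <- y + offs$dy[k]; xx <- x + offs$dx[k]
      if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3])
        next
      j <- zz + d[1] * (yy - 1) + d[1] * d[2] * (xx - 1)
      if (mask[j] == 0 || out[j] != 0 || done[j]) next
      push(j, lab)
    }
  }
  out
}

# random multi-label map: a few seed points grown into blobs
random_label_map <- function(dim3, n_labels, seed) {
  set.seed(seed)
  lab <- array(0L, dim3)
  n <- prod(dim3)
  seeds <- sample.int(n, n_labels)
  co <- arrayInd(seq_len(n), dim3)
  sc <- co[seeds, , drop = FALSE]
  rad <- runif(n_labels, 1.5, max(dim3) / 2.5)
  for (i in seq_len(n)) {
    d2 <- (co[i, 1] - sc[, 1])^2 + (co[i, 2] - sc[, 2])^2 +
      (co[i, 3] - sc[, 3])^2
    k <- which(d2 <= rad^2)
    if (length(k)) lab[i] <- k[which.min(d2[k])]
  }
  lab
}
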