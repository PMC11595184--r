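## Deep-learning analysis tool: a compact convolutional classifier on
## 4-channel per-cell crops -> {M0, M1like, M2like, dead} with a softmax
## confidence and a 40% exclusion gate. The network is implemented
## directly on BLAS matrix products (im2col convolutions, Adam, seeded
## initialization), trains on CPU in minutes at the package's default
## problem sizes and is fully deterministic given the seed.
## Architecture: avgpool2 -> conv 5x5x4->8 + ReLU -> maxpool2 ->
## conv 3x3x8->16 + ReLU -> maxpool2 -> dense 576->32 + ReLU -> dense 4.
## ~21k parameters.

#' Cut per-cell crops from a plate bundle
#'
#' One square 4-channel patch per retained cell, centred on the nucleus
#' centroid, zero-padded at field borders. Channels are normalized to
#' \[0, 1\] by plate-level 1st/99th intensity percentiles (recorded in the
#' result).
#'
#' @param bundle A [plate_bundle()].
#' @param segs Named list of [cell_segmentation()]s keyed like
#'   `bundle$images` (e.g. from [segment_field()] per field); if `NULL`,
#'   every field is segmented with defaults.
#' @param size Patch edge length in px (default 64).
#' @return List with `crops` (array size x size x 4 x n), `meta`
#'   (`data.frame`: plate, well, field, cell_id, cy, cx) and
#'   `percentiles` (4 x 2 matrix).
#' @export
make_crops <- function(bundle, segs = NULL, size = 64L) {
  stopifnot(inherits(bundle, "PlateBundle"))
  fl <- bundle_fields(bundle)
  if (is.null(segs)) {
    segs <- lapply(seq_len(nrow(fl)), function(i)
      segment_field(bundle, fl$well[i], fl$field[i]))
    names(segs) <- fl$key
  }
  ## plate-level normalization percentiles per channel
  pct <- t(vapply(CP_CHANNELS, function(ch) {
    v <- unlist(lapply(bundle$images, function(f) as.vector(f[[ch]])),
                use.names = FALSE)
    stats::quantile(v, c(0.01, 0.99), names = FALSE)
  }, numeric(2)))
  meta <- list(); patches <- list()
  half <- size %/% 2L
  for (key in names(segs)) {
    seg <- segs[[key]]
    if (!length(seg$cell_ids)) next
    summ <- seg_cell_summary(seg)
    H <- nrow(seg$cell_mask); W <- ncol(seg$cell_mask)
    for (i in seq_len(nrow(summ))) {
      cy <- round(summ$cy[i]); cx <- round(summ$cx[i])
      patch <- array(0, c(size, size, 4L))
      r0 <- cy - half + 1L; c0 <- cx - half + 1L   # 0-based patch origin
      rr <- (r0:(r0 + size - 1L)) + 1L             # 1-based grid rows
      cc <- (c0:(c0 + size - 1L)) + 1L
      rok <- which(rr >= 1L & rr <= H); cok <- which(cc >= 1L & cc <= W)
      for (k in seq_along(CP_CHANNELS)) {
        img <- bundle$images[[key]][[CP_CHANNELS[k]]]
        sub <- img[rr[rok], cc[cok], drop = FALSE]
        lo <- pct[k, 1]; hi <- max(pct[k, 2] - pct[k, 1], 1e-9)
        patch[rok, cok, k] <- pmin(pmax((sub - lo) / hi, 0), 1)
      }
      patches[[length(patches) + 1L]] <- patch
      meta[[length(meta) + 1L]] <- data.frame(
        plate = bundle$platemap$plate_id, well = seg$well, field = seg$field,
        cell_id = summ$cell_id[i], cy = summ$cy[i], cx = summ$cx[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(patches)) {
    warning("degenerate plate: no cells, returning empty crop list")
    return(list(crops = array(0, c(size, size, 4L, 0L)),
                meta = data.frame(), percentiles = pct))
  }
  crops <- array(unlist(patches, use.names = FALSE),
                 c(size, size, 4L, length(patches)))
  list(crops = crops, meta = do.call(rbind, meta), percentiles = pct)
}

## ---- minimal CNN machinery ----

## im2col gather-index matrix for an H x W x C volume and kh x kw kernel
conv_indices <- function(H, W, C, kh, kw) {
  oh <- H - kh + 1L; ow <- W - kw + 1L
  pos_r <- rep(seq_len(oh), ow); pos_c <- rep(seq_len(ow), each = oh)
  M <- matrix(0L, oh * ow, kh * kw * C)
  col <- 0L
  for (c in seq_len(C)) for (dc in seq_len(kw) - 1L) for (dr in seq_len(kh) - 1L) {
    col <- col + 1L
    M[, col] <- (c - 1L) * H * W + (pos_c + dc - 1L) * H + (pos_r + dr)
  }
  list(M = M, oh = oh, ow = ow)
}

pool2 <- function(x, H, W, C, what = c("max", "avg")) {
  ## x: vector volume; returns list(out vector volume, sel for max)
  what <- match.arg(what)
  a <- array(x, c(H, W, C))
  i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, W, 2L); j2 <- j1 + 1L
  s1 <- a[i1, j1, , drop = FALSE]; s2 <- a[i2, j1, , drop = FALSE]
  s3 <- a[i1, j2, , drop = FALSE]; s4 <- a[i2, j2, , drop = FALSE]
  if (what == "avg")
    return(list(out = as.vector((s1 + s2 + s3 + s4) / 4)))
  out <- pmax(pmax(s1, s2), pmax(s3, s4))
  ## selector = first maximal quadrant (deterministic tie-break)
  sel <- ifelse(s1 == out, 1L, ifelse(s2 == out, 2L, ifelse(s3 == out, 3L, 4L)))
  list(out = as.vector(out), sel = as.vector(sel))
}

unpool2_max <- function(dout, sel, H, W, C) {
  ## dout over pooled grid (H/2, W/2, C); scatter to (H, W, C)
  dh <- H %/% 2L; dw <- W %/% 2L
  a <- array(0, c(H, W, C))
  d <- array(dout, c(dh, dw, C)); s <- array(sel, c(dh, dw, C))
  i1 <- seq(1L, H, 2L); j1 <- seq(1L, W, 2L)
  a[i1, j1, ][s == 1L] <- d[s == 1L]
  a[i1 + 1L, j1, ][s == 2L] <- d[s == 2L]
  a[i1, j1 + 1L, ][s == 3L] <- d[s == 3L]
  a[i1 + 1L, j1 + 1L, ][s == 4L] <- d[s == 4L]
  as.vector(a)
}

cnn_init <- function(size = 64L, n_classes = 4L, seed = 1L) {
  with_seed(derive_seed(seed, "cnn-init"), {
    he <- function(nin, nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nin)),
                                       nr, nc)
    s2 <- size %/% 2L                      # after avgpool
    ix1 <- conv_indices(s2, s2, 4L, 5L, 5L)
    p1 <- ix1$oh %/% 2L                    # after maxpool
    ix2 <- conv_indices(p1, p1, 8L, 3L, 3L)
    p2 <- ix2$oh %/% 2L
    nflat <- p2 * p2 * 16L
    list(size = size, s2 = s2, ix1 = ix1, p1 = p1, ix2 = ix2, p2 = p2,
         nflat = nflat, n_classes = n_classes,
         W1 = he(100, 100, 8L), b1 = numeric(8L),
         W2 = he(72, 72, 16L), b2 = numeric(16L),
         W3 = he(nflat, nflat, 32L), b3 = numeric(32L),
         W4 = he(32, 32L, n_classes), b4 = numeric(n_classes))
  })
}

## forward pass for one sample volume (returns cache when training)
cnn_forward1 <- function(net, x, keep = FALSE) {
  a0 <- pool2(x, net$size, net$size, 4L, "avg")$out
  P1 <- matrix(a0[as.vector(net$ix1$M)], nrow(net$ix1$M), ncol(net$ix1$M))
  z1 <- sweep(P1 %*% net$W1, 2, net$b1, "+")
  r1 <- pos_part(z1)
  o1 <- net$ix1$oh
  mp1 <- pool2(as.vector(r1), o1, o1, 8L, "max")
  P2 <- matrix(mp1$out[as.vector(net$ix2$M)], nrow(net$ix2$M), ncol(net$ix2$M))
  z2 <- sweep(P2 %*% net$W2, 2, net$b2, "+")
  r2 <- pos_part(z2)
  o2 <- net$ix2$oh
  mp2 <- pool2(as.vector(r2), o2, o2, 16L, "max")
  f <- mp2$out
  z3 <- drop(f %*% net$W3) + net$b3
  r3 <- pos_part(z3)
  z4 <- drop(r3 %*% net$W4) + net$b4
  p <- exp(z4 - max(z4)); p <- p / sum(p)
  if (!keep) return(list(p = p))
  list(p = p, a0 = a0, P1 = P1, z1 = z1, mp1 = mp1, P2 = P2, z2 = z2,
       mp2 = mp2, f = f, z3 = z3, r3 = r3)
}

cnn_backward1 <- function(net, cache, y_onehot, grads) {
  d4 <- cache$p - y_onehot
  grads$W4 <- grads$W4 + outer(cache$r3, d4)
  grads$b4 <- grads$b4 + d4
  d3 <- drop(net$W4 %*% d4) * (cache$z3 > 0)
  grads$W3 <- grads$W3 + outer(cache$f, d3)
  grads$b3 <- grads$b3 + d3
  df <- drop(net$W3 %*% d3)
  o2 <- net$ix2$oh
  dr2 <- unpool2_max(df, cache$mp2$sel, o2, o2, 16L)
  dz2 <- matrix(dr2, ncol = 16L) * (cache$z2 > 0)
  grads$W2 <- grads$W2 + crossprod(cache$P2, dz2)
  grads$b2 <- grads$b2 + colSums(dz2)
  dP2 <- dz2 %*% t(net$W2)
  dmp1 <- numeric(net$p1 * net$p1 * 8L)
  sums <- rowsum(as.vector(dP2), as.vector(net$ix2$M))
  dmp1[as.integer(rownames(sums))] <- sums
  o1 <- net$ix1$oh
  dr1 <- unpool2_max(dmp1, cache$mp1$sel, o1, o1, 8L)
  dz1 <- matrix(dr1, ncol = 8L) * (cache$z1 > 0)
  grads$W1 <- grads$W1 + crossprod(cache$P1, dz1)
  grads$b1 <- grads$b1 + colSums(dz1)
  grads
}

#' Train the compact CNN classifier
#'
#' Trains the four-class (M0, M1like, M2like, dead) convolutional
#' classifier on labeled crops with Adam and cross-entropy. Seeded and
#' deterministic; designed to train on CPU in minutes at the package's
#' default problem sizes (hundreds of crops per class).
#'
#' @param crops Array size x size x 4 x n (from [make_crops()]).
#' @param labels Character vector of length n over [cp_classes()]; every
#'   class must be present.
#' @param seed Integer seed.
#' @param epochs Training epochs (default 12).
#' @param batch_size Minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @return An object of class `CnnModel` (network weights + `loss_history`).
#' @export
train_cnn <- function(crops, labels, seed = 1L, epochs = 12L,
                      batch_size = 32L, lr = 1e-3) {
  n <- dim(crops)[4]
  stopifnot(length(labels) == n, n > 0)
  labels <- as.character(labels)
  absent <- setdiff(CP_CLASSES, unique(labels))
  if (length(absent))
    stop("class(es) absent from training data: ",
         paste(absent, collapse = ", "))
  if (min(table(labels)) < 50)
    cp_log("cnn", "note: fewer than 50 crops in the smallest class")
  size <- dim(crops)[1]
  net <- cnn_init(size = size, seed = seed)
  y_idx <- match(labels, CP_CLASSES)
  pnames <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")
  mom <- lapply(pnames, function(p) net[[p]] * 0)
  vel <- lapply(pnames, function(p) net[[p]] * 0)
  names(mom) <- names(vel) <- pnames
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  loss_history <- numeric(epochs)
  t0 <- as.numeric(Sys.time())
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, paste("cnn-epoch", ep)), sample(n))
    ep_loss <- 0
    for (b0 in seq(1, n, by = batch_size)) {
      batch <- ord[b0:min(b0 + batch_size - 1, n)]
      grads <- lapply(pnames, function(p) net[[p]] * 0)
      names(grads) <- pnames
      for (i in batch) {
        cache <- cnn_forward1(net, as.vector(crops[, , , i]), keep = TRUE)
        onehot <- numeric(4); onehot[y_idx[i]] <- 1
        ep_loss <- ep_loss - log(max(cache$p[y_idx[i]], 1e-12))
        grads <- cnn_backward1(net, cache, onehot, grads)
      }
      step <- step + 1
      for (p in pnames) {
        g <- grads[[p]] / length(batch)
        mom[[p]] <- beta1 * mom[[p]] + (1 - beta1) * g
        vel[[p]] <- beta2 * vel[[p]] + (1 - beta2) * g^2
        mhat <- mom[[p]] / (1 - beta1^step)
        vhat <- vel[[p]] / (1 - beta2^step)
        net[[p]] <- net[[p]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_history[ep] <- ep_loss / n
  }
  cp_log("cnn", sprintf("trained %d epochs on %d crops, final loss %.4f",
                        epochs, n, loss_history[epochs]), t0 = t0)
  structure(c(net, list(classes = CP_CLASSES, seed = seed,
                        loss_history = loss_history)),
            class = "CnnModel")
}

#' @export
print.CnnModel <- function(x, ...) {
  npar <- sum(vapply(c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4"),
                     function(p) length(x[[p]]), numeric(1)))
  cat(sprintf("CnnModel: 4-class, %d px crops, %d parameters\n", x$size, npar))
  invisible(x)
}

#' Classify crops with confidence gating
#'
#' Softmax prediction per crop; the confidence is the maximal class
#' probability, and predictions with confidence below `threshold`
#' (default 0.40) are excluded from downstream ratio aggregation.
#'
#' @param model A [train_cnn()] model.
#' @param crops Crop array (or a [make_crops()] list, whose `meta` is then
#'   carried into the result).
#' @param threshold Exclusion threshold in \[0, 1\].
#' @return List with `predictions` (`data.frame`: optional meta columns,
#'   `class`, `confidence`, `retained`) and `excluded` (count).
#' @export
predict_with_confidence <- function(model, crops, threshold = 0.40) {
  stopifnot(inherits(model, "CnnModel"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  meta <- NULL
  if (is.list(crops) && !is.null(crops$crops)) {
    meta <- crops$meta
    crops <- crops$crops
  }
  n <- dim(crops)[4]
  cls <- character(n); conf <- numeric(n)
  for (i in seq_len(n)) {
    p <- cnn_forward1(model, as.vector(crops[, , , i]))$p
    j <- which.max(p)   # ties: first in fixed class order
    cls[i] <- model$classes[j]
    conf[i] <- p[j]
  }
  retained <- conf >= threshold
  out <- data.frame(class = cls, confidence = conf, retained = retained,
                    stringsAsFactors = FALSE)
  if (!is.null(meta) && nrow(meta) == n) out <- cbind(meta, out)
  if (!any(retained))
    cp_log("cnn", "warning: all ", n, " predictions below threshold ",
           threshold, "; ratios undefined")
  list(predictions = out, excluded = sum(!retained))
}

#' Per-well class ratios and replicate averaging
#'
#' Aggregates retained predictions per well (cell count, class ratios
#' summing to 1, mean confidence per class), then averages wells of the
#' same condition (`replicate_group` in the plate map) with equal weight.
#'
#' @param predictions `predictions` data.frame from
#'   [predict_with_confidence()] (needs a `well` column).
#' @param platemap Optional [plate_map()] for condition averaging.
#' @return List with `wells` and (if a plate map is given) `conditions`
#'   data.frames; wells where every cell was excluded are dropped and
#'   logged.
#' @export
well_ratios <- function(predictions, platemap = NULL) {
  stopifnot("well" %in% names(predictions))
  kept <- predictions[predictions$retained, , drop = FALSE]
  dropped <- setdiff(unique(predictions$well), unique(kept$well))
  if (length(dropped))
    cp_log("cnn", "well(s) with no retained cells dropped: ",
           paste(dropped, collapse = ", "))
  wells <- unique(kept$well)
  rows <- lapply(wells, function(w) {
    sub <- kept[kept$well == w, ]
    r <- vapply(CP_CLASSES, function(cl) mean(sub$class == cl), numeric(1))
    mc <- vapply(CP_CLASSES, function(cl)
      if (any(sub$class == cl)) mean(sub$confidence[sub$class == cl]) else NA_real_,
      numeric(1))
    cbind(data.frame(well = w, n = nrow(sub)),
          as.data.frame(as.list(stats::setNames(r, paste0("ratio_", CP_CLASSES)))),
          as.data.frame(as.list(stats::setNames(mc, paste0("conf_", CP_CLASSES)))))
  })
  wdf <- do.call(rbind, rows)
  rownames(wdf) <- NULL
  out <- list(wells = wdf)
  if (!is.null(platemap)) {
    wdf$condition <- platemap$wells$replicate_group[
      match(wdf$well, platemap$wells$well)]
    conds <- unique(wdf$condition)
    cdf <- do.call(rbind, lapply(conds, function(cn) {
      sub <- wdf[wdf$condition == cn, ]
      num <- vapply(c("n", paste0("ratio_", CP_CLASSES),
                      paste0("conf_", CP_CLASSES)),
                    function(col) mean(sub[[col]], na.rm = TRUE), numeric(1))
      cbind(data.frame(condition = cn, n_wells = nrow(sub)),
            as.data.frame(as.list(num)))
    }))
    rownames(cdf) <- NULL
    out$conditions <- cdf
    out$wells <- wdf
  }
  out
}

#' Pearson correlation
#'
#' Standard product-moment correlation with input validation (equal
#' lengths >= 3, nonzero variance), as used to compare the deep-learning
#' and feature-based polarization scores.
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input")
  stats::cor(x, y, method = "pearson")
}
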