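# Small convolutional heatmap-regression detector.
#
# The detector localizes behavior instances by regressing per-class heatmaps
# from single grayscale frames and reading out peaks with non-maximum
# suppression. The network is a configurable stack of 3x3 stride-2 conv
# blocks (ReLU) followed by nearest-neighbor x2 upsampling conv stages and a
# 1x1 sigmoid head. Convolutions are evaluated as 9 shifted-slice matrix
# products (BLAS does the heavy lifting); gradients are hand-derived.

#' Detector model configuration
#'
#' @param input_size (height, width) of training frames.
#' @param channels encoder channel widths, one per stride-2 conv block.
#' @param up_channels channel widths of the upsampling stages; their count
#'   sets how much of the encoder downsampling is undone (default 3 stages,
#'   matching the three-upsampling-layer + sigmoid-head contract).
#' @param n_classes number of behavior classes (output channels).
#' @param loss "bce" (default) or "mse" on the heatmap pixels.
#' @param pos_weight multiplier on positive-pixel loss (class imbalance).
#' @param epochs,batch_size,lr,seed training hyperparameters.
#' @return `detector_config` list.
#' @export
detector_config <- function(input_size = c(64L, 64L),
                            channels = c(8L, 16L, 32L),
                            up_channels = c(16L),
                            n_classes = 1L,
                            loss = c("bce", "mse"),
                            pos_weight = 20,
                            epochs = 20L, batch_size = 16L, lr = 2e-3,
                            seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(length(channels) >= 1, length(up_channels) >= 0,
            length(up_channels) <= length(channels))
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 up_channels = as.integer(up_channels),
                 n_classes = as.integer(n_classes), loss = loss,
                 pos_weight = pos_weight, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed)),
            class = "detector_config")
}

#' Gaussian heatmap targets from point labels
#'
#' One map per frame per class at `1/stride` of input resolution, with an
#' unnormalized Gaussian bump (value exactly 1 at the scaled label pixel)
#' per label; overlapping bumps combine by elementwise max.
#'
#' @param labels data.frame `frame,class,x,y` (frame indexes the stack).
#' @param n_frames number of frames in the stack.
#' @param dim input (height, width).
#' @param classes class vocabulary (character); channel order.
#' @param sigma Gaussian SD in output-map pixels.
#' @param stride output stride.
#' @return array (frames, H/stride, W/stride, classes), values in [0, 1].
#' @export
make_heatmap_targets <- function(labels, n_frames, dim, classes = "attending",
                                 sigma = 2, stride = 1L) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  h <- dim[1] %/% stride; w <- dim[2] %/% stride
  out <- array(0, dim = c(n_frames, h, w, length(classes)))
  if (nrow(labels) == 0) return(out)
  stopifnot(all(labels$class %in% classes),
            all(labels$x >= 1), all(labels$y >= 1))
  half <- ceiling(3 * sigma)
  for (i in seq_len(nrow(labels))) {
    f <- labels$frame[i]
    ci <- match(labels$class[i], classes)
    cx <- min(max(round(labels$x[i] / stride), 1L), w)
    cy <- min(max(round(labels$y[i] / stride), 1L), h)
    x0 <- max(1, cx - half); x1 <- min(w, cx + half)
    y0 <- max(1, cy - half); y1 <- min(h, cy + half)
    gx <- exp(-((x0:x1) - cx)^2 / (2 * sigma^2))
    gy <- exp(-((y0:y1) - cy)^2 / (2 * sigma^2))
    bump <- outer(gy, gx)
    out[f, y0:y1, x0:x1, ci] <- pmax(out[f, y0:y1, x0:x1, ci], bump)
  }
  out
}

# ---- conv primitives (arrays are N x H x W x C) --------------------------

pad_hw <- function(x, p) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  out[, p + seq_len(d[2]), p + seq_len(d[3]), ] <- x
  out
}

# 3x3 'same' convolution with stride; W is array (3, 3, Cin, Cout).
conv_forward <- function(x, W, b, stride = 1L) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  Cout <- dim(W)[4]
  xp <- pad_hw(x, 1L)
  ho <- seq(1L, H, by = stride); wo <- seq(1L, Wd, by = stride)
  Ho <- length(ho); Wo <- length(wo)
  acc <- matrix(rep(b, each = N * Ho * Wo), N * Ho * Wo, Cout)
  for (dh in 0:2) for (dw in 0:2) {
    sl <- xp[, ho + dh, wo + dw, , drop = FALSE]
    dim(sl) <- c(N * Ho * Wo, Cin)
    acc <- acc + sl %*% matrix(W[dh + 1, dw + 1, , ], Cin, Cout)
  }
  dim(acc) <- c(N, Ho, Wo, Cout)
  acc
}

conv_backward <- function(x, W, dy, stride = 1L) {
  d <- dim(x); N <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  Cout <- dim(W)[4]
  xp <- pad_hw(x, 1L)
  ho <- seq(1L, H, by = stride); wo <- seq(1L, Wd, by = stride)
  Ho <- length(ho); Wo <- length(wo)
  dym <- dy; dim(dym) <- c(N * Ho * Wo, Cout)
  dW <- array(0, dim = dim(W))
  dxp <- array(0, dim = dim(xp))
  for (dh in 0:2) for (dw in 0:2) {
    sl <- xp[, ho + dh, wo + dw, , drop = FALSE]
    dim(sl) <- c(N * Ho * Wo, Cin)
    dW[dh + 1, dw + 1, , ] <- crossprod(sl, dym)
    dsl <- dym %*% t(matrix(W[dh + 1, dw + 1, , ], Cin, Cout))
    dim(dsl) <- c(N, Ho, Wo, Cin)
    dxp[, ho + dh, wo + dw, ] <- dxp[, ho + dh, wo + dw, , drop = FALSE] + dsl
  }
  db <- colSums(dym)
  dx <- dxp[, 1L + seq_len(H), 1L + seq_len(Wd), , drop = FALSE]
  list(dW = dW, db = db, dx = dx)
}

upsample2 <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), ,
    drop = FALSE]
}

downsum2 <- function(dy) {
  d <- dim(dy)
  o <- seq(1L, d[2], by = 2L); e <- o + 1L
  ow <- seq(1L, d[3], by = 2L); ew <- ow + 1L
  dy[, o, ow, , drop = FALSE] + dy[, o, ew, , drop = FALSE] +
    dy[, e, ow, , drop = FALSE] + dy[, e, ew, , drop = FALSE]
}

init_detector <- function(cfg) {
  with_seed(cfg$seed, {
    layers <- list()
    cin <- 1L
    for (i in seq_along(cfg$channels)) {
      cout <- cfg$channels[i]
      layers[[length(layers) + 1L]] <- list(
        type = "conv", stride = 2L,
        W = array(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                  dim = c(3, 3, cin, cout)),
        b = numeric(cout))
      cin <- cout
    }
    for (i in seq_along(cfg$up_channels)) {
      cout <- cfg$up_channels[i]
      layers[[length(layers) + 1L]] <- list(
        type = "upconv", stride = 1L,
        W = array(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))),
                  dim = c(3, 3, cin, cout)),
        b = numeric(cout))
      cin <- cout
    }
    layers[[length(layers) + 1L]] <- list(
      type = "head", stride = 1L,
      W = array(rnorm(cin * cfg$n_classes, sd = sqrt(2 / cin)),
                dim = c(1, 1, cin, cfg$n_classes)),
      b = numeric(cfg$n_classes))
    layers
  })
}

detector_stride <- function(cfg) {
  as.integer(2^length(cfg$channels) / 2^length(cfg$up_channels))
}

forward_detector <- function(layers, x, keep = FALSE) {
  cache <- list()
  for (li in seq_along(layers)) {
    L <- layers[[li]]
    if (L$type == "upconv") x <- upsample2(x)
    if (keep) cache[[li]] <- x
    if (L$type == "head") {
      d <- dim(x)
      xm <- x; dim(xm) <- c(prod(d[1:3]), d[4])
      z <- xm %*% matrix(L$W[1, 1, , ], d[4], dim(L$W)[4])
      z <- sweep(z, 2, L$b, "+")
      dim(z) <- c(d[1:3], dim(L$W)[4])
      x <- z
    } else {
      x <- conv_forward(x, L$W, L$b, L$stride)
      x <- pmax(x, 0)  # ReLU
    }
  }
  logits <- x
  list(prob = 1 / (1 + exp(-logits)), logits = logits, cache = cache)
}

#' Train the heatmap detector
#'
#' Minimizes per-pixel binary cross-entropy (or MSE) between the sigmoid
#' heatmap and the Gaussian targets with Adam; batches are drawn in a
#' seeded, reproducible order. `epochs = 0` returns the freshly initialized
#' model untouched.
#'
#' @param frames array (N, H, W) of grayscale frames in [0, 1].
#' @param targets array (N, Ho, Wo, classes) from [make_heatmap_targets()].
#' @param cfg a [detector_config()].
#' @return `detector_model` list: `layers`, `cfg`, `stride`,
#'   `loss_history` (mean loss per epoch).
#' @export
train_detector <- function(frames, targets, cfg = detector_config()) {
  d <- dim(frames)
  stopifnot(length(d) == 3)
  x_all <- array(frames, dim = c(d, 1L))
  stride <- detector_stride(cfg)
  td <- dim(targets)
  if (td[1] != d[1] || td[2] != d[2] %/% stride || td[3] != d[3] %/% stride) {
    stop("frames/targets shape mismatch for this architecture")
  }
  layers <- init_detector(cfg)
  mstate <- lapply(layers, function(L) list(mW = 0 * L$W, vW = 0 * L$W,
                                            mb = 0 * L$b, vb = 0 * L$b))
  loss_hist <- numeric(0)
  if (cfg$epochs > 0) {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0
    order_all <- with_seed(cfg$seed + 1L, {
      lapply(seq_len(cfg$epochs), function(e) sample.int(d[1]))
    })
    for (ep in seq_len(cfg$epochs)) {
      idx <- order_all[[ep]]
      batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
      ep_loss <- 0; ep_n <- 0
      for (bidx in batches) {
        xb <- x_all[bidx, , , , drop = FALSE]
        yb <- targets[bidx, , , , drop = FALSE]
        fw <- forward_detector(layers, xb, keep = TRUE)
        p <- fw$prob
        wpix <- 1 + (cfg$pos_weight - 1) * yb
        npix <- length(p)
        if (cfg$loss == "bce") {
          eps2 <- 1e-12
          lvec <- -(yb * log(p + eps2) + (1 - yb) * log(1 - p + eps2)) * wpix
          dlogit <- wpix * (p - yb) / npix
        } else {
          lvec <- wpix * (p - yb)^2
          dlogit <- wpix * 2 * (p - yb) * p * (1 - p) / npix
        }
        ep_loss <- ep_loss + sum(lvec); ep_n <- ep_n + npix
        # backward
        dy <- dlogit
        tstep <- tstep + 1
        for (li in rev(seq_along(layers))) {
          L <- layers[[li]]
          xin <- fw$cache[[li]]
          if (L$type == "head") {
            dd <- dim(xin)
            xm <- xin; dim(xm) <- c(prod(dd[1:3]), dd[4])
            dym <- dy; dim(dym) <- c(prod(dd[1:3]), dim(L$W)[4])
            dW <- array(crossprod(xm, dym), dim = dim(L$W))
            db <- colSums(dym)
            dx <- dym %*% t(matrix(L$W[1, 1, , ], dd[4], dim(L$W)[4]))
            dim(dx) <- dd
          } else {
            # ReLU grad uses the layer output; recompute cheap mask from
            # forward pass of this layer
            out <- conv_forward(xin, L$W, L$b, L$stride)
            dy <- dy * (out > 0)
            bk <- conv_backward(xin, L$W, dy, L$stride)
            dW <- bk$dW; db <- bk$db; dx <- bk$dx
            if (L$type == "upconv") dx <- downsum2(dx)
          }
          ms <- mstate[[li]]
          ms$mW <- b1 * ms$mW + (1 - b1) * dW
          ms$vW <- b2 * ms$vW + (1 - b2) * dW^2
          ms$mb <- b1 * ms$mb + (1 - b1) * db
          ms$vb <- b2 * ms$vb + (1 - b2) * db^2
          mhW <- ms$mW / (1 - b1^tstep); vhW <- ms$vW / (1 - b2^tstep)
          mhb <- ms$mb / (1 - b1^tstep); vhb <- ms$vb / (1 - b2^tstep)
          layers[[li]]$W <- L$W - cfg$lr * mhW / (sqrt(vhW) + eps)
          layers[[li]]$b <- L$b - cfg$lr * mhb / (sqrt(vhb) + eps)
          mstate[[li]] <- ms
          dy <- dx
        }
      }
      loss_hist <- c(loss_hist, ep_loss / ep_n)
    }
  }
  structure(list(layers = layers, cfg = cfg, stride = stride,
                 loss_history = loss_hist),
            class = "detector_model")
}

#' Predict heatmaps for a stack of frames
#'
#' @param model a trained `detector_model`.
#' @param frames array (N, H, W).
#' @param batch_size frames per forward pass.
#' @return array (N, Ho, Wo, classes) of sigmoid confidences in (0, 1).
#' @export
predict_heatmaps <- function(model, frames, batch_size = 32L) {
  d <- dim(frames)
  n <- d[1]
  out <- NULL
  for (i0 in seq(1L, n, by = batch_size)) {
    ii <- i0:min(n, i0 + batch_size - 1L)
    xb <- array(frames[ii, , , drop = FALSE], dim = c(length(ii), d[2], d[3], 1L))
    p <- forward_detector(model$layers, xb)$prob
    if (is.null(out)) out <- array(0, dim = c(n, dim(p)[2:4]))
    out[ii, , , ] <- p
  }
  out
}

#' Non-maximum suppression on a single-class heatmap
#'
#' Retains strict 8-neighborhood local maxima at or above the confidence
#' threshold, then greedily suppresses, in descending confidence (ties by
#' row then column), any remaining peak within `radius_px` (Euclidean,
#' inclusive) of a retained one.
#'
#' @param map numeric matrix in [0, 1] (rows = y, cols = x).
#' @param conf_thresh minimum peak confidence.
#' @param radius_px suppression radius in map pixels.
#' @return data.frame `x`, `y`, `conf`, ordered by descending confidence.
#' @export
nms_peaks <- function(map, conf_thresh = 0.5, radius_px = 16) {
  if (radius_px <= 0) stop("radius_px must be > 0", call. = FALSE)
  h <- nrow(map); w <- ncol(map)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- map
  ctr <- pad[2:(h + 1), 2:(w + 1)]
  ismax <- ctr >= conf_thresh
  for (dh in -1:1) for (dw in -1:1) {
    if (dh == 0 && dw == 0) next
    ismax <- ismax & (ctr > pad[2:(h + 1) + dh, 2:(w + 1) + dw])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), conf = numeric(0)))
  }
  conf <- map[idx]
  ord <- order(-conf, idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]; conf <- conf[ord]
  keep <- logical(length(conf))
  for (i in seq_along(conf)) {
    if (i == 1) { keep[1] <- TRUE; next }
    ki <- which(keep)
    dd <- sqrt((idx[ki, 1] - idx[i, 1])^2 + (idx[ki, 2] - idx[i, 2])^2)
    keep[i] <- all(dd > radius_px)
  }
  data.frame(x = idx[keep, 2], y = idx[keep, 1], conf = conf[keep])
}

#' Frame classification from detector output
#'
#' Runs the detector over a frame stack, applies NMS per frame and class,
#' and marks a frame positive for a class iff at least one detection is
#' retained. Detection coordinates are reported at input resolution
#' (map coordinates times the output stride).
#'
#' @param model trained `detector_model`.
#' @param frames array (N, H, W).
#' @param conf_thresh,radius_px NMS parameters (radius at input scale).
#' @param classes class names (channel order).
#' @return list `ethogram` (N x classes logical matrix), `detections`
#'   (data.frame `frame,class,x,y,conf`).
#' @export
classify_frames <- function(model, frames, conf_thresh = 0.5, radius_px = 16,
                            classes = "attending") {
  hm <- predict_heatmaps(model, frames)
  n <- dim(hm)[1]; nc <- dim(hm)[4]
  stopifnot(length(classes) == nc)
  etho <- matrix(FALSE, n, nc, dimnames = list(NULL, classes))
  dets <- vector("list", n * nc)
  r_map <- radius_px / model$stride
  for (f in seq_len(n)) for (ci in seq_len(nc)) {
    pk <- nms_peaks(hm[f, , , ci], conf_thresh, max(r_map, 1e-9))
    if (nrow(pk) > 0) {
      etho[f, ci] <- TRUE
      dets[[(f - 1) * nc + ci]] <- data.frame(
        frame = f, class = classes[ci],
        x = pk$x * model$stride, y = pk$y * model$stride, conf = pk$conf)
    }
  }
  dets <- do.call(rbind, dets[!vapply(dets, is.null, logical(1))])
  if (is.null(dets)) {
    dets <- data.frame(frame = integer(0), class = character(0),
                       x = numeric(0), y = numeric(0), conf = numeric(0))
  }
  list(ethogram = etho, detections = dets)
}
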