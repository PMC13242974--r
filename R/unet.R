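## U-Net encoder-decoder for stratum-corneum segmentation, implemented
## directly on BLAS: 3x3 convolutions as im2col + gemm, 2x2 max pooling,
## nearest-neighbour upsampling followed by a 3x3 "up-convolution", skip
## concatenations, a 1x1 sigmoid output head, and Adam. Feature maps are
## stored as (B*H*W) x C matrices with column-major pixel order per image,
## which keeps every heavy step a single matrix product or indexed copy.

# cache of index maps keyed by geometry; shared across calls
.idxCache <- new.env(parent = emptyenv())

.cacheGet <- function(key, build) {
  if (is.null(.idxCache[[key]])) .idxCache[[key]] <- build()
  .idxCache[[key]]
}

# 9 index vectors mapping each output pixel to its (zero-padded) input row
.convIndex <- function(H, W, B) {
  .cacheGet(sprintf("conv:%d:%d:%d", H, W, B), function() {
    n <- H * W
    pad <- B * n + 1L
    rr <- rep.int(seq_len(H), W)
    cc <- rep(seq_len(W), each = H)
    off <- rep((0:(B - 1L)) * n, each = n)
    idx <- vector("list", 9L)
    o <- 0L
    for (dc in -1:1) {
      for (dr in -1:1) {
        o <- o + 1L
        r2 <- rr + dr
        c2 <- cc + dc
        base <- r2 + (c2 - 1L) * H
        base[r2 < 1L | r2 > H | c2 < 1L | c2 > W] <- NA_integer_
        v <- rep(base, B) + off
        v[is.na(v)] <- pad
        idx[[o]] <- as.integer(v)
      }
    }
    idx
  })
}

# index quadruple of the 2x2 pooling windows
.poolIndex <- function(H, W, B) {
  .cacheGet(sprintf("pool:%d:%d:%d", H, W, B), function() {
    Ho <- H %/% 2L
    Wo <- W %/% 2L
    ro <- rep.int(seq_len(Ho), Wo)
    co <- rep(seq_len(Wo), each = Ho)
    r1 <- 2L * ro - 1L
    c1 <- 2L * co - 1L
    off <- rep((0:(B - 1L)) * H * W, each = Ho * Wo)
    lin <- function(r, c) as.integer(rep(r + (c - 1L) * H, B) + off)
    list(lin(r1, c1), lin(r1 + 1L, c1), lin(r1, c1 + 1L), lin(r1 + 1L, c1 + 1L))
  })
}

# fine-pixel -> coarse-pixel map for nearest-neighbour 2x upsampling
.upIndex <- function(Ho, Wo, B) {
  .cacheGet(sprintf("up:%d:%d:%d", Ho, Wo, B), function() {
    H <- 2L * Ho
    W <- 2L * Wo
    rf <- rep.int(seq_len(H), W)
    cf <- rep(seq_len(W), each = H)
    v <- ((rf + 1L) %/% 2L) + (((cf + 1L) %/% 2L) - 1L) * Ho
    off <- rep((0:(B - 1L)) * Ho * Wo, each = H * W)
    as.integer(rep(v, B) + off)
  })
}

.convForward <- function(X, Wt, b, idx) {
  cin <- ncol(X)
  n <- length(idx[[1L]])
  Xp <- rbind(X, 0)
  Xc <- matrix(0, n, 9L * cin)
  for (o in 1:9) {
    Xc[, ((o - 1L) * cin + 1L):(o * cin)] <- Xp[idx[[o]], , drop = FALSE]
  }
  Z <- Xc %*% Wt
  Z <- Z + rep(b, each = n)
  list(Z = Z, Xc = Xc)
}

.convBackward <- function(dZ, Xc, Wt, idx, cin, nIn) {
  dW <- crossprod(Xc, dZ)
  db <- colSums(dZ)
  dXc <- tcrossprod(dZ, Wt)
  dX <- matrix(0, nIn + 1L, cin)
  for (o in 1:9) {
    ii <- idx[[o]]
    dX[ii, ] <- dX[ii, ] + dXc[, ((o - 1L) * cin + 1L):(o * cin), drop = FALSE]
  }
  list(dX = dX[seq_len(nIn), , drop = FALSE], dW = dW, db = db)
}

.heInit <- function(fanIn, nOut) {
  matrix(stats::rnorm(fanIn * nOut, sd = sqrt(2 / fanIn)), fanIn, nOut)
}

.initUnetParams <- function(depth, base) {
  ch <- function(i) as.integer(base * 2L^(i - 1L))
  p <- list()
  inC <- 1L
  for (i in seq_len(depth)) {
    p[[sprintf("enc%d.c1.W", i)]] <- .heInit(9L * inC, ch(i))
    p[[sprintf("enc%d.c1.b", i)]] <- numeric(ch(i))
    p[[sprintf("enc%d.c2.W", i)]] <- .heInit(9L * ch(i), ch(i))
    p[[sprintf("enc%d.c2.b", i)]] <- numeric(ch(i))
    inC <- ch(i)
  }
  p[["bot.c1.W"]] <- .heInit(9L * ch(depth), ch(depth + 1L))
  p[["bot.c1.b"]] <- numeric(ch(depth + 1L))
  p[["bot.c2.W"]] <- .heInit(9L * ch(depth + 1L), ch(depth + 1L))
  p[["bot.c2.b"]] <- numeric(ch(depth + 1L))
  for (i in depth:1) {
    p[[sprintf("dec%d.up.W", i)]] <- .heInit(9L * ch(i + 1L), ch(i))
    p[[sprintf("dec%d.up.b", i)]] <- numeric(ch(i))
    p[[sprintf("dec%d.c1.W", i)]] <- .heInit(9L * 2L * ch(i), ch(i))
    p[[sprintf("dec%d.c1.b", i)]] <- numeric(ch(i))
    p[[sprintf("dec%d.c2.W", i)]] <- .heInit(9L * ch(i), ch(i))
    p[[sprintf("dec%d.c2.b", i)]] <- numeric(ch(i))
  }
  p[["out.W"]] <- matrix(stats::rnorm(ch(1L), sd = sqrt(2 / ch(1L))), ch(1L), 1L)
  p[["out.b"]] <- 0
  p
}

# forward pass; with keep = TRUE also returns the caches backprop needs
.unetForward <- function(p, X, H, W, B, depth, keep = FALSE) {
  cache <- list()
  convRelu <- function(A, name, h, w) {
    idx <- .convIndex(h, w, B)
    cv <- .convForward(A, p[[paste0(name, ".W")]], p[[paste0(name, ".b")]], idx)
    A2 <- cv$Z
    mask <- A2 > 0
    A2[!mask] <- 0
    if (keep) {
      cache[[name]] <<- list(Xc = cv$Xc, mask = mask, cin = ncol(A),
                             nIn = nrow(A), h = h, w = w)
    }
    A2
  }
  A <- X
  h <- H
  w <- W
  skips <- vector("list", depth)
  for (i in seq_len(depth)) {
    A <- convRelu(A, sprintf("enc%d.c1", i), h, w)
    A <- convRelu(A, sprintf("enc%d.c2", i), h, w)
    skips[[i]] <- A
    pid <- .poolIndex(h, w, B)
    X1 <- A[pid[[1L]], , drop = FALSE]
    X2 <- A[pid[[2L]], , drop = FALSE]
    X3 <- A[pid[[3L]], , drop = FALSE]
    X4 <- A[pid[[4L]], , drop = FALSE]
    Y <- pmax(X1, X2, X3, X4)
    if (keep) {
      cache[[sprintf("pool%d", i)]] <- list(
        parts = list(X1, X2, X3, X4), Y = Y, h = h, w = w, nIn = nrow(A)
      )
    }
    A <- Y
    h <- h %/% 2L
    w <- w %/% 2L
  }
  A <- convRelu(A, "bot.c1", h, w)
  A <- convRelu(A, "bot.c2", h, w)
  for (i in depth:1) {
    uid <- .upIndex(h, w, B)
    A <- A[uid, , drop = FALSE]
    h <- 2L * h
    w <- 2L * w
    A <- convRelu(A, sprintf("dec%d.up", i), h, w)
    if (keep) cache[[sprintf("skipw%d", i)]] <- ncol(skips[[i]])
    A <- cbind(skips[[i]], A)
    A <- convRelu(A, sprintf("dec%d.c1", i), h, w)
    A <- convRelu(A, sprintf("dec%d.c2", i), h, w)
  }
  Aout <- A
  Z <- Aout %*% p[["out.W"]] + p[["out.b"]]
  if (keep) cache[["out"]] <- list(A = Aout)
  list(Z = Z, cache = cache)
}

# backward pass; returns gradients named like the parameters
.unetBackward <- function(p, cache, dZ, H, W, B, depth) {
  g <- list()
  convReluBack <- function(dA, name) {
    cc <- cache[[name]]
    dA[!cc$mask] <- 0
    idx <- .convIndex(cc$h, cc$w, B)
    bk <- .convBackward(dA, cc$Xc, p[[paste0(name, ".W")]], idx, cc$cin, cc$nIn)
    g[[paste0(name, ".W")]] <<- bk$dW
    g[[paste0(name, ".b")]] <<- bk$db
    bk$dX
  }
  outA <- cache[["out"]]$A
  g[["out.W"]] <- crossprod(outA, dZ)
  g[["out.b"]] <- sum(dZ)
  dA <- tcrossprod(dZ, p[["out.W"]])
  dSkips <- vector("list", depth)
  h <- H
  w <- W
  for (i in 1:depth) {
    dA <- convReluBack(dA, sprintf("dec%d.c2", i))
    dA <- convReluBack(dA, sprintf("dec%d.c1", i))
    sw <- cache[[sprintf("skipw%d", i)]]
    dSkips[[i]] <- dA[, seq_len(sw), drop = FALSE]
    dA <- dA[, -seq_len(sw), drop = FALSE]
    dA <- convReluBack(dA, sprintf("dec%d.up", i))
    # undo nearest-neighbour upsampling: sum the 4 children of each coarse px
    cc <- cache[[sprintf("dec%d.up", i)]]
    uid <- .upIndex(cc$h %/% 2L, cc$w %/% 2L, B)
    dA <- rowsum(dA, uid, reorder = TRUE)
  }
  dA <- convReluBack(dA, "bot.c2")
  dA <- convReluBack(dA, "bot.c1")
  for (i in depth:1) {
    pc <- cache[[sprintf("pool%d", i)]]
    pid <- .poolIndex(pc$h, pc$w, B)
    dX <- matrix(0, pc$nIn, ncol(dA))
    taken <- matrix(FALSE, nrow(dA), ncol(dA))
    for (q in 1:4) {
      m <- (pc$parts[[q]] == pc$Y) & !taken
      taken <- taken | m
      ii <- pid[[q]]
      dX[ii, ] <- dX[ii, ] + dA * m
    }
    dA <- dX + dSkips[[i]]   # pooled path + decoder skip concatenation
    dA <- convReluBack(dA, sprintf("enc%d.c2", i))
    dA <- convReluBack(dA, sprintf("enc%d.c1", i))
  }
  g
}

# combined binary cross-entropy (on logits) + soft-Dice loss and gradient
.segLoss <- function(Z, Tg, lossType) {
  n <- length(Z)
  P <- stats::plogis(Z)
  out <- list(loss = 0, dZ = 0)
  if (lossType %in% c("bce", "bce+dice")) {
    bce <- mean(pmax(Z, 0) - Z * Tg + log1p(exp(-abs(Z))))
    out$loss <- out$loss + bce
    out$dZ <- out$dZ + (P - Tg) / n
  }
  if (lossType %in% c("dice", "bce+dice")) {
    eps <- 1
    sp <- sum(P)
    st <- sum(Tg)
    inter <- sum(P * Tg)
    denom <- sp + st + eps
    out$loss <- out$loss + 1 - (2 * inter + eps) / denom
    dP <- -(2 * Tg * denom - (2 * inter + eps)) / denom^2
    out$dZ <- out$dZ + dP * P * (1 - P)
  }
  out
}

#' Construct a training configuration
#'
#' Architecture and optimization hyperparameters of the segmentation
#' U-Net. All values are exposed; defaults target CPU desk-scale training.
#'
#' @param depth encoder levels (default 4).
#' @param baseChannels channels of the first level (default 16); each
#'   deeper level doubles them.
#' @param loss `"bce"`, `"dice"` or `"bce+dice"` (default).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param epochs maximum epochs (default 50).
#' @param batchSize minibatch size (default 8).
#' @param patience early-stopping patience on validation loss (default 10).
#' @param seed seed fixing initialization and data order.
#' @param inputSizePx training raster side; must be divisible by `2^depth`.
#' @return a [TrainConfig-class].
#' @examples
#' trainConfig(depth = 2, baseChannels = 4, inputSizePx = 64)
#' @export
trainConfig <- function(depth = 4L, baseChannels = 16L,
                        loss = "bce+dice", learningRate = 1e-3,
                        epochs = 50L, batchSize = 8L, patience = 10L,
                        seed = 1L, inputSizePx = 512L) {
  new("TrainConfig",
    depth = as.integer(depth), baseChannels = as.integer(baseChannels),
    loss = loss, learningRate = learningRate, epochs = as.integer(epochs),
    batchSize = as.integer(batchSize), patience = as.integer(patience),
    seed = as.integer(seed), inputSizePx = as.integer(inputSizePx)
  )
}

#' Build an untrained U-Net
#'
#' Initializes a U-Net with `depth` encoder levels (two 3x3 convolutions
#' and a 2x2 max pool per level, channels doubling from `baseChannels`), a
#' two-convolution bottleneck, a mirrored decoder with nearest-neighbour
#' upsampling, 3x3 up-convolutions and skip concatenations, and a 1x1
#' sigmoid output congruent with the input raster. Weights use He
#' initialization seeded from the config.
#'
#' @param config a [TrainConfig-class].
#' @return an untrained [UNetModel-class].
#' @examples
#' m <- buildUnet(trainConfig(depth = 1, baseChannels = 1, inputSizePx = 16))
#' @export
buildUnet <- function(config) {
  stopifnot(is(config, "TrainConfig"))
  validObject(config)
  set.seed(config@seed)
  params <- .initUnetParams(config@depth, config@baseChannels)
  new("UNetModel",
    params = params, config = config,
    history = data.frame(epoch = integer(), trainLoss = numeric(),
                         valLoss = numeric()),
    bestEpoch = NA_integer_
  )
}

.checkGeom <- function(H, W, depth) {
  if (H %% 2L^depth != 0L || W %% 2L^depth != 0L) {
    stop(sprintf(
      "configuration error: raster %d x %d not divisible by 2^depth = %d",
      H, W, 2L^depth
    ))
  }
}

.stackBatch <- function(imgList) {
  matrix(unlist(imgList, use.names = FALSE), ncol = 1L)
}

#' Train a U-Net on images and masks
#'
#' Minibatch Adam training with a combined BCE + soft-Dice loss (per the
#' model config), per-epoch train/validation loss history, best-validation
#' checkpointing and early stopping. A fixed config seed fixes the weight
#' initialization and the shuffling order, making runs reproducible.
#'
#' @param model an untrained (or previously trained) [UNetModel-class].
#' @param images named list of `H x W` matrices in `[0, 1]`.
#' @param masks named list of congruent 0/1 matrices.
#' @param split a [DatasetSplit-class] naming train/validation items, or
#'   `NULL` to use `trainIdsChr`/`valIdsChr`.
#' @param trainIdsChr,valIdsChr explicit id vectors (ignored when `split`
#'   is given).
#' @param verbose print per-epoch losses.
#' @return the trained [UNetModel-class] with `history()` filled in.
#' @export
trainUnet <- function(model, images, masks, split = NULL,
                      trainIdsChr = NULL, valIdsChr = NULL, verbose = FALSE) {
  stopifnot(is(model, "UNetModel"))
  cfg <- model@config
  if (!is.null(split)) {
    stopifnot(is(split, "DatasetSplit"))
    trainIdsChr <- split@trainIds
    valIdsChr <- split@valIds
  }
  if (!length(trainIdsChr) || !length(valIdsChr)) {
    stop("training error: train and validation subsets must be non-empty")
  }
  missing <- setdiff(c(trainIdsChr, valIdsChr), names(images))
  if (length(missing)) {
    stop("training error: images missing for ids: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  d1 <- dim(images[[trainIdsChr[1L]]])
  H <- d1[1L]
  W <- d1[2L]
  .checkGeom(H, W, cfg@depth)

  p <- model@params
  adamM <- lapply(p, function(x) x * 0)
  adamV <- adamM
  b1 <- 0.9
  b2 <- 0.999
  epsA <- 1e-8
  stepN <- 0L

  evalLoss <- function(ids) {
    tot <- 0
    for (i in seq(1L, length(ids), by = cfg@batchSize)) {
      ix <- ids[i:min(i + cfg@batchSize - 1L, length(ids))]
      B <- length(ix)
      X <- .stackBatch(images[ix])
      Tg <- .stackBatch(masks[ix])
      fw <- .unetForward(p, X, H, W, B, cfg@depth, keep = FALSE)
      tot <- tot + .segLoss(fw$Z, Tg, cfg@loss)$loss * B
    }
    tot / length(ids)
  }

  set.seed(cfg@seed + 1L)
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric())
  bestVal <- Inf
  bestParams <- p
  bestEpoch <- NA_integer_
  sinceBest <- 0L

  for (ep in seq_len(cfg@epochs)) {
    order <- sample(trainIdsChr)
    epLoss <- 0
    for (i in seq(1L, length(order), by = cfg@batchSize)) {
      ix <- order[i:min(i + cfg@batchSize - 1L, length(order))]
      B <- length(ix)
      X <- .stackBatch(images[ix])
      Tg <- .stackBatch(masks[ix])
      fw <- .unetForward(p, X, H, W, B, cfg@depth, keep = TRUE)
      ls <- .segLoss(fw$Z, Tg, cfg@loss)
      if (!is.finite(ls$loss)) {
        stop(sprintf(
          "training error: non-finite loss at epoch %d, batch starting '%s'",
          ep, ix[1L]
        ))
      }
      epLoss <- epLoss + ls$loss * B
      g <- .unetBackward(p, fw$cache, ls$dZ, H, W, B, cfg@depth)
      stepN <- stepN + 1L
      corr1 <- 1 - b1^stepN
      corr2 <- 1 - b2^stepN
      for (nm in names(p)) {
        gi <- g[[nm]]
        adamM[[nm]] <- b1 * adamM[[nm]] + (1 - b1) * gi
        adamV[[nm]] <- b2 * adamV[[nm]] + (1 - b2) * gi * gi
        p[[nm]] <- p[[nm]] - cfg@learningRate * (adamM[[nm]] / corr1) /
          (sqrt(adamV[[nm]] / corr2) + epsA)
      }
    }
    trainLoss <- epLoss / length(order)
    valLoss <- evalLoss(valIdsChr)
    hist <- rbind(hist, data.frame(epoch = ep, trainLoss = trainLoss,
                                   valLoss = valLoss))
    if (verbose) {
      message(sprintf("epoch %3d: train %.4f  val %.4f", ep, trainLoss, valLoss))
    }
    if (valLoss < bestVal - 1e-12) {
      bestVal <- valLoss
      bestParams <- p
      bestEpoch <- ep
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= cfg@patience) break
    }
  }
  new("UNetModel",
    params = bestParams, config = cfg, history = hist,
    bestEpoch = as.integer(bestEpoch)
  )
}

#' Predict a binary stratum-corneum mask for one frame
#'
#' Runs the U-Net forward pass and thresholds the sigmoid output. The tie
#' at a probability of exactly `threshold` is broken toward background
#' (strict `>`), so a zero-weight model yields an empty mask.
#'
#' @param model a [UNetModel-class].
#' @param frame an `H x W` matrix with both sides divisible by `2^depth`.
#' @param threshold probability threshold in `(0, 1)` (default 0.5).
#' @return an integer 0/1 matrix congruent with `frame`.
#' @export
predictMask <- function(model, frame, threshold = 0.5) {
  stopifnot(is(model, "UNetModel"), is.matrix(frame))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  pr <- predictProbability(model, frame)
  matrix(as.integer(pr > threshold), nrow(frame), ncol(frame))
}

#' @rdname predictMask
#' @return `predictProbability()` returns the sigmoid probability map.
#' @export
predictProbability <- function(model, frame) {
  stopifnot(is(model, "UNetModel"), is.matrix(frame))
  d <- dim(frame)
  .checkGeom(d[1L], d[2L], model@config@depth)
  fw <- .unetForward(model@params, matrix(as.numeric(frame), ncol = 1L),
                     d[1L], d[2L], 1L, model@config@depth, keep = FALSE)
  matrix(stats::plogis(fw$Z), d[1L], d[2L])
}

#' Predict masks for a whole frame stack
#'
#' Batched inference over an `H x W x T` array; equivalent to calling
#' [predictMask()] frame by frame but substantially faster because frames
#' share each convolution's matrix product.
#'
#' @param model a [UNetModel-class].
#' @param framesArr `H x W x T` numeric array.
#' @param threshold probability threshold (default 0.5).
#' @param batchSize frames per forward pass (default 8).
#' @return an integer 0/1 array congruent with `framesArr`.
#' @export
predictMaskStack <- function(model, framesArr, threshold = 0.5, batchSize = 8L) {
  stopifnot(is(model, "UNetModel"), length(dim(framesArr)) == 3L)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  d <- dim(framesArr)
  .checkGeom(d[1L], d[2L], model@config@depth)
  out <- array(0L, dim = d)
  for (i in seq(1L, d[3L], by = batchSize)) {
    ix <- i:min(i + batchSize - 1L, d[3L])
    B <- length(ix)
    X <- matrix(as.numeric(framesArr[, , ix]), ncol = 1L)
    fw <- .unetForward(model@params, X, d[1L], d[2L], B, model@config@depth,
                       keep = FALSE)
    out[, , ix] <- array(as.integer(stats::plogis(fw$Z) > threshold),
                         dim = c(d[1L], d[2L], B))
  }
  out
}

#' Save / load a U-Net checkpoint
#'
#' The checkpoint is an RDS of the parameter list plus a JSON sidecar
#' describing the architecture, so a model can be inspected without
#' deserializing it.
#'
#' @param model a [UNetModel-class].
#' @param path file path of the checkpoint (`.rds`).
#' @return `loadUnet()` returns the [UNetModel-class].
#' @export
saveUnet <- function(model, path) {
  stopifnot(is(model, "UNetModel"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  cfg <- model@config
  jsonlite::write_json(
    list(
      depth = cfg@depth, base_channels = cfg@baseChannels, loss = cfg@loss,
      learning_rate = cfg@learningRate, epochs = cfg@epochs,
      batch_size = cfg@batchSize, seed = cfg@seed,
      input_size_px = cfg@inputSizePx, best_epoch = model@bestEpoch,
      n_parameters = sum(vapply(model@params, length, 1L))
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname saveUnet
#' @export
loadUnet <- function(path) {
  m <- readRDS(path)
  stopifnot(is(m, "UNetModel"))
  m
}
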