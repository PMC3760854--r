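#' Encode a region and its structural tracks as BRNN input channels
#'
#' Builds the fixed 26-channel per-residue input layout: channels 1-20 are a
#' one-hot encoding of the 20 standard amino acids (a non-standard residue
#' maps to an all-zero block, with a warning), channel 21 encodes the parent
#' sequence length (length / 1000, clipped to [0, 1], constant across
#' positions), channels 22-24 the predicted helix/strand/coil probabilities,
#' channel 25 the predicted disorder and channel 26 the normalised docking
#' score. Structural channels not selected in `features` are zero-filled, so
#' all seven feature combinations share one input geometry.
#'
#' @param region a [ProteinRegion-class]
#' @param ss L x 3 matrix of helix/strand/coil probabilities (rows sum to 1)
#' @param disorder numeric disorder track in [0, 1], length L
#' @param vina numeric normalised docking-score track in [0, 1], length L
#' @param features character subset of `c("ss", "disorder", "vina")` naming
#'   the structural channels to fill (default: all three)
#' @return numeric matrix L x 26
#' @export
encodeInputs <- function(region, ss = NULL, disorder = NULL, vina = NULL,
                         features = c("ss", "disorder", "vina")) {
  stopifnot(is(region, "ProteinRegion"))
  if (length(features))
    features <- match.arg(features, several.ok = TRUE)
  L <- nchar(region@seq)
  x <- matrix(0, L, 26L)
  res <- strsplit(region@seq, "")[[1]]
  idx <- match(res, AA_ALPHABET20)
  if (anyNA(idx))
    warning("non-standard residue(s) ", paste(unique(res[is.na(idx)]), collapse = ","),
            " encoded as all-zero one-hot")
  ok <- which(!is.na(idx))
  x[cbind(ok, idx[ok])] <- 1
  x[, 21L] <- min(region@parentLength / 1000, 1)
  if ("ss" %in% features) {
    if (is.null(ss)) stop("ss track requested but not supplied", call. = FALSE)
    ss <- as.matrix(ss)
    if (nrow(ss) != L || ncol(ss) != 3)
      stop("ss must be an L x 3 matrix", call. = FALSE)
    if (any(ss < 0) || any(abs(rowSums(ss) - 1) > 1e-6))
      stop("ss rows must be probability vectors summing to 1", call. = FALSE)
    x[, 22:24] <- ss
  }
  if ("disorder" %in% features) {
    if (is.null(disorder)) stop("disorder track requested but not supplied",
                                call. = FALSE)
    if (length(disorder) != L) stop("disorder track length mismatch", call. = FALSE)
    x[, 25L] <- assertProb(disorder, "disorder")
  }
  if ("vina" %in% features) {
    if (is.null(vina)) stop("vina track requested but not supplied", call. = FALSE)
    if (length(vina) != L) stop("vina track length mismatch", call. = FALSE)
    x[, 26L] <- assertProb(vina, "normalised docking score")
  }
  x
}

#' Initialise a BRNN model
#'
#' Weights of the three two-layer update networks are drawn uniform(-0.1, 0.1)
#' from `seed`; boundary hidden states are implicit zeros.
#'
#' @param nIn input channels per residue (default 26)
#' @param window odd local input window for the output network (default 9)
#' @param hidden hidden-chain state width (default 11)
#' @param ffHidden hidden-layer width of the update networks (default 20)
#' @param seed integer seed for reproducible initialisation
#' @return a [BRNNModel-class]
#' @export
newBRNN <- function(nIn = 26L, window = 9L, hidden = 11L, ffHidden = 20L,
                    seed = NULL) {
  nIn <- as.integer(nIn); window <- as.integer(window)
  hidden <- as.integer(hidden); ffHidden <- as.integer(ffHidden)
  rmat <- function(r, c) matrix(stats::runif(r * c, -0.1, 0.1), r, c)
  weights <- withSeed(seed, list(
    Wf1 = rmat(nIn + hidden, ffHidden), bf1 = stats::runif(ffHidden, -0.1, 0.1),
    Wf2 = rmat(ffHidden, hidden),       bf2 = stats::runif(hidden, -0.1, 0.1),
    Wb1 = rmat(nIn + hidden, ffHidden), bb1 = stats::runif(ffHidden, -0.1, 0.1),
    Wb2 = rmat(ffHidden, hidden),       bb2 = stats::runif(hidden, -0.1, 0.1),
    Wo1 = rmat(nIn * window + 2L * hidden, ffHidden),
    bo1 = stats::runif(ffHidden, -0.1, 0.1),
    Wo2 = rmat(ffHidden, 1L),           bo2 = stats::runif(1L, -0.1, 0.1)))
  new("BRNNModel", nIn = nIn, window = window, hidden = hidden,
      ffHidden = ffHidden, weights = weights,
      log = data.frame(epoch = integer(), loss = numeric(), lr = numeric()))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Stack equal-length feature matrices into per-position B x nIn matrices,
# zero-padded by half a window on each side for the output net's local window.
stackBatch <- function(xs, nIn, hw) {
  L <- nrow(xs[[1]]); B <- length(xs)
  Xl <- vector("list", L + 2L * hw)
  zero <- matrix(0, B, nIn)
  for (p in seq_len(hw)) Xl[[p]] <- zero
  for (p in seq_len(hw)) Xl[[L + hw + p]] <- zero
  for (j in seq_len(L)) {
    m <- matrix(0, B, nIn)
    for (b in seq_len(B)) m[b, ] <- xs[[b]][j, ]
    Xl[[hw + j]] <- m
  }
  Xl
}

# Full forward pass over one equal-length batch; returns outputs and caches.
brnnForwardBatch <- function(wt, nIn, H, w, Xl, L, B) {
  hw <- (w - 1L) %/% 2L
  U <- A1f <- Hf <- V <- A1b <- Hb <- Z <- A1o <- vector("list", L)
  hprev <- matrix(0, B, H)
  for (j in seq_len(L)) {
    U[[j]] <- cbind(Xl[[hw + j]], hprev)
    A1f[[j]] <- tanh(sweep(U[[j]] %*% wt$Wf1, 2, wt$bf1, `+`))
    Hf[[j]] <- tanh(sweep(A1f[[j]] %*% wt$Wf2, 2, wt$bf2, `+`))
    hprev <- Hf[[j]]
  }
  hnext <- matrix(0, B, H)
  for (j in rev(seq_len(L))) {
    V[[j]] <- cbind(Xl[[hw + j]], hnext)
    A1b[[j]] <- tanh(sweep(V[[j]] %*% wt$Wb1, 2, wt$bb1, `+`))
    Hb[[j]] <- tanh(sweep(A1b[[j]] %*% wt$Wb2, 2, wt$bb2, `+`))
    hnext <- Hb[[j]]
  }
  O <- matrix(0, B, L)
  for (j in seq_len(L)) {
    win <- do.call(cbind, Xl[j:(j + 2L * hw)])
    Z[[j]] <- cbind(win, Hf[[j]], Hb[[j]])
    A1o[[j]] <- tanh(sweep(Z[[j]] %*% wt$Wo1, 2, wt$bo1, `+`))
    O[, j] <- sigmoid(A1o[[j]] %*% wt$Wo2 + wt$bo2[1])
  }
  list(O = O, U = U, A1f = A1f, Hf = Hf, V = V, A1b = A1b, Hb = Hb,
       Z = Z, A1o = A1o)
}

# Backpropagation through time for one equal-length batch. dO is the gradient
# of the loss w.r.t. the output logits (B x L). Returns gradients named like
# the weights.
brnnBackwardBatch <- function(wt, nIn, H, w, cache, dO, L, B) {
  g <- lapply(wt, function(m) m * 0)
  dHfOut <- dHbOut <- vector("list", L)
  nw <- nIn * w
  for (j in seq_len(L)) {
    d2 <- dO[, j, drop = FALSE]                       # B x 1
    g$Wo2 <- g$Wo2 + crossprod(cache$A1o[[j]], d2)
    g$bo2 <- g$bo2 + sum(d2)
    d1 <- (d2 %*% t(wt$Wo2)) * (1 - cache$A1o[[j]]^2) # B x F
    g$Wo1 <- g$Wo1 + crossprod(cache$Z[[j]], d1)
    g$bo1 <- g$bo1 + colSums(d1)
    dz <- d1 %*% t(wt$Wo1)
    dHfOut[[j]] <- dz[, nw + seq_len(H), drop = FALSE]
    dHbOut[[j]] <- dz[, nw + H + seq_len(H), drop = FALSE]
  }
  carry <- matrix(0, B, H)
  for (j in rev(seq_len(L))) {
    dh <- dHfOut[[j]] + carry
    d2 <- dh * (1 - cache$Hf[[j]]^2)
    g$Wf2 <- g$Wf2 + crossprod(cache$A1f[[j]], d2)
    g$bf2 <- g$bf2 + colSums(d2)
    d1 <- (d2 %*% t(wt$Wf2)) * (1 - cache$A1f[[j]]^2)
    g$Wf1 <- g$Wf1 + crossprod(cache$U[[j]], d1)
    g$bf1 <- g$bf1 + colSums(d1)
    carry <- (d1 %*% t(wt$Wf1))[, nIn + seq_len(H), drop = FALSE]
  }
  carry <- matrix(0, B, H)
  for (j in seq_len(L)) {
    dh <- dHbOut[[j]] + carry
    d2 <- dh * (1 - cache$Hb[[j]]^2)
    g$Wb2 <- g$Wb2 + crossprod(cache$A1b[[j]], d2)
    g$bb2 <- g$bb2 + colSums(d2)
    d1 <- (d2 %*% t(wt$Wb2)) * (1 - cache$A1b[[j]]^2)
    g$Wb1 <- g$Wb1 + crossprod(cache$V[[j]], d1)
    g$bb1 <- g$bb1 + colSums(d1)
    carry <- (d1 %*% t(wt$Wb1))[, nIn + seq_len(H), drop = FALSE]
  }
  g
}

# Group a dataset (list of list(x = L x nIn matrix, y = labels)) by sequence
# length so each group can be processed as one batch.
groupByLength <- function(dataset) {
  lens <- vapply(dataset, function(d) nrow(d$x), integer(1))
  lapply(split(seq_along(dataset), lens), identity)
}

#' Per-residue predictions from a BRNN
#'
#' Runs the forward/backward hidden chains (zero boundary states) and the
#' windowed output network over one feature matrix. Outputs are logistic, so
#' strictly inside (0, 1), and are read as binding probabilities.
#'
#' @param model a [BRNNModel-class]
#' @param x feature matrix (L x nIn), see [encodeInputs()]
#' @return numeric vector of length L
#' @export
brnnPredict <- function(model, x) {
  stopifnot(is(model, "BRNNModel"))
  x <- as.matrix(x)
  if (ncol(x) != model@nIn)
    stop("feature matrix has ", ncol(x), " channels; model expects ",
         model@nIn, call. = FALSE)
  hw <- (model@window - 1L) %/% 2L
  Xl <- stackBatch(list(x), model@nIn, hw)
  fw <- brnnForwardBatch(model@weights, model@nIn, model@hidden, model@window,
                         Xl, nrow(x), 1L)
  as.numeric(fw$O[1L, ])
}

#' @describeIn brnnPredict `predict` method for [BRNNModel-class]
#' @param object a [BRNNModel-class]
#' @param ... ignored
#' @export
setMethod("predict", "BRNNModel", function(object, x, ...) brnnPredict(object, x))

#' Loss and analytic gradient of a BRNN on a labelled dataset
#'
#' Mean per-residue binary cross-entropy over all residues of the dataset,
#' with its exact gradient from backpropagation through time. Exposed so the
#' gradients can be validated against finite differences.
#'
#' @param model a [BRNNModel-class]
#' @param dataset list of `list(x = feature matrix, y = 0/1 labels)`
#' @return list with `loss` (numeric) and `grads` (list shaped like the
#'   model weights)
#' @export
brnnLossGrad <- function(model, dataset) {
  stopifnot(is(model, "BRNNModel"), length(dataset) > 0)
  wt <- model@weights
  nIn <- model@nIn; H <- model@hidden; w <- model@window
  hw <- (w - 1L) %/% 2L
  denom <- sum(vapply(dataset, function(d) nrow(d$x), integer(1)))
  groups <- groupByLength(dataset)
  loss <- 0
  grads <- lapply(wt, function(m) m * 0)
  eps <- 1e-12
  for (idx in groups) {
    xs <- lapply(dataset[idx], `[[`, "x")
    B <- length(idx); L <- nrow(xs[[1]])
    Y <- matrix(0, B, L)
    for (b in seq_len(B)) Y[b, ] <- dataset[[idx[b]]]$y
    Xl <- stackBatch(xs, nIn, hw)
    fw <- brnnForwardBatch(wt, nIn, H, w, Xl, L, B)
    Oc <- pmin(pmax(fw$O, eps), 1 - eps)
    loss <- loss + sum(-(Y * log(Oc) + (1 - Y) * log(1 - Oc))) / denom
    g <- brnnBackwardBatch(wt, nIn, H, w, fw, (fw$O - Y) / denom, L, B)
    grads <- Map(`+`, grads, g)
  }
  list(loss = loss, grads = grads)
}

#' Learning-rate schedule from an error trace
#'
#' Reproduces the trainer's halving rule on a recorded per-epoch error series:
#' a counter of consecutive epochs without improvement over the best error so
#' far is kept; when it reaches `patience` the rate halves and the counter
#' resets. The first epoch establishes the baseline, so on a fully stagnant
#' trace the first halving lands on epoch `patience + 1`.
#'
#' @param errors numeric per-epoch training errors
#' @param lr0 initial learning rate (default 0.01)
#' @param patience stagnation tolerance in epochs (default 50)
#' @return numeric vector: the learning rate in force at each epoch
#' @export
scheduleLearningRate <- function(errors, lr0 = 0.01, patience = 50L) {
  stopifnot(patience >= 1L)
  lr <- lr0; best <- Inf; since <- 0L
  out <- numeric(length(errors))
  for (e in seq_along(errors)) {
    if (errors[e] < best) { best <- errors[e]; since <- 0L }
    else {
      since <- since + 1L
      if (since >= patience) { lr <- lr / 2; since <- 0L }
    }
    out[e] <- lr
  }
  out
}

#' Train a BRNN by full-batch gradient descent
#'
#' Minimises mean per-residue binary cross-entropy for `epochs` epochs with
#' the learning-rate halving rule of [scheduleLearningRate()] applied to the
#' training error. Fully reproducible from `seed` (which also draws the
#' initial weights when no `model` is supplied). `epochs = 0` returns the
#' initial model untouched.
#'
#' @param dataset list of `list(x = feature matrix, y = 0/1 labels)`; both
#'   classes must be present across the dataset
#' @param epochs training epochs (default 10000)
#' @param lr initial learning rate (default 0.01)
#' @param patience epochs of stagnation before the rate halves (default 50)
#' @param window,hidden,ffHidden,nIn architecture, see [newBRNN()]
#' @param seed integer seed
#' @param model optional starting [BRNNModel-class] (overrides architecture
#'   arguments)
#' @return a trained [BRNNModel-class]; the per-epoch loss and learning rate
#'   are in its `log` slot
#' @export
trainBRNN <- function(dataset, epochs = 10000L, lr = 0.01, patience = 50L,
                      window = 9L, hidden = 11L, ffHidden = 20L, nIn = 26L,
                      seed = NULL, model = NULL) {
  if (length(dataset) == 0) stop("empty dataset", call. = FALSE)
  ally <- unlist(lapply(dataset, `[[`, "y"))
  if (length(unique(ally)) < 2)
    stop("training labels are degenerate: both classes must be present",
         call. = FALSE)
  if (is.null(model))
    model <- newBRNN(nIn = nIn, window = window, hidden = hidden,
                     ffHidden = ffHidden, seed = seed)
  if (epochs == 0L) return(model)
  wt <- model@weights
  best <- Inf; since <- 0L
  logE <- integer(epochs); logL <- numeric(epochs); logR <- numeric(epochs)
  for (e in seq_len(epochs)) {
    lg <- brnnLossGrad(methods::initialize(model, weights = wt),
                       dataset)
    if (lg$loss < best) { best <- lg$loss; since <- 0L }
    else {
      since <- since + 1L
      if (since >= patience) { lr <- lr / 2; since <- 0L }
    }
    wt <- Map(function(w0, g) w0 - lr * g, wt, lg$grads)
    logE[e] <- e; logL[e] <- lg$loss; logR[e] <- lr
  }
  methods::initialize(model, weights = wt,
                      log = data.frame(epoch = logE, loss = logL, lr = logR))
}

#' Ensemble-average predictions over several BRNN models
#'
#' The member models (conventionally three per cross-validation fold, with
#' input windows 7, 9 and 11) are applied to the same feature matrix and their
#' per-residue outputs arithmetically averaged.
#'
#' @param models non-empty list of [BRNNModel-class]
#' @param x feature matrix
#' @return numeric vector of per-residue predictions
#' @export
ensemblePredict <- function(models, x) {
  if (length(models) == 0) stop("empty model list", call. = FALSE)
  preds <- vapply(models, brnnPredict, numeric(nrow(as.matrix(x))), x = x)
  rowMeans(as.matrix(preds))
}

#' Ten-fold cross-validation with window-size ensembling
#'
#' Partitions the dataset into `folds` roughly equal, disjoint folds (sizes
#' differ by at most one) whose union covers the set; for each fold, one model
#' per entry of `windows` is trained on the remaining items and the held-out
#' items are predicted by the fold's ensemble average. Every item is therefore
#' predicted exactly once, by models that never saw it.
#'
#' @inheritParams trainBRNN
#' @param folds number of folds (default 10)
#' @param windows input window sizes of the per-fold ensemble members
#'   (default `c(7, 9, 11)`)
#' @param seed integer seed driving the fold shuffle and every member's
#'   initialisation
#' @return list with `predictions` (per-item numeric vectors, in dataset
#'   order), `folds` (per-item fold assignment) and `models` (per-fold lists)
#' @export
crossValidate <- function(dataset, folds = 10L, windows = c(7L, 9L, 11L),
                          epochs = 10000L, lr = 0.01, patience = 50L,
                          hidden = 11L, ffHidden = 20L, seed = 1L) {
  n <- length(dataset)
  folds <- as.integer(folds)
  if (n < folds)
    stop("dataset has ", n, " items; need at least one per fold (folds = ",
         folds, ")", call. = FALSE)
  perm <- withSeed(childSeed(seed, 0), sample.int(n))
  assign <- integer(n)
  assign[perm] <- rep_len(seq_len(folds), n)
  nIn <- ncol(dataset[[1]]$x)
  predictions <- vector("list", n)
  modelList <- vector("list", folds)
  for (f in seq_len(folds)) {
    trainIdx <- which(assign != f); testIdx <- which(assign == f)
    members <- lapply(seq_along(windows), function(m)
      trainBRNN(dataset[trainIdx], epochs = epochs, lr = lr,
                patience = patience, window = windows[m], hidden = hidden,
                ffHidden = ffHidden, nIn = nIn,
                seed = childSeed(seed, f * 100 + m)))
    for (i in testIdx)
      predictions[[i]] <- ensemblePredict(members, dataset[[i]]$x)
    modelList[[f]] <- members
  }
  list(predictions = predictions, folds = assign, models = modelList)
}

#' Serialise a BRNN model to JSON
#'
#' Architecture metadata plus flattened weight arrays, plain text.
#'
#' @param model a [BRNNModel-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeBRNNModel <- function(model, path) {
  stopifnot(is(model, "BRNNModel"))
  obj <- list(nIn = model@nIn, window = model@window, hidden = model@hidden,
              ffHidden = model@ffHidden,
              weights = lapply(model@weights, function(m)
                list(dim = if (is.matrix(m)) dim(m) else length(m),
                     data = as.numeric(m))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a BRNN model written by [writeBRNNModel()]
#'
#' @param path path to the JSON checkpoint
#' @return a [BRNNModel-class]
#' @export
readBRNNModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(obj$weights, function(w) {
    if (length(w$dim) == 2) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  new("BRNNModel", nIn = as.integer(obj$nIn), window = as.integer(obj$window),
      hidden = as.integer(obj$hidden), ffHidden = as.integer(obj$ffHidden),
      weights = weights,
      log = data.frame(epoch = integer(), loss = numeric(), lr = numeric()))
}
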