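test_that("input encoding lays out the 26 channels as documented", {
  corpus <- syntheticRegions(n = 1, len = 50, seed = 3)
  fx <- corpus[[1]]
  vina <- runif(50)
  x <- encodeInputs(fx$region, ss = fx$ss, disorder = fx$disorder, vina = vina)
  expect_equal(dim(x), c(50, 26))
  expect_true(all(rowSums(x[, 1:20]) == 1))            # one-hot per residue
  expect_equal(x[, 21], rep(0.05, 50))                 # length 50 / 1000
  expect_equal(x[, 22:24], unname(fx$ss))
  expect_equal(x[, 25], fx$disorder)
  expect_equal(x[, 26], vina)
  # deselected channels are zero-filled
  xs <- encodeInputs(fx$region, vina = vina, features = "vina")
  expect_true(all(xs[, 22:25] == 0))
  expect_equal(xs[, 26], vina)
  expect_error(encodeInputs(fx$region, ss = fx$ss, disorder = fx$disorder,
                            vina = runif(10)), "length mismatch")
})

test_that("non-standard residues encode as all-zero one-hot with a warning", {
  r <- new("ProteinRegion", parentId = "p", parentLength = 5L, start = 1L,
           end = 5L, seq = "ACXDE", labels = integer(5))
  expect_warning(x <- encodeInputs(r, features = character(0)), "X")
  expect_equal(rowSums(x[, 1:20]), c(1, 1, 0, 1, 1))
})

test_that("forward outputs are squashed and constant under zero weights", {
  m <- constantModel()
  x <- matrix(runif(50 * 26), 50, 26)
  p <- brnnPredict(m, x)
  expect_equal(p, rep(0.5, 50))
  m2 <- newBRNN(seed = 8)
  p2 <- brnnPredict(m2, x)
  expect_true(all(p2 > 0 & p2 < 1))
  expect_equal(predict(m2, x), p2)
  expect_error(brnnPredict(m2, x[, 1:10]), "channels")
})

test_that("analytic gradients match central finite differences", {
  set.seed(55)
  m <- newBRNN(nIn = 12L, window = 7L, hidden = 5L, ffHidden = 6L, seed = 14)
  ds <- list(list(x = matrix(runif(10 * 12), 10, 12),
                  y = c(0, 1, 1, 0, 0, 1, 0, 0, 1, 0)),
             list(x = matrix(runif(8 * 12), 8, 12),
                  y = c(1, 0, 0, 1, 0, 0, 0, 1)))
  lg <- brnnLossGrad(m, ds)
  expect_equal(lg$loss, forwardLoss(m, ds), tolerance = 1e-12)
  fd <- fdGradient(m, ds)
  rel <- unlist(Map(function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-6),
                    fd, lg$grads))
  expect_lt(max(rel), 1e-5)
  expect_lt(max(unlist(Map(function(a, b) abs(a - b), fd, lg$grads))), 1e-9)
})

test_that("training is seed-deterministic and a zero-epoch run is a no-op", {
  corpus <- syntheticCorpus(n = 6, len = 20, seed = 5)
  ds <- lapply(corpus, function(d) list(x = d$x, y = d$y))
  m0 <- trainBRNN(ds, epochs = 0, seed = 21)
  expect_identical(m0@weights, newBRNN(seed = 21)@weights)
  mA <- trainBRNN(ds, epochs = 15, lr = 0.3, seed = 21)
  mB <- trainBRNN(ds, epochs = 15, lr = 0.3, seed = 21)
  expect_identical(mA@weights, mB@weights)
  expect_identical(brnnPredict(mA, ds[[1]]$x), brnnPredict(mB, ds[[1]]$x))
  # loss decreases in the long run on training data
  expect_lt(tail(mA@log$loss, 1), mA@log$loss[1])
  bad <- lapply(ds, function(d) list(x = d$x, y = rep(0L, length(d$y))))
  expect_error(trainBRNN(bad, epochs = 1), "degenerate")
})

test_that("the learning rate halves exactly per the stagnation rule", {
  # stagnant from epoch 1 with patience 50: first halving lands on epoch 51
  lr <- scheduleLearningRate(rep(1, 60), lr0 = 0.01, patience = 50)
  expect_equal(lr[50], 0.01)
  expect_equal(lr[51], 0.005)
  expect_equal(lr[60], 0.005)
  # an improvement resets the counter
  errs <- c(seq(1, 0.5, length.out = 10), rep(0.6, 55))
  lr2 <- scheduleLearningRate(errs, lr0 = 0.01, patience = 50)
  expect_equal(lr2[59], 0.01)   # only 49 stagnant epochs so far
  expect_equal(lr2[60], 0.005)  # the 50th stagnant epoch triggers halving
  # number of halvings equals the number of completed patience-long runs
  lr3 <- scheduleLearningRate(rep(1, 103), patience = 50)
  expect_equal(tail(lr3, 1), 0.01 / 4)
  # the trainer applies the same rule to its own loss trace
  corpus <- syntheticCorpus(n = 4, len = 15, seed = 2)
  ds <- lapply(corpus, function(d) list(x = d$x, y = d$y))
  m <- trainBRNN(ds, epochs = 25, lr = 0.05, patience = 3, seed = 4)
  expect_equal(m@log$lr, scheduleLearningRate(m@log$loss, 0.05, 3))
})

test_that("ensembles average member outputs and default to windows 7/9/11", {
  x <- matrix(runif(20 * 26), 20, 26)
  m <- newBRNN(seed = 31)
  expect_equal(ensemblePredict(list(m, m, m), x), brnnPredict(m, x))
  # members with constant outputs 0.5 average to 0.5
  cm <- constantModel()
  shifted <- constantModel(); shifted@weights$bo2 <- 1e9   # output 1
  low <- constantModel(); low@weights$bo2 <- -1e9          # output 0
  expect_equal(ensemblePredict(list(cm, shifted, low), x), rep(0.5, 20))
  expect_error(ensemblePredict(list(), x), "empty")
  expect_equal(eval(formals(crossValidate)$windows), c(7L, 9L, 11L))
})

test_that("cross-validation folds are disjoint, covering and balanced", {
  corpus <- syntheticCorpus(n = 12, len = 15, seed = 6)
  ds <- lapply(corpus, function(d) list(x = d$x, y = d$y))
  cv <- crossValidate(ds, folds = 10, windows = 7, epochs = 2, seed = 6)
  expect_equal(sort(unique(cv$folds)), 1:10)
  expect_true(all(table(cv$folds) %in% c(1, 2)))     # 12 items, 10 folds
  expect_equal(length(cv$predictions), 12)
  expect_true(all(lengths(cv$predictions) == 15))
  # 10 items in 10 folds: forced singleton partition
  cv1 <- crossValidate(ds[1:10], folds = 10, windows = 7, epochs = 1, seed = 6)
  expect_true(all(table(cv1$folds) == 1))
  expect_error(crossValidate(ds[1:5], folds = 10, windows = 7, epochs = 1),
               "at least one per fold")
  # fold-size arithmetic at the corpus scale: 84 items over 10 folds
  sizes <- table(rep_len(1:10, 84))
  expect_true(all(sizes %in% c(8, 9)))
})

test_that("model checkpoints survive a JSON round-trip", {
  m <- newBRNN(window = 7L, seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  writeBRNNModel(m, path)
  back <- readBRNNModel(path)
  expect_equal(back@weights, m@weights)
  x <- matrix(runif(15 * 26), 15, 26)
  expect_equal(brnnPredict(back, x), brnnPredict(m, x))
})
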