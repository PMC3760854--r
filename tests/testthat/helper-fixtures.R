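# shared fixtures and independent oracles

# small two-chain structure built in code: chain A (3 atoms), chain B (2 atoms)
toyStructure <- function() {
  atoms <- data.frame(
    type = "ATOM",
    chain = c("A", "A", "A", "B", "B"),
    resno = c(1L, 1L, 2L, 1L, 2L),
    resid = c("ALA", "ALA", "GLY", "SER", "SER"),
    elety = c("N", "CA", "CA", "CA", "CB"),
    x = c(20, 21, 22, 0, 10),
    y = c(20, 21, 22, 0, 10),
    z = c(20, 21, 22, 0, 10),
    stringsAsFactors = FALSE)
  new("StructureModel", atoms = atoms)
}

# Mann-Whitney pairwise probability: P(random positive outranks a random
# negative), ties counted half. Brute force over all (pos, neg) pairs.
pairwiseAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# forward-only loss (no backprop code involved): mean per-residue BCE
forwardLoss <- function(model, dataset) {
  eps <- 1e-12
  tot <- 0; nres <- 0
  for (d in dataset) {
    p <- pmin(pmax(brnnPredict(model, d$x), eps), 1 - eps)
    tot <- tot + sum(-(d$y * log(p) + (1 - d$y) * log(1 - p)))
    nres <- nres + length(d$y)
  }
  tot / nres
}

# five-point central-difference gradient of forwardLoss (O(h^4) truncation)
fdGradient <- function(model, dataset, h = 1e-3) {
  shift <- function(nm, i, d) {
    m <- model; m@weights[[nm]][i] <- model@weights[[nm]][i] + d
    forwardLoss(m, dataset)
  }
  lapply(stats::setNames(names(model@weights), names(model@weights)),
         function(nm) {
    w <- model@weights[[nm]]
    g <- w * 0
    for (i in seq_along(w))
      g[i] <- (8 * (shift(nm, i, h) - shift(nm, i, -h)) -
                 (shift(nm, i, 2 * h) - shift(nm, i, -2 * h))) / (12 * h)
    g
  })
}

# brute-force overlapping motif matcher: anchor the pattern at every start
bruteMotifScan <- function(seq, pattern) {
  L <- nchar(seq)
  out <- data.frame(start = integer(), end = integer(), match = character())
  for (i in seq_len(L)) {
    tail <- substring(seq, i)
    m <- regexpr(paste0("^(", pattern, ")"), tail, perl = TRUE)
    if (m[1] == 1) {
      len <- attr(m, "match.length")
      out <- rbind(out, data.frame(start = i, end = i + len - 1L,
                                   match = substr(tail, 1, len)))
    }
  }
  out
}

# a model whose every weight is zero emits a constant 0.5 everywhere
constantModel <- function(nIn = 26L, window = 9L) {
  m <- newBRNN(nIn = nIn, window = window, seed = 1)
  m@weights <- lapply(m@weights, function(w) w * 0)
  m
}
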