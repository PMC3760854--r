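test_that("best-pose selection takes the minimum affinity and flags failures", {
  eng <- function(receptor, box, kmer, offset) c(-4.1, -6.3, -5.0)
  expect_equal(dockFragment(eng, NULL, NULL, "ACD", 1), -6.3)
  empty <- function(receptor, box, kmer, offset) numeric(0)
  expect_error(dockFragment(empty, NULL, NULL, "ACD", 1), "no finite poses")
  dying <- function(receptor, box, kmer, offset) stop("boom")
  expect_error(dockFragment(dying, NULL, NULL, "ACD", 1), "ACD")
})

test_that("the mock engine is deterministic and label-responsive", {
  labels <- c(0, 0, 1, 1, 1, 0, 0)
  eng <- mockEngine(labels, k = 3, effect = 2, sigma = 0, seed = 5)
  # identical calls give identical poses
  expect_identical(eng(NULL, NULL, "ACD", 2), eng(NULL, NULL, "ACD", 2))
  # noiseless scores follow -(base + effect * label fraction)
  expect_equal(min(eng(NULL, NULL, "XXX", 3)), -6)   # fully positive fragment
  expect_equal(min(eng(NULL, NULL, "XXX", 1)), -4 - 2 / 3)
  eng0 <- mockEngine(c(0, 0, 0, 0, 0), k = 3, effect = 2, sigma = 0, seed = 5)
  expect_equal(min(eng0(NULL, NULL, "XXX", 1)), -4)  # baseline
})

test_that("fragment docking failures are retried then imputed with a warning", {
  calls <- new.env(); calls$n <- 0
  flaky <- function(receptor, box, kmer, offset) {
    if (offset == 2) stop("engine crash")
    -5 - offset / 10
  }
  expect_warning(res <- dockRegion(flaky, NULL, NULL, "ACDEFG", k = 3),
                 "imputing")
  expect_equal(nrow(res), 4)
  expect_equal(res$score[2], median(res$score[-2]))
  allBad <- function(receptor, box, kmer, offset) stop("down")
  expect_error(suppressWarnings(dockRegion(allBad, NULL, NULL, "ACDEFG", 3)),
               "every fragment")
})

test_that("residue aggregation takes the best covering fragment", {
  # residue 3 of a 5-residue region (k = 3) is covered by all three fragments
  frags <- data.frame(offset = 1:3, score = c(-3, -6, -2))
  track <- aggregateToResidues(frags, 5, k = 3)
  expect_equal(track[3], -6)
  expect_equal(track[1], -3)   # single coverage at the first residue
  expect_equal(track[5], -2)
  uni <- data.frame(offset = 1:4, score = rep(-5, 4))
  expect_equal(aggregateToResidues(uni, 6, k = 3), rep(-5, 6))
  gap <- data.frame(offset = c(1, 3), score = c(-1, -2))
  expect_error(aggregateToResidues(gap, 5, k = 3), "tile")
})

test_that("aggregation matches a brute-force scan over residue/fragment pairs", {
  set.seed(33)
  for (i in 1:20) {
    L <- sample(10:60, 1)
    k <- sample(2:5, 1)
    frags <- data.frame(offset = seq_len(L - k + 1),
                        score = -runif(L - k + 1, 2, 9))
    for (method in c("min", "mean")) {
      got <- aggregateToResidues(frags, L, k, method = method)
      want <- vapply(seq_len(L), function(res) {
        covering <- frags$score[frags$offset <= res & frags$offset + k - 1 >= res]
        if (method == "min") min(covering) else mean(covering)
      }, numeric(1))
      expect_equal(got, want)
    }
  }
})

test_that("normalisation maps tracks into [0,1] with the minimum pinned at 1", {
  expect_equal(normalizeScores(c(-10, -5, 0)), c(1, 0.5, 0))
  expect_equal(normalizeScores(-7), 1)
  expect_equal(normalizeScores(c(2, -4)), c(0, 1))  # positive clamps to 0
  expect_warning(z <- normalizeScores(c(1, 2)), "degenerate")
  expect_equal(z, c(0, 0))
  # properties on random tracks: range, unique max unless tied, monotone
  set.seed(44)
  for (i in 1:25) {
    raw <- -runif(sample(5:50, 1), 0, 12)
    v <- normalizeScores(raw)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(sum(v == 1), sum(raw == min(raw)))
    ord <- order(raw)                       # more negative => larger v
    expect_true(all(diff(v[ord]) <= 1e-12))
  }
})

test_that("mock-engine tracks carry signal over the planted span", {
  labels <- c(rep(0, 20), rep(1, 8), rep(0, 22))
  eng <- mockEngine(labels, k = 3, effect = 2, sigma = 0.1, seed = 9)
  frags <- dockRegion(eng, NULL, NULL, paste(rep("A", 50), collapse = ""), 3)
  v <- normalizeScores(aggregateToResidues(frags, 50, 3))
  expect_gt(mean(v[labels == 1]), mean(v[labels == 0]))
})

test_that("engine result tables parse and missing binaries are actionable", {
  out <- c("mode |   affinity | dist from best mode",
           "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
           "-----+------------+----------+----------",
           "   1       -6.3      0.000      0.000",
           "   2       -5.1      1.202      2.310",
           "   3        1.2      3.400      5.100")
  tab <- parseVinaOutput(out)
  expect_equal(tab$affinity, c(-6.3, -5.1, 1.2))
  expect_equal(nrow(parseVinaOutput("no table here")), 0)
  expect_error(vinaEngine(binary = "no_such_docking_binary_xyz"),
               "not found")
})
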