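test_that("FASTA records are parsed, normalised and order-preserving", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p", "ACDEF", ">q extra words", "ghKLm", "npQR"), path)
  seqs <- readFasta(path)
  expect_length(seqs, 2)
  expect_identical(names(seqs), c("p", "q"))
  expect_identical(as.character(seqs[[1]]), "ACDEF")
  expect_identical(as.character(seqs[[2]]), "GHKLMNPQR")  # uppercased, joined
})

test_that("malformed FASTA input is rejected with the record named", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "ACDEF", ">empty", "", ">next", "ACD"), path)
  expect_error(readFasta(path), "empty")
  writeLines(c(">bad", "AC1EF"), path)
  expect_error(readFasta(path), "bad")
  expect_error(readFasta(file.path(tempdir(), "noSuchFile.fasta")), "not found")
})

test_that("toy PDB files round-trip through write and parse", {
  model <- toyStructure()
  path <- withr::local_tempfile(fileext = ".pdb")
  writePDB(model, path)
  back <- parsePDB(path)
  expect_identical(chains(back), c("A", "B"))
  expect_equal(nrow(atoms(back)), 5)
  expect_equal(atoms(back)$x, atoms(model)$x, tolerance = 1e-3)
  expect_identical(atoms(back)$elety, atoms(model)$elety)
})

test_that("PDB parsing errors on degenerate or corrupt input", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), path)
  expect_error(parsePDB(path), "no ATOM/HETATM")
  writeLines("ATOM      1  CA  ALA A   1      xx.xxx   1.000   1.000  1.00  0.00           C",
             path)
  expect_error(parsePDB(path), "line 1")
})

test_that("a HETATM-only file yields atoms but an empty chain index", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH W   1       1.000   2.000   3.000  1.00  0.00           O",
    "END"), path)
  model <- parsePDB(path)
  expect_equal(nrow(atoms(model)), 1)
  expect_length(chains(model), 0)
  expect_error(computeSearchBox(model, "W"), "no standard ATOM")
})

test_that("search box centres and pads the peptide bounding box", {
  model <- toyStructure()  # chain B spans [0,10] on every axis
  box <- computeSearchBox(model, "B", padding = 4)
  expect_equal(boxCentre(box), c(5, 5, 5))
  expect_equal(boxDims(box), c(18, 18, 18))
  # degenerate single-atom chain: box is 2 * padding wide
  one <- new("StructureModel", atoms = data.frame(
    type = "ATOM", chain = "P", resno = 1L, resid = "GLY", elety = "CA",
    x = 1, y = 2, z = 3, stringsAsFactors = FALSE))
  box1 <- computeSearchBox(one, "P", padding = 4)
  expect_equal(boxCentre(box1), c(1, 2, 3))
  expect_equal(boxDims(box1), c(8, 8, 8))
  expect_error(computeSearchBox(model, "Z"), "not present")
})

test_that("oversized boxes are clamped to the maximum edge with a warning", {
  wide <- new("StructureModel", atoms = data.frame(
    type = "ATOM", chain = c("P", "P"), resno = 1:2, resid = "GLY",
    elety = "CA", x = c(0, 40), y = c(0, 1), z = c(0, 1),
    stringsAsFactors = FALSE))
  expect_warning(box <- computeSearchBox(wide, "P", padding = 4, maxEdge = 30),
                 "clamped")
  expect_equal(boxDims(box)[1], 30)
  expect_equal(boxDims(box)[2:3], c(9, 9))
})

test_that("every peptide atom lies inside the unclamped search box", {
  for (seed in 1:10) {
    path <- withr::local_tempfile(fileext = ".pdb")
    genToyPDB(path, peptideLength = 5, bbox = c(-3, 12), seed = seed)
    model <- parsePDB(path)
    box <- computeSearchBox(model, "B", padding = 2, maxEdge = 1e6)
    at <- atoms(model)
    pep <- as.matrix(at[at$chain == "B", c("x", "y", "z")])
    lo <- boxCentre(box) - boxDims(box) / 2
    hi <- boxCentre(box) + boxDims(box) / 2
    expect_true(all(t(pep) >= lo - 1e-9) && all(t(pep) <= hi + 1e-9))
  }
})

test_that("chain stripping removes exactly the named chain and is idempotent", {
  model <- toyStructure()
  stripped <- stripChain(model, "B")
  expect_identical(chains(stripped), "A")
  expect_equal(nrow(atoms(stripped)), 3)
  # conservation: the two parts add up to the original
  expect_equal(nrow(atoms(stripped)) + sum(atoms(model)$chain == "B"),
               nrow(atoms(model)))
  expect_error(stripChain(stripped, "B"), "not present")  # idempotent-by-error
  expect_warning(onlyA <- stripChain(stripped, "A"), "empty")
  expect_equal(nrow(atoms(onlyA)), 0)
})

test_that("a stripped receptor survives a write/parse round-trip", {
  path <- withr::local_tempfile(fileext = ".pdb")
  genToyPDB(path, peptideLength = 4, seed = 2)
  model <- parsePDB(path)
  receptor <- stripChain(model, "B")
  out <- withr::local_tempfile(fileext = ".pdb")
  writePDB(receptor, out)
  back <- parsePDB(out)
  expect_identical(chains(back), "A")
  expect_equal(atoms(back)$x, atoms(receptor)$x, tolerance = 1e-3)
})

test_that("box config is written in engine key-value form", {
  box <- new("SearchBox", centre = c(1, 2, 3), dims = c(10, 11, 12))
  path <- withr::local_tempfile()
  writeBoxConfig(box, path)
  lines <- readLines(path)
  expect_match(lines[1], "^center_x = 1")
  expect_match(lines[6], "^size_z = 12")
})
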