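test_that("SMILES tokenization keeps multi-character tokens atomic", {
  expect_identical(tokenizeSmiles("CCl"), c("C", "Cl"))
  expect_identical(tokenizeSmiles("C[NH3+]C"), c("C", "[NH3+]", "C"))
  expect_identical(tokenizeSmiles("CBr"), c("C", "Br"))
  v <- buildSmilesVocab(c("CCO"))
  expect_setequal(setdiff(v@tokens, c("<PAD>", "<GO>", "<EOS>", "<SEP>")),
                  c("C", "O", "."))   # "." is the fragment separator
  expect_true("Cl" %in% buildSmilesVocab("CCl")@tokens)
  expect_true("[NH3+]" %in% buildSmilesVocab("C[NH3+]C")@tokens)
})

test_that("vocabulary construction is deterministic and errors when empty", {
  corp <- fixtureCorpus(15)
  expect_identical(buildSmilesVocab(corp)@tokens,
                   buildSmilesVocab(corp)@tokens)
  expect_identical(buildGraphVocab(corp)@atomTypes,
                   buildGraphVocab(corp)@atomTypes)
  expect_error(buildSmilesVocab(character(0)), "empty")
  expect_error(buildGraphVocab(character(0)), "empty")
})

test_that("SMILES encoding is padded, framed and invertible", {
  v <- buildSmilesVocab("CCO")
  codes <- encodeSmiles("CCO", v, maxLen = 6)
  expect_length(codes, 6)
  expect_identical(v@tokens[codes[1]], "<GO>")
  expect_identical(sum(v@tokens[codes] == "<PAD>"), 1L)
  expect_identical(decodeSmiles(codes, v), "CCO")
  ## PAD only after EOS
  eosAt <- which(v@tokens[codes] == "<EOS>")
  expect_true(all(which(v@tokens[codes] == "<PAD>") > eosAt))
  ## out-of-vocabulary tokens are reported by name
  expect_error(encodeSmiles("CN", v, 6), "N")
  expect_error(encodeSmiles("CCCCCCCC", v, 6), "too long")
})

test_that("SMILES round-trip holds over the fixture corpus", {
  v <- fixtureSmilesVocab()
  for (s in fixtureCorpus(30)) {
    expect_identical(decodeSmiles(encodeSmiles(s, v, 120), v), s)
  }
})

test_that("graph matrices have the default 5 x 400 layout", {
  gv <- fixtureGraphVocab()
  m <- encodeGraph(canonicalSmiles("CC(=O)Nc1ccc(O)cc1"), vocab = gv)
  expect_identical(dim(m), c(5L, 400L))
  ## acetaminophen has 3 BRICS fragments: fragment row runs 1, 2, 3
  expect_identical(sort(unique(m[5, m[5, ] > 0])), 1:3)
  expect_true(validateGraphMatrix(m))
})

test_that("graph round-trip reconstructs the molecule", {
  gv <- fixtureGraphVocab()
  for (s in c("CC(=O)Nc1ccc(O)cc1", fixtureCorpus(25))) {
    can <- canonicalSmiles(s)
    m <- encodeGraph(can, vocab = gv)
    expect_identical(canonicalSmiles(decodeGraph(m, gv)), can)
  }
})

test_that("graph decoding rejects inconsistent matrices", {
  gv <- fixtureGraphVocab()
  ## all padding: no atoms
  expect_error(decodeGraph(matrix(0L, 5, 10), gv), "no atoms")
  ## a single carbon atom decodes to methane
  code <- match("C", gv@atomTypes) + 2L
  m <- matrix(0L, 5, 4)
  m[1, 1] <- 1L
  m[, 2] <- c(code, 0L, 0L, 0L, 1L)
  m[1, 3] <- 2L
  expect_identical(decodeGraph(m, gv), "C")
  ## fragment-start column has neighbor = self
  expect_identical(m[2, 2], m[3, 2])
  ## dangling neighbor index
  bad <- m
  bad[, 3] <- c(code, 1L, 5L, 1L, 1L)
  expect_error(decodeGraph(bad, gv), "dangling")
})

test_that("vocabularies round-trip through their file format", {
  tmp <- withr::local_tempdir()
  sv <- fixtureSmilesVocab()
  p <- file.path(tmp, "vocab_smiles.txt")
  writeVocabulary(sv, p)
  expect_identical(readVocabulary(p)@tokens, sv@tokens)
  gv <- fixtureGraphVocab()
  p2 <- file.path(tmp, "vocab_graph.txt")
  writeVocabulary(gv, p2)
  gv2 <- readVocabulary(p2)
  expect_identical(gv2@atomTypes, gv@atomTypes)
  expect_identical(gv2@bondTypes, gv@bondTypes)
})
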