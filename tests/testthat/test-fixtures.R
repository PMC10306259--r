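test_that("the toy corpus generator honors its contract", {
  smi <- makeCorpus(40, seed = 1, weightRange = c(200, 500))
  expect_length(smi, 40)
  expect_identical(anyDuplicated(smi), 0L)
  r <- records(standardizeMolecules(smi))
  expect_true(all(r$isValid & r$isOrganic))
  expect_true(all(r$molWeight >= 200 & r$molWeight <= 500))
  ## determinism
  expect_identical(makeCorpus(40, seed = 1, weightRange = c(200, 500)), smi)
  ## element bias raises the nitrogen-containing fraction
  plain <- makeCorpus(40, seed = 3)
  biased <- makeCorpus(40, seed = 3, elementBias = c(N = 6))
  nFrac <- function(x) mean(grepl("[Nn]", x))
  expect_gt(nFrac(biased), nFrac(plain))
  expect_error(makeCorpus(5, weightRange = c(30, 50)), "infeasible")
})

test_that("the toy environment classifies reference molecules", {
  env <- makeEnvToy()
  ## ~300 Da nitrogen-containing molecule: both objectives satisfied
  mol300 <- "NCCc1ccc(OCCN2CCOCC2)cc1OC"
  tab <- scoreBatch(env, c(mol300, "CC(=O)Nc1ccc(O)cc1"))
  expect_true(desired(tab)[1])
  ## ~150 Da molecule falls off the weight hump
  expect_false(desired(tab)[2])
})
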