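test_that("the spiking-pattern scenario reproduces both phenotypes", {
  res <- run_scenario("fig2", quick = TRUE)
  expect_true(res$pass)
  expect_true(all(res$self_check$pass))
})

test_that("the fast-slow scenario matches full-model regimes", {
  res <- run_scenario("figS3", quick = TRUE)
  expect_true(res$pass)
})

test_that("the suprathreshold-current scenario shows no excitability change", {
  out <- withr::local_tempdir()
  res <- run_scenario("figS4", out = out, quick = TRUE)
  expect_true(res$pass)
  expect_true(file.exists(file.path(out, "self_check.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
})

test_that("unknown scenarios are rejected", {
  expect_error(run_scenario("fig99"))
})
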