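# Network construction and validation.

test_that("validation rejects dangling references and bad delays", {
  pops <- list(population("a", 3, "source",
                          stimulus = list(type = "poisson", rate = 1)),
               population("b", 3, "lif"))
  expect_error(network(pops, list(projection("a", "zzz"))), "zzz")
  expect_error(network(pops, list(projection("a", "b", delay = 0))),
               ">= 1 ms")
  expect_error(projection("a", "b", plastic = TRUE,
                          rule = list(name = "nope")), "unknown")
  # one_to_one needs matching sizes
  pops2 <- c(pops, list(population("c", 2, "lif")))
  expect_error(network(pops2, list(projection("a", "c",
                                              list(type = "one_to_one")))),
               "equal sizes")
})

test_that("connectivity patterns realise the expected synapse sets", {
  pops <- list(population("a", 4, "source",
                          stimulus = list(type = "poisson", rate = 1)),
               population("b", 4, "lif"))
  one <- network(pops, list(projection("a", "b",
                                       list(type = "one_to_one"))))
  expect_equal(one$projections[[1]]$pre_local,
               one$projections[[1]]$post_local)
  full <- network(pops, list(projection("b", "b",
                                        list(type = "all_to_all",
                                             self = FALSE))))
  expect_equal(nrow(unique(data.frame(full$projections[[1]]$pre_local,
                                      full$projections[[1]]$post_local))),
               12)
  expect_true(all(full$projections[[1]]$pre_local !=
                    full$projections[[1]]$post_local))
})

test_that("bernoulli connectivity density matches its binomial expectation", {
  pops <- list(population("a", 50, "source",
                          stimulus = list(type = "poisson", rate = 1)),
               population("b", 40, "lif"))
  n_tot <- 50 * 40
  for (sd in 1:3) {
    net <- network(pops, list(projection("a", "b",
                                         list(type = "bernoulli", p = 0.5))),
                   seed = sd)
    S <- length(net$projections[[1]]$pre)
    expect_lt(abs(S - 0.5 * n_tot), 4 * sqrt(n_tot * 0.25))
    # same seed reproduces the same adjacency
    net2 <- network(pops, list(projection("a", "b",
                                          list(type = "bernoulli",
                                               p = 0.5))), seed = sd)
    expect_identical(net$projections[[1]]$pre, net2$projections[[1]]$pre)
  }
})

test_that("weight and delay distributions are drawn from seeded sub-streams", {
  pops <- list(population("a", 10, "source",
                          stimulus = list(type = "poisson", rate = 1)),
               population("b", 10, "lif"))
  net <- network(pops, list(projection(
    "a", "b", list(type = "all_to_all"),
    weight = list(type = "uniform", min = 1, max = 2),
    delay = list(type = "uniform_int", min = 1, max = 6))), seed = 9)
  pr <- net$projections[[1]]
  expect_true(all(pr$w >= 1 & pr$w <= 2))
  expect_true(all(pr$d %in% 1:6))
  expect_gt(length(unique(pr$d)), 1)
})
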