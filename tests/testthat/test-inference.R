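test_that("exact marginals agree with the brute-force oracle", {
  net <- chain3_network()
  # no evidence
  for (q in c("A", "B", "C")) {
    want <- brute_force_marginal(net, evidence(), q)
    expect_equal(exact_marginal(net, evidence(), q, method = "enumeration"),
                 want, tolerance = 1e-12)
    expect_equal(exact_marginal(net, evidence(), q, method = "elimination"),
                 want, tolerance = 1e-12)
  }
  # diagnostic evidence (child observed, cause queried)
  ev <- evidence(C = 2)
  want <- brute_force_marginal(net, ev, "A")
  expect_equal(exact_marginal(net, ev, "A"), want, tolerance = 1e-12)
})

test_that("a node clamped in the evidence has marginal 0 or 1", {
  net <- chain3_network()
  expect_equal(exact_marginal(net, evidence(B = 2), "B"), 1)
  expect_equal(exact_marginal(net, evidence(B = 1), "B"), 0)
})

test_that("OR of independent lesions: 1 - prod(1 - p)", {
  net <- bn_network(
    bn_stochastic("Ab", cpt(c(0.5, 0.5))),
    bn_stochastic("LewyBodies", cpt(c(0.884, 0.116))),
    bn_max("ProdromalAD", c("Ab", "LewyBodies"))
  )
  expect_equal(exact_marginal(net, evidence(), "ProdromalAD"),
               1 - 0.5 * 0.884, tolerance = 1e-12)
})

test_that("impossible evidence on a free-parent child is an error", {
  # B copies A; A is surely False, B observed True
  net <- bn_network(
    bn_stochastic("A", cpt(c(1, 0))),
    bn_stochastic("B", cpt(array(c(1, 0, 0, 1), c(2, 2))), parents = "A")
  )
  expect_error(exact_marginal(net, evidence(B = 2), "A"),
               "impossible evidence")
})

test_that("clamping a root overrides its own prior (BUGS observation semantics)", {
  # the prior of an observed root is a constant factor and cancels, even
  # when it assigns probability 0 to the observed state
  net <- bn_network(
    bn_stochastic("A", cpt(c(1, 0))),
    bn_stochastic("B", cpt(array(c(0.9, 0.2, 0.1, 0.8), c(2, 2))),
                  parents = "A")
  )
  expect_equal(exact_marginal(net, evidence(A = 2), "B"), 0.8,
               tolerance = 1e-12)
  expect_equal(exact_marginal(net, evidence(A = 2), "B",
                              method = "elimination"), 0.8,
               tolerance = 1e-12)
})

test_that("enumeration and elimination agree on random networks", {
  for (s in 1:25) {
    net <- simulate_network(sample(3:10, 1), max_parents = 3, seed = 200 + s,
                            max_nodes = sample(0:2, 1))$network
    stoch <- adbn:::stochastic_names(net)
    ev_nodes <- sample(stoch, sample(0:min(2, length(stoch) - 1L), 1))
    ev <- evidence(stats::setNames(sample(1:2, length(ev_nodes),
                                          replace = TRUE), ev_nodes))
    q <- sample(setdiff(names(net$nodes), names(ev)), 1)
    a <- try(exact_marginal(net, ev, q, method = "enumeration"), silent = TRUE)
    b <- try(exact_marginal(net, ev, q, method = "elimination"), silent = TRUE)
    if (inherits(a, "try-error")) {
      expect_true(inherits(b, "try-error"))  # both report impossible evidence
    } else {
      expect_equal(a, b, tolerance = 1e-9)
    }
  }
})

test_that("mean_to_probability inverts the 1/2 state coding", {
  expect_equal(mean_to_probability(1.999), 0.999)
  expect_equal(mean_to_probability(1), 0)
  expect_equal(mean_to_probability(2), 1)
  expect_error(mean_to_probability(0.9), "\\[1, 2\\]")
  expect_error(mean_to_probability(2.1), "\\[1, 2\\]")
})

test_that("a fully deterministic network yields a constant chain", {
  net <- bn_network(
    bn_stochastic("A", cpt(c(0, 1))),
    bn_stochastic("B", cpt(array(c(1, 0, 0, 1), c(2, 2))), parents = "A"),
    bn_max("M", c("A", "B"))
  )
  ch <- sample_posterior(net, evidence(), iterations = 200, seed = 7)
  expect_true(all(ch$states[, "A"] == 2L))
  expect_true(all(ch$states[, "B"] == 2L))
  expect_true(all(ch$states[, "M"] == 2L))
  s <- posterior_summary(ch, batches = 10)
  expect_equal(s$mean, rep(2, 3))
  expect_equal(s$sd, rep(0, 3))
  expect_equal(s$mc_error, rep(0, 3))
})

test_that("ancestral sampling converges to the exact marginal", {
  net <- chain3_network()
  exact <- exact_marginal(net, evidence(A = 2), "C")
  for (seed in c(11, 12)) {
    ch <- sample_posterior(net, evidence(A = 2), iterations = 10000,
                           seed = seed)
    expect_identical(ch$sampler, "ancestral")
    s <- posterior_summary(ch)
    est <- mean_to_probability(s$mean[s$node == "C"])
    expect_lt(abs(est - exact), 4 * s$mc_error[s$node == "C"])
  }
  # distinct seeds produce distinct chains
  ch1 <- sample_posterior(net, evidence(), iterations = 1000, seed = 11)
  ch2 <- sample_posterior(net, evidence(), iterations = 1000, seed = 12)
  expect_false(identical(ch1$states, ch2$states))
})

test_that("per-node substreams are stable under monitor changes", {
  net <- chain3_network()
  all_nodes <- sample_posterior(net, evidence(), iterations = 500, seed = 3)
  just_c <- sample_posterior(net, evidence(), iterations = 500, seed = 3,
                             monitor = "C")
  expect_identical(all_nodes$states[, "C"], just_c$states[, "C"])
})

test_that("Gibbs sampling handles non-ancestral evidence", {
  net <- chain3_network()
  ev <- evidence(C = 2)   # child observed: ancestral sampling not applicable
  exact <- exact_marginal(net, ev, "A")
  ch <- sample_posterior(net, ev, iterations = 6000, seed = 5, burn_in = 200)
  expect_identical(ch$sampler, "gibbs")
  s <- posterior_summary(ch)
  est <- mean_to_probability(s$mean[s$node == "A"])
  expect_lt(abs(est - exact), 4 * s$mc_error[s$node == "A"])
  expect_error(sample_posterior(net, ev, iterations = 100, seed = 1,
                                sampler = "ancestral"),
               "ancestral-closed")
})

test_that("posterior summaries follow the batch-means convention", {
  # iid Bernoulli(0.5) on the 1/2 coding: mc error ~ sd/sqrt(n) = 0.005
  set.seed(99)
  x <- 1L + stats::rbinom(10000, 1L, 0.5)
  ch <- structure(list(states = matrix(x, ncol = 1,
                                       dimnames = list(NULL, "X")),
                       iterations = 10000L, seed = 99L, burn_in = 0L,
                       sampler = "ancestral", monitor = "X"),
                  class = "bn_chain")
  s <- posterior_summary(ch, batches = 50)
  expect_lt(s$mc_error, 0.005 * 1.5)
  expect_gt(s$mc_error, 0.005 / 1.5)
  # sd identity for binary chains: sd = sqrt(p(1-p))
  p <- s$mean - 1
  expect_equal(s$sd, sqrt(p * (1 - p)), tolerance = 1e-12)
  expect_lt(s$mc_error, s$sd + 1e-12)

  expect_error(posterior_summary(ch, batches = 1), "at least 2")
  expect_error(posterior_summary(ch, batches = 20000), "too short")
})

test_that("ancestral draws are serially independent", {
  net <- bn_network(bn_stochastic("Ab", cpt(c(0.5, 0.5))))
  ch <- sample_posterior(net, evidence(), iterations = 10000, seed = 21)
  x <- ch$states[, "Ab"]
  rho1 <- stats::cor(x[-length(x)], x[-1])
  expect_lt(abs(rho1), 0.05)
})

test_that("degenerate sampling inputs are rejected", {
  net <- chain3_network()
  expect_error(sample_posterior(net, evidence(), iterations = 0),
               "positive")
  expect_error(sample_posterior(net, evidence(), iterations = -5),
               "positive")
})
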