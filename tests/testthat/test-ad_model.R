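test_that("the assembled network matches the curated structure", {
  fx <- get_fixture(1)
  net <- fx$network
  expect_identical(validate_network(net), character())
  expect_length(net$nodes, 57L)
  expect_length(adbn:::stochastic_names(net), 41L)
  expect_true(all(names(ad_categories()) %in% names(net$nodes)))

  # golden structural snapshot of the load-bearing edges
  expect_identical(net$nodes$Ab12$parents, c("APOE4", "PS1_2"))
  expect_identical(net$nodes$AbAPP$parents, "APP")
  expect_identical(net$nodes$MCI$parents, "DailyActivities")
  expect_identical(net$nodes$Tau_Phospho$parents, "Cytokines")
  expect_identical(net$nodes$GTP$parents, "p53")
  expect_identical(net$nodes$Ab$members, c("Ab12", "AbAPP"))
  expect_identical(net$nodes$ProdromalAD$members, c("max1", "OxidStress"))
  expect_identical(net$nodes$MixedAD$members, c("Vascular", "ProdromalAD"))
  expect_identical(net$nodes$ADPathology$members, "miRNAs")
  expect_setequal(net$nodes$Lifestyle$members,
                  c("Hypertension", "Depression", "Smoking", "Diabetes",
                    "Obesity", "PhysicalActivity"))
  expect_true("Lifestyle" %in% net$nodes$max1$members)
  expect_length(net$nodes$max1$members, 10L)
  # 47 stochastic edges + 45 aggregator memberships
  n_edges <- sum(vapply(net$nodes, function(n) length(adbn:::node_deps(n)),
                        integer(1L)))
  expect_identical(n_edges, 92L)
})

test_that("missing or misshaped parameter tables are reported by name", {
  fx <- get_fixture(1)
  params <- fx$params
  params$APP <- NULL
  expect_error(build_ad_network(params), "p\\.APP")
  params <- fx$params
  params$Ab <- cpt(c(0.5, 0.5))  # needs two parent axes
  expect_error(build_ad_network(params), "dimension")
})

test_that("case study 1 loads with the printed evidence and priors", {
  fx <- get_fixture(1)
  expect_length(fx$evidence, 6L)
  expect_true(all(fx$evidence == 2L))
  expect_setequal(names(fx$evidence),
                  c("Age_Inheritance", "MetalIons", "APP", "Cytokines",
                    "DailyActivities", "p53"))
  expect_length(fx$params, 41L)
  expect_equal(as.vector(unclass(fx$params$DailyActivities)), c(0, 1))
  expect_equal(as.vector(unclass(fx$params$MetalIons)), c(0.76, 0.24))
  expect_length(fx$corrections, 0L)
})

test_that("case study 2 keeps the printed always-true miRNAs table", {
  fx <- get_fixture(2)
  rows <- adbn:::cpt_rows(fx$params$miRNAs)
  expect_equal(unname(rows), matrix(c(0, 0, 1, 1), 2))
  expect_length(fx$corrections, 0L)
})

test_that("corrections reconcile case studies 3 and 4 with their tables", {
  expect_message(load_example(3), "miRNAs")
  fx3 <- get_fixture(3)
  expect_equal(unname(adbn:::cpt_rows(fx3$params$miRNAs)),
               matrix(c(1, 1, 0, 0), 2))

  fx4p <- get_fixture(4, corrected = FALSE)
  cp <- category_probabilities(fx4p$network, fx4p$evidence, mode = "exact")
  # as printed, Vascular is always true and drags Mixed AD to 1.0,
  # contradicting the published 0.464
  expect_equal(cp$probability[cp$category == "MixedAD"], 1)
  expect_false(isTRUE(all.equal(cp$probability[cp$category == "MixedAD"],
                                fx4p$expected$probability[5])))

  fx4 <- get_fixture(4)
  cp <- category_probabilities(fx4$network, fx4$evidence, mode = "exact")
  expect_equal(cp$probability[cp$category == "MixedAD"],
               1 - 0.884 * 0.868 * 0.726 * 0.966, tolerance = 1e-12)
})

test_that("Alzheimer's Pathology tracks the miRNAs marginal in every fixture", {
  for (id in 1:4) {
    fx <- get_fixture(id)
    expect_equal(exact_marginal(fx$network, fx$evidence, "ADPathology"),
                 exact_marginal(fx$network, fx$evidence, "miRNAs"),
                 tolerance = 1e-12)
  }
})

test_that("clamped roots only parent CPTs with identical rows", {
  # the claim that clamping the parent knots "does not affect the model
  # execution" requires every child CPT to repeat its rows across the
  # clamped parent's states
  for (id in 1:4) {
    fx <- get_fixture(id)
    for (node in fx$network$nodes) {
      if (node$kind != "stochastic") next
      clamped <- intersect(node$parents, names(fx$evidence))
      for (v in clamped) {
        k <- match(v, node$parents)
        a <- unclass(node$cpt)
        idx1 <- rep(list(TRUE), length(dim(a))); idx1[[k]] <- 1L
        idx2 <- rep(list(TRUE), length(dim(a))); idx2[[k]] <- 2L
        expect_equal(do.call(`[`, c(list(a), idx1)),
                     do.call(`[`, c(list(a), idx2)),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("category probabilities are invariant to the ambiguous wiring", {
  rewired <- list(
    list(Mito1 = c("MFN1", "DVLP"), Mito2 = c("OPA1", "FIS1"),
         Mito3 = "MetalIons"),
    list(OxidStress1 = c("Mito3", "MetalIons"),
         Inflamation2 = c("Mito1", "MetalIons"),
         Vascular = c("Ab12", "Tau_Phospho"))
  )
  fx <- get_fixture(1)
  base <- category_probabilities(fx$network, fx$evidence, mode = "exact")
  for (w in rewired) {
    alt <- load_example(1, wiring = utils::modifyList(ad_default_wiring(), w),
                        quiet = TRUE)
    cp <- category_probabilities(alt$network, alt$evidence, mode = "exact")
    expect_equal(cp$probability, base$probability, tolerance = 1e-12)
  }
  expect_error(build_ad_network(get_fixture(1)$params,
                                wiring = list(Mito3 = c("OPA1", "MFN1"))),
               "wiring slot 'Mito3'")
})

test_that("the prior registry reproduces the published rates", {
  reg <- prior_registry()
  expect_true(all(reg$low >= 0 & reg$high <= 1 & reg$low <= reg$high))
  expect_equal(prior_probability("Depression"), 0.132)
  expect_equal(prior_probability("Smoking"), 0.274)
  expect_equal(prior_probability("Obesity"), 0.034)
  gtp <- reg[reg$biomarker == "GTPases", ]
  expect_equal(gtp$high, 0.01)
  expect_lte(gtp$point, 0.01)
  apoe <- reg[reg$biomarker == "APOE4", ]
  expect_equal(c(apoe$low, apoe$high), c(0.30, 0.70))
  expect_equal(apoe$point, 0.70)
  expect_error(prior_probability("Unobtainium"), "unknown biomarker")
})
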