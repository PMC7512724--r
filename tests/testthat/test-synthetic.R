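test_that("random networks are valid, respect bounds, and are seed-deterministic", {
  one <- random_network(1, 0, 2, seed = 5)
  expect_identical(length(one$nodes), 1L)
  net <- random_network(6, 2, 2, seed = 99)
  expect_identical(nrow(validate_network(net)), 0L)
  expect_true(all(lengths(net$parents) <= 2))
  expect_equal(random_network(6, 2, 2, seed = 99), net)
  expect_false(isTRUE(all.equal(random_network(6, 2, 2, seed = 100), net)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(random_network(4, 2, 2, seed = 77))
  expect_identical(runif(1), before)
})

test_that("panel generation is a pure function of (consensus, recipe)", {
  net <- random_network(4, 2, 2, seed = 3)
  recipe <- panel_recipe(6, 15, seed = 12)
  p1 <- generate_panel(net, recipe)
  p2 <- generate_panel(net, recipe)
  expect_equal(p1$experts, p2$experts)
  expect_identical(p1$covariates, p2$covariates)
  expect_identical(nrow(validate_panel(p1)), 0L)
})

test_that("large concentration collapses the panel onto the consensus", {
  net <- random_network(4, 2, 2, seed = 8)
  panel <- generate_panel(net, panel_recipe(5, 1e9, seed = 21))
  for (id in names(panel$experts)) {
    for (nd in names(net$nodes)) {
      expect_equal(panel$experts[[id]][[nd]]$prob, net$cpts[[nd]]$prob,
                   tolerance = 1e-3)
    }
  }
  cmp <- pool_compare(panel, names(net$nodes)[1])
  expect_lt(max(cmp$abs_diff), 1e-3)
})

test_that("an injected subgroup shift is recovered from subgroup pooled CPTs", {
  consensus <- discrete_bn(list(cpt("X", c("up", "down"), prob = c(0.6, 0.4))))
  kappa <- 50
  n <- 200
  recipe <- panel_recipe(
    n, kappa,
    subgroup_effects = subgroup_effect("grp", "treated", "X", "up", 0.15),
    covariate_frequencies = list(grp = c(treated = 0.5, control = 0.5)),
    seed = 6060)
  panel <- generate_panel(consensus, recipe)
  treated <- pool_prior(filter_subgroup(panel, c(grp = "treated")))
  control <- pool_prior(filter_subgroup(panel, c(grp = "control")))
  diff <- treated$cpts$X$prob[1, "up"] - control$cpts$X$prob[1, "up"]
  # Dirichlet row variance p(1-p)/(kappa+1); two subgroups of n/2
  se <- sqrt((0.75 * 0.25 + 0.6 * 0.4) / (kappa + 1) / (n / 2))
  expect_lt(abs(diff - 0.15), 2 * se)
})

test_that("covariate frequencies are honoured exactly by largest remainder", {
  net <- random_network(2, 1, 2, seed = 14)
  panel <- generate_panel(net, panel_recipe(
    10, 10, covariate_frequencies = list(g = c(a = 0.25, b = 0.75)), seed = 2))
  counts <- table(panel$covariates$g)
  expect_identical(as.integer(counts[c("a", "b")]), c(3L, 7L))
})

test_that("the wayfinding fixture matches the published panel composition", {
  fx <- wayfinding_fixture()
  expect_identical(nrow(validate_network(fx$network)), 0L)
  expect_identical(nrow(validate_panel(fx$panel)), 0L)
  expect_identical(length(fx$panel$experts), 99L)
  covs <- fx$panel$covariates
  expect_identical(sum(covs$Gender == "Female"), 46L)
  expect_identical(sum(covs$Gender == "Male"), 53L)
  expect_identical(sum(covs[["Travel Purpose"]] == "Business"), 32L)
  expect_identical(sum(covs[["Travel Purpose"]] == "Personal"), 67L)
  expect_identical(sum(covs[["Travel Experience"]] == "Experienced"), 85L)
  expect_identical(sum(covs[["Travel Experience"]] == "Inexperienced"), 14L)
  expect_setequal(names(fx$network$nodes),
                  c("Communication", "Environmental Factors", "Human Factors",
                    "Navigation Pathway", "Visual Elements of Communication",
                    "Wayfinding"))
  expect_identical(fx$network$nodes$Wayfinding, c("Effective", "Ineffective"))
  expect_identical(fx$network$nodes$Communication, c("Effective", "Ineffective"))
  expect_identical(fx$network$nodes[["Human Factors"]], c("Good", "Bad"))
  expect_identical(fx$network$nodes[["Environmental Factors"]], c("Good", "Bad"))
  expect_identical(fx$network$nodes[["Navigation Pathway"]], c("Simple", "Complex"))
  expect_identical(fx$network$nodes[["Visual Elements of Communication"]],
                   c("Good", "Bad"))
})
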