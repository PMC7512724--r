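test_that("a well-formed panel validates cleanly and defaults to equal weights", {
  panel <- two_expert_panel()
  expect_identical(nrow(validate_panel(panel)), 0L)
  expect_equal(unname(panel$weights), c(0.5, 0.5))
})

test_that("a missing CPT is reported naming expert and node", {
  net <- chain_net()
  broken <- expert_panel(net,
                         list(x1 = chain_cpts(0.8, 0.9, 0.2),
                              x2 = chain_cpts(0.2, 0.6, 0.3)[1]),
                         check = FALSE)
  rep <- validate_panel(broken)
  expect_true(any(rep$violation == "missing_cpt" & rep$expert_id == "x2" &
                    rep$node == "B"))
})

test_that("bad weights are reported", {
  panel <- two_expert_panel()
  bad <- expert_panel(panel$structure, panel$experts,
                      weights = c(x1 = 0.5, x2 = 0.6), check = FALSE)
  rep <- validate_panel(bad)
  expect_true("weight_sum" %in% rep$violation)
  expect_match(rep$message[rep$violation == "weight_sum"], "1.1")
  neg <- expert_panel(panel$structure, panel$experts,
                      weights = c(x1 = 1.5, x2 = -0.5), check = FALSE)
  expect_true("weight_sign" %in% validate_panel(neg)$violation)
})

test_that("structure mismatches per expert are reported", {
  net <- chain_net()
  flipped <- list(cpt("A", c("f", "t"), prob = c(0.2, 0.8)),
                  net$cpts$B)
  panel <- expert_panel(net, list(x1 = chain_cpts(0.8, 0.9, 0.2), x2 = flipped),
                        check = FALSE)
  rep <- validate_panel(panel)
  expect_true(any(rep$violation == "state_mismatch" & rep$expert_id == "x2"))
})

test_that("filter_subgroup selects on all constraints and renormalises weights", {
  fx <- wayfinding_fixture()
  females <- filter_subgroup(fx$panel, c(Gender = "Female"))
  expect_identical(length(females$experts), 46L)
  expect_equal(sum(females$weights), 1, tolerance = 1e-12)
  expect_equal(unname(females$weights), rep(1 / 46, 46))
  # empty constraints are a no-op
  expect_identical(filter_subgroup(fx$panel), fx$panel)
  # conjunction of constraints
  both <- filter_subgroup(fx$panel, c(Gender = "Female",
                                      `Travel Experience` = "Inexperienced"))
  covs <- both$covariates
  expect_true(all(covs$Gender == "Female" &
                    covs[["Travel Experience"]] == "Inexperienced"))
  expect_error(filter_subgroup(fx$panel, c(Gender = "Other")),
               class = "bnpool_empty_subgroup")
  expect_error(filter_subgroup(fx$panel, c(Eyesight = "Good")),
               class = "bnpool_input_error")
})

test_that("complementary categories partition the panel", {
  fx <- wayfinding_fixture()
  f <- filter_subgroup(fx$panel, c(Gender = "Female"))
  m <- filter_subgroup(fx$panel, c(Gender = "Male"))
  expect_identical(length(f$experts) + length(m$experts), 99L)
  expect_length(intersect(names(f$experts), names(m$experts)), 0L)
})

test_that("subgroup weights stay proportional to the originals", {
  panel <- two_expert_panel()
  weighted <- expert_panel(panel$structure, panel$experts,
                           covariates = tibble::tibble(
                             expert_id = c("x1", "x2"), g = c("a", "a")),
                           weights = c(x1 = 0.3, x2 = 0.7))
  sub <- filter_subgroup(weighted, c(g = "a"))
  expect_equal(unname(sub$weights), c(0.3, 0.7), tolerance = 1e-12)
  one <- expert_panel(weighted$structure, weighted$experts,
                      covariates = tibble::tibble(
                        expert_id = c("x1", "x2"), g = c("a", "b")),
                      weights = c(x1 = 0.3, x2 = 0.7))
  solo <- filter_subgroup(one, c(g = "b"))
  expect_identical(length(solo$experts), 1L)
  expect_equal(unname(solo$weights), 1, tolerance = 1e-12)
})

test_that("subgroup_partitions enumerates observed categories", {
  fx <- wayfinding_fixture()
  parts <- subgroup_partitions(fx$panel, "Gender")
  expect_setequal(names(parts), c("Female", "Male"))
  expect_identical(unname(parts$Female), "Female")
  expect_identical(names(parts$Female), "Gender")
})
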