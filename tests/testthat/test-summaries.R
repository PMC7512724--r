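test_that("diagnostic scenarios condition against the arc direction", {
  net <- chain_net()
  res <- diagnostic_scenario(net, c(B = "t"), "A")
  expect_equal(res$prob[res$state == "t"], 0.72 / 0.76, tolerance = 1e-12)
  # clamping a disconnected node leaves the report marginal unchanged
  iso <- discrete_bn(c(chain_cpts(0.8, 0.9, 0.2),
                       list(cpt("Z", c("t", "f"), prob = c(0.3, 0.7)))))
  res2 <- diagnostic_scenario(iso, c(Z = "t"), "B")
  expect_equal(res2$prob[res2$state == "t"], 0.76, tolerance = 1e-12)
  # clamping a state already certain changes nothing
  certain <- chain_net(p_a = 1)
  res3 <- diagnostic_scenario(certain, c(A = "t"), "B")
  expect_equal(res3$prob[res3$state == "t"],
               marginal(certain, "B")$probabilities[["t"]], tolerance = 1e-12)
  expect_error(diagnostic_scenario(net, c(B = "t"), "B"),
               class = "bnpool_input_error")
})

test_that("delta tables report absolute differences per (label, node, state)", {
  base <- tibble::tibble(node = "HF", state = c("Good", "Bad"),
                         prob = c(0.8033, 1 - 0.8033))
  scen <- tibble::tibble(node = "HF", state = c("Good", "Bad"),
                         prob = c(0.7282, 1 - 0.7282))
  dt <- delta_table(base, list(`Female, Inexperienced` = scen))
  expect_equal(dt$abs_diff[dt$state == "Good"], 0.0751, tolerance = 1e-12)
  same <- delta_table(base, list(self = base))
  expect_true(all(same$abs_diff == 0))
  half <- delta_table(tibble::tibble(node = "X", state = c("a", "b"), prob = c(0.5, 0.5)),
                      list(s = tibble::tibble(node = "X", state = c("a", "b"),
                                              prob = c(1, 0))))
  expect_equal(half$abs_diff, c(0.5, 0.5))
  # symmetric under swapping baseline and scenario
  dt_sw <- delta_table(scen, list(x = base))
  expect_equal(sort(dt_sw$abs_diff), sort(dt$abs_diff), tolerance = 1e-15)
  expect_error(delta_table(base, list(bad = scen[1, ])), class = "bnpool_input_error")
})

test_that("per-expert marginals line up with the panel order and the pool", {
  panel <- two_expert_panel()
  pem <- per_expert_marginals(panel, "B", "t")
  expect_identical(pem$expert_id, c("x1", "x2"))
  expect_equal(pem$prob, c(0.76, 0.36), tolerance = 1e-12)
  # homogeneous panel: identical values
  net <- chain_net()
  hom <- homogeneous_panel(net, 4)
  vals <- per_expert_marginals(hom, "B", "t")$prob
  expect_equal(vals, rep(0.76, 4), tolerance = 1e-12)
  # weighted mean of the vector reproduces the PoLP value
  w <- panel$weights[pem$expert_id]
  expect_equal(sum(w * pem$prob),
               pool_posterior(panel, "B")$marginals$B$probabilities[["t"]],
               tolerance = 1e-12)
})

test_that("describe_spread computes sample sd and type-7 quantiles", {
  sp <- describe_spread(c(0.76, 0.36))
  expect_equal(sp$mean, 0.56)
  expect_equal(sp$sd, sd(c(0.76, 0.36)))
  expect_equal(sp$sd, 0.2828427, tolerance = 1e-6)
  const <- describe_spread(c(0.5, 0.5, 0.5))
  expect_equal(const$sd, 0)
  expect_equal(const$min, 0.5)
  expect_equal(const$max, 0.5)
  q <- describe_spread(c(0.2, 0.4, 0.6, 0.8))
  expect_equal(q$median, 0.5)
  expect_equal(q$q1, 0.35)
  expect_equal(q$q3, 0.65)
  single <- describe_spread(0.4)
  expect_equal(single$sd, 0)
  expect_error(describe_spread(numeric()), class = "bnpool_input_error")
  expect_error(describe_spread(c(0.5, 1.2)), class = "bnpool_input_error")
})

test_that("subgroup reports recover a constructed subgroup shift", {
  fx <- wayfinding_fixture()
  parts <- c(subgroup_partitions(fx$panel, "Gender"),
             subgroup_partitions(fx$panel, "Travel Purpose"),
             subgroup_partitions(fx$panel, "Travel Experience"))
  rep <- subgroup_report(fx$panel, "Wayfinding", subgroups = parts, method = "PoLP")
  eff <- rep[rep$state == "Effective" & rep$subgroup != "All", ]
  # the generator shifts Inexperienced respondents' Wayfinding CPT downward,
  # so that subgroup must show the largest absolute delta at Wayfinding
  expect_identical(eff$subgroup[which.max(eff$abs_diff)], "Inexperienced")
  expect_lt(eff$value[eff$subgroup == "Inexperienced"],
            rep$value[rep$subgroup == "All" & rep$state == "Effective"])
})

test_that("identical covariates make every subgroup equal the full panel", {
  net <- chain_net()
  panel <- expert_panel(net,
                        list(x1 = chain_cpts(0.8, 0.9, 0.2),
                             x2 = chain_cpts(0.2, 0.6, 0.3)),
                        covariates = tibble::tibble(expert_id = c("x1", "x2"),
                                                    g = c("same", "same")))
  rep <- subgroup_report(panel, "B", subgroups = list(same = c(g = "same")))
  expect_true(all(rep$abs_diff < 1e-15))
})

test_that("PoLP decomposes linearly over any covariate partition", {
  fx <- wayfinding_fixture()
  full <- pool_posterior(fx$panel, "Wayfinding")$marginals$Wayfinding$probabilities
  for (cov in c("Gender", "Travel Purpose", "Travel Experience")) {
    parts <- subgroup_partitions(fx$panel, cov)
    acc <- 0
    for (p in parts) {
      sub <- filter_subgroup(fx$panel, p)
      w_s <- sum(fx$panel$weights[names(sub$experts)])
      acc <- acc + w_s *
        pool_posterior(sub, "Wayfinding")$marginals$Wayfinding$probabilities
    }
    expect_equal(acc, full, tolerance = 1e-12)
  }
})

test_that("the conditioning route clamps subgroup nodes as evidence", {
  # structure with an explicit subgroup node: G -> B
  net <- discrete_bn(list(
    cpt("G", c("F", "M"), prob = c(0.5, 0.5)),
    cpt("B", c("t", "f"), parents = "G", parent_states = list(G = c("F", "M")),
        prob = rbind(c(0.7, 0.3), c(0.4, 0.6)))))
  panel <- homogeneous_panel(net, 3)
  rep <- subgroup_report(panel, "B",
                         subgroup_evidence = list(Female = c(G = "F")),
                         method = "PrLP")
  expect_equal(rep$value[rep$subgroup == "Female" & rep$state == "t"], 0.7,
               tolerance = 1e-12)
  expect_equal(rep$value[rep$subgroup == "All" & rep$state == "t"], 0.55,
               tolerance = 1e-12)
})

test_that("spread_report summarises each subgroup and node", {
  fx <- wayfinding_fixture()
  parts <- subgroup_partitions(fx$panel, "Gender")
  sp <- spread_report(fx$panel, c(Wayfinding = "Effective",
                                  `Human Factors` = "Good"),
                      subgroups = parts)
  expect_identical(nrow(sp), 6L)  # (All, Female, Male) x 2 nodes
  expect_true(all(sp$n[sp$label == "All"] == 99))
  expect_true(all(sp$mean >= sp$min & sp$mean <= sp$max))
  expect_true(all(sp$sd >= 0))
  expect_true(all(sp$q1 <= sp$median & sp$median <= sp$q3))
})
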