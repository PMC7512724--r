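test_that("linear_pool averages with weights and checks its inputs", {
  expect_equal(linear_pool(list(c(0.6, 0.4), c(0.8, 0.2))), c(0.7, 0.3))
  expect_equal(linear_pool(list(c(0.3, 0.7))), c(0.3, 0.7))
  expect_equal(linear_pool(list(c(1, 0), c(0, 1)), c(0.25, 0.75)), c(0.25, 0.75))
  expect_error(linear_pool(list(c(0.6, 0.4), c(0.5, 0.2, 0.3))),
               class = "bnpool_input_error")
  expect_error(linear_pool(list(c(0.6, 0.5))), class = "bnpool_input_error")
  expect_error(linear_pool(list(c(0.6, 0.4), c(0.8, 0.2)), c(0.5, 0.6)),
               class = "bnpool_input_error")
})

test_that("prior pooling averages every CPT row (worked two-expert chain)", {
  pooled <- pool_prior(two_expert_panel())
  expect_equal(pooled$cpts$A$prob[1, "t"][[1]], 0.5, tolerance = 1e-12)
  expect_equal(pooled$cpts$B$prob[, "t"], c(0.75, 0.25), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(nrow(validate_network(pooled)), 0L)
})

test_that("prior pooling of a homogeneous panel returns the expert's network", {
  net <- random_network(5, 2, 2, seed = 31)
  pooled <- pool_prior(homogeneous_panel(net, 7))
  for (nd in names(net$nodes)) {
    expect_equal(pooled$cpts[[nd]]$prob, net$cpts[[nd]]$prob, tolerance = 1e-12)
  }
  solo <- pool_prior(homogeneous_panel(net, 1))
  for (nd in names(net$nodes)) {
    expect_equal(solo$cpts[[nd]]$prob, net$cpts[[nd]]$prob, tolerance = 1e-15)
  }
})

test_that("posterior pooling pools per-expert marginals (worked example)", {
  res <- pool_posterior(two_expert_panel(), "B")
  expect_equal(res$marginals$B$probabilities[["t"]], 0.56, tolerance = 1e-12)
  expect_identical(res$method, "PoLP")
  expect_identical(res$n_experts, 2L)
  # per-expert values that feed the pool
  pem <- per_expert_marginals(two_expert_panel(), "B", "t")
  expect_equal(pem$prob, c(0.76, 0.36), tolerance = 1e-12)
})

test_that("the worked chain keeps PrLP and PoLP apart by 0.06 at node B", {
  cmp <- pool_compare(two_expert_panel(), "B")
  t_row <- cmp[cmp$state == "t", ]
  expect_equal(t_row$prlp, 0.50, tolerance = 1e-12)
  expect_equal(t_row$polp, 0.56, tolerance = 1e-12)
  expect_equal(t_row$abs_diff, 0.06, tolerance = 1e-12)
})

test_that("PrLP and PoLP collapse onto each other for homogeneous panels", {
  set.seed(23)
  for (k in 1:40) {
    net <- random_network(sample(3:6, 1), 2, 2, seed = 7000 + k)
    panel <- homogeneous_panel(net, sample(2:5, 1))
    ev <- random_evidence(net, sample(0:1, 1))
    tg <- sample(setdiff(names(net$nodes), names(ev)), 1)
    prior <- tryCatch(pool_prior_marginals(panel, tg, ev),
                      bnpool_impossible_evidence = function(e) NULL)
    if (is.null(prior)) next
    post <- pool_posterior(panel, tg, ev)
    expect_equal(prior$marginals[[tg]]$probabilities,
                 post$marginals[[tg]]$probabilities, tolerance = 1e-12)
  }
})

test_that("root-node queries agree between methods even for heterogeneous panels", {
  set.seed(29)
  for (k in 1:10) {
    panel <- random_panel(5, 6, seed = 400 + k)
    net <- panel$structure
    roots <- names(net$nodes)[lengths(net$parents) == 0]
    for (tg in roots) {
      cmp <- pool_compare(panel, tg)
      expect_lt(max(cmp$abs_diff), 1e-12)
    }
  }
})

test_that("pooled PoLP marginals stay inside the experts' convex hull", {
  set.seed(37)
  for (k in 1:10) {
    panel <- random_panel(5, 8, seed = 600 + k)
    tg <- sample(names(panel$structure$nodes), 1)
    res <- pool_posterior(panel, tg)
    per <- vapply(names(panel$experts), function(id) {
      marginal(bnpool:::expert_bn(panel, id), tg)$probabilities
    }, numeric(2))
    pooled <- res$marginals[[tg]]$probabilities
    expect_true(all(pooled >= apply(per, 1, min) - 1e-12))
    expect_true(all(pooled <= apply(per, 1, max) + 1e-12))
  }
})

test_that("without evidence PoLP equals the mixture-of-joints marginal", {
  set.seed(41)
  for (k in 1:10) {
    panel <- random_panel(4, 5, seed = 800 + k)
    w <- panel$weights
    mix <- NULL
    for (id in names(panel$experts)) {
      jt <- enumerate_joint(bnpool:::expert_bn(panel, id))
      if (is.null(mix)) { mix <- jt; mix$prob <- w[[id]] * jt$prob }
      else mix$prob <- mix$prob + w[[id]] * jt$prob
    }
    tg <- sample(names(panel$structure$nodes), 1)
    agg <- tapply(mix$prob, factor(mix[[tg]], levels = panel$structure$nodes[[tg]]), sum)
    res <- pool_posterior(panel, tg)
    expect_equal(unname(res$marginals[[tg]]$probabilities), as.numeric(agg),
                 tolerance = 1e-10)
  }
})

test_that("under evidence PoLP is NOT the conditioned mixture (regression)", {
  panel <- two_expert_panel()
  res <- pool_posterior(panel, "A", c(B = "t"))
  polp <- res$marginals$A$probabilities[["t"]]
  expect_equal(polp, (0.72 / 0.76 + 0.12 / 0.36) / 2, tolerance = 1e-12)
  # conditioned equal-weight mixture of joints: P(A=t | B=t) = 0.42 / 0.56
  mixture <- ((0.72 + 0.12) / 2) / ((0.76 + 0.36) / 2)
  expect_equal(mixture, 0.75, tolerance = 1e-12)
  # the two genuinely differ, and in this network PoLP sits below the mixture
  expect_lt(polp, mixture)
  expect_gt(abs(polp - mixture), 0.1)
})

test_that("impossible evidence for one expert errors by default, drops on request", {
  net <- chain_net()
  panel <- expert_panel(net, list(x1 = chain_cpts(1, 0.9, 0.2),   # A certainly t
                                  x2 = chain_cpts(0.5, 0.9, 0.2)))
  expect_error(pool_posterior(panel, "B", c(A = "f")),
               class = "bnpool_impossible_evidence")
  expect_warning(res <- pool_posterior(panel, "B", c(A = "f"),
                                       drop_impossible = TRUE),
                 "dropping")
  expect_identical(res$n_experts, 1L)
  expect_equal(res$marginals$B$probabilities[["t"]], 0.2, tolerance = 1e-12)
})

test_that("pooling refuses an invalid panel citing the report", {
  net <- chain_net()
  broken <- expert_panel(net, list(x1 = chain_cpts(0.8, 0.9, 0.2)[1]),
                         check = FALSE)
  expect_error(pool_prior(broken), class = "bnpool_validation_error")
  expect_error(pool_posterior(broken, "B"), class = "bnpool_validation_error")
})
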