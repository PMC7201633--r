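# Bayesian networks: scoring, structure learning, parameter fitting,
# and inference against the exact-enumeration oracle.

test_that("DAG construction enforces acyclicity and rejects self-loops", {
  expect_error(bn_dag(c("a", "b"), rbind(c("a", "b"), c("b", "a"))), "cycle")
  expect_error(bn_dag(c("a", "b"), rbind(c("a", "a"))), "self-loop")
  d <- bn_dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_equal(nrow(dag_arcs(d)), 2)
})

test_that("BIC score matches the closed form for a single binary node", {
  x <- factor(c(rep("yes", 60), rep("no", 40)), levels = c("no", "yes"))
  df <- data.frame(v = x, w = factor(rep(c("a", "b"), 50)))
  sc <- bic_score(bn_dag(c("v", "w")), df)
  ll <- 60 * log(0.6) + 40 * log(0.4)
  expect_equal(unname(sc$by_node[["v"]]), ll - 0.5 * log(100), tolerance = 1e-12)
})

test_that("BIC is decomposable: a local edit changes only that node's term", {
  fx <- coded_cohort_fixture(800, 17)
  nodes <- c("hm_category", "hemoglobin_low", "egfr_band", "aki")
  d0 <- bn_dag(nodes)
  d1 <- bn_dag(nodes, rbind(c("hm_category", "hemoglobin_low")))
  s0 <- bic_score(d0, fx$coded); s1 <- bic_score(d1, fx$coded)
  changed <- names(which(abs(s0$by_node - s1$by_node) > 1e-9))
  expect_identical(changed, "hemoglobin_low")
  expect_equal(s1$score - s0$score,
               s1$by_node[["hemoglobin_low"]] - s0$by_node[["hemoglobin_low"]],
               tolerance = 1e-9)
  expect_error(bic_score(bn_dag(c("aki", "nope")), fx$coded), "absent")
})

test_that("under independence the empty graph beats any single arc", {
  withr::with_seed(5, {
    df <- data.frame(a = factor(sample(c("x", "y"), 5000, TRUE)),
                     b = factor(sample(c("u", "v", "w"), 5000, TRUE)))
  })
  s_empty <- bic_score(bn_dag(c("a", "b")), df)$score
  s_arc <- bic_score(bn_dag(c("a", "b"), rbind(c("a", "b"))), df)$score
  s_arc2 <- bic_score(bn_dag(c("a", "b"), rbind(c("b", "a"))), df)$score
  expect_gt(s_empty, s_arc)
  expect_gt(s_empty, s_arc2)
})

test_that("tabu search recovers a strong chain and leaves noise unconnected", {
  lev <- list(A = c("a1", "a2"), B = c("b1", "b2"), C = c("c1", "c2"))
  chain <- bayes_net(
    bn_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C"))),
    list(A = bn_cpt("A", lev$A, prob = c(0.4, 0.6)),
         B = bn_cpt("B", lev$B, "A", lev, rbind(c(0.9, 0.1), c(0.15, 0.85))),
         C = bn_cpt("C", lev$C, "B", lev, rbind(c(0.85, 0.15), c(0.2, 0.8)))))
  df <- rbn(chain, 5000, seed = 3)
  learned <- tabu_learn(df)
  expect_setequal(skel_set(dag_arcs(learned)), c("A~B", "B~C"))

  withr::with_seed(6, {
    ind <- data.frame(a = factor(sample(c("x", "y"), 5000, TRUE)),
                      b = factor(sample(c("u", "v"), 5000, TRUE)),
                      c = factor(sample(c("p", "q"), 5000, TRUE)))
  })
  expect_equal(nrow(dag_arcs(tabu_learn(ind))), 0)
})

test_that("whitelists are honored, blacklists enforced, cyclic whitelists rejected", {
  fx <- coded_cohort_fixture(800, 17)
  wl <- rbind(c("wbc_high", "aki"))
  d <- tabu_learn(fx$coded, nodes = c("wbc_high", "aki", "egfr_band"), whitelist = wl)
  expect_true("wbc_high" %in% d$parents[["aki"]])
  bl <- rbind(c("egfr_band", "aki"), c("aki", "egfr_band"))
  d2 <- tabu_learn(fx$coded, nodes = c("egfr_band", "aki", "sodium_band"), blacklist = bl)
  expect_false("egfr_band" %in% d2$parents[["aki"]])
  expect_false("aki" %in% d2$parents[["egfr_band"]])
  expect_error(tabu_learn(fx$coded, nodes = c("aki", "egfr_band"),
                          whitelist = rbind(c("aki", "egfr_band"), c("egfr_band", "aki"))),
               "cycle")
})

test_that("maximum-likelihood CPTs: frequencies, smoothing, zero-row fallback", {
  df <- data.frame(x = factor(c(rep("a", 60), rep("b", 40)), levels = c("a", "b")))
  net <- fit_cpts(bn_dag("x"), df)
  expect_equal(unname(net$cpts$x$prob[1, ]), c(0.6, 0.4))

  # parent level never observed: uniform fallback with a warning
  df2 <- data.frame(p = factor(rep("u", 50), levels = c("u", "v")),
                    y = factor(rep(c("a", "b"), 25)))
  expect_warning(net2 <- fit_cpts(bn_dag(c("p", "y"), rbind(c("p", "y"))), df2),
                 "unobserved")
  expect_equal(unname(net2$cpts$y$prob[2, ]), c(0.5, 0.5))
  # pseudo-count 1 on the unobserved row of a binary node is also uniform
  net3 <- fit_cpts(bn_dag(c("p", "y"), rbind(c("p", "y"))), df2, smoothing = 1)
  expect_equal(unname(net3$cpts$y$prob[2, ]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(net3$cpts$y$prob) - 1) < 1e-12))
})

test_that("cpd_table formats percentages in parent-configuration order", {
  fx <- coded_cohort_fixture(2000, 31)
  dag <- bn_dag(c("egfr_band", "hemoglobin_low", "sodium_band", "aki"),
                rbind(c("egfr_band", "aki"), c("hemoglobin_low", "aki"),
                      c("sodium_band", "aki")))
  net <- suppressWarnings(fit_cpts(dag, fx$coded, smoothing = 1))
  tab <- cpd_table(net, "aki")
  expect_equal(nrow(tab), 18)
  expect_true(all(abs(tab$pct_no + tab$pct_yes - 100) < 1e-9))
  # first parent varies slowest
  expect_equal(as.character(tab$egfr_band[1:6]), rep(">=90", 6))
  # monotone generator: worst configuration clearly exceeds the best
  worst <- tab$egfr_band == "<=59" & tab$hemoglobin_low == "yes" & tab$sodium_band == "hypo"
  best <- tab$egfr_band == ">=90" & tab$hemoglobin_low == "no" & tab$sodium_band == "normal"
  expect_gt(tab$pct_yes[worst], tab$pct_yes[best] + 20)
  # and on the generator's own network the conditional is maximal there
  truth <- cohort_params(n_patients = 1)$truth
  sub_nodes <- truth_nodes()
  sub <- bayes_net(bn_dag(sub_nodes, truth_arc_matrix()), truth$cpts[sub_nodes])
  p_cond <- function(e, h, s) infer_exact(
    sub, list(egfr_band = e, hemoglobin_low = h, sodium_band = s), "aki")[["yes"]]
  expect_gt(p_cond("<=59", "yes", "hypo"), p_cond(">=90", "no", "normal"))
  expect_gt(p_cond("<=59", "yes", "hypo"), p_cond("<=59", "no", "normal"))
  # parentless node gives a single row
  net0 <- fit_cpts(bn_dag("aki"), fx$coded)
  expect_equal(nrow(cpd_table(net0, "aki")), 1)
})

test_that("exact inference: point mass, hand Bayes rule, marginals, impossible evidence", {
  lev <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  net <- bayes_net(bn_dag(c("A", "B"), rbind(c("A", "B"))),
                   list(A = bn_cpt("A", lev$A, prob = c(0.3, 0.7)),
                        B = bn_cpt("B", lev$B, "A", lev,
                                   rbind(c(0.9, 0.1), c(0.2, 0.8)))))
  expect_equal(unname(infer_exact(net, list(A = "a2"), "A")), c(0, 1))
  # hand Bayes rule: P(A=a1 | B=b1) = .3*.9 / (.3*.9 + .7*.2)
  expect_equal(infer_exact(net, list(B = "b1"), "A")[["a1"]],
               0.27 / 0.41, tolerance = 1e-12)
  expect_equal(infer_exact(net, list(), "B")[["b1"]],
               0.3 * 0.9 + 0.7 * 0.2, tolerance = 1e-12)

  net0 <- bayes_net(bn_dag(c("A", "B"), rbind(c("A", "B"))),
                    list(A = bn_cpt("A", lev$A, prob = c(1, 0)),
                         B = bn_cpt("B", lev$B, "A", lev,
                                    rbind(c(1, 0), c(0.5, 0.5)))))
  expect_error(infer_exact(net0, list(B = "b2"), "A"), "impossible evidence")
  # enumerated joint is normalized on random nets
  for (s in 1:5) {
    j <- akinet:::joint_enumeration(rand_net(5, s))
    expect_equal(sum(j$prob), 1, tolerance = 1e-9)
  }
})

test_that("likelihood weighting agrees with enumeration and beats rejection variance", {
  for (s in 1:15) {
    net <- rand_net(5, s)
    ev <- list(X5 = net$cpts$X5$levels[1])
    ex <- infer_exact(net, ev, "X1")
    lw <- infer_lw(net, ev, "X1", n_samples = 20000, seed = s)
    expect_lt(abs(lw$prob[[1]] - ex[[1]]), 3 * lw$se[[1]] + 1e-3,
              label = sprintf("net %d", s))
    ls <- infer_logic_sampling(net, ev, "X1", n_samples = 20000, seed = s)
    expect_lt(abs(ls$prob[[1]] - ex[[1]]), 0.05)
  }
  # no evidence: weights are all one and LW reduces to forward sampling
  net <- rand_net(4, 99)
  lw <- infer_lw(net, list(), "X2", n_samples = 5000, seed = 1)
  expect_equal(lw$ess, 5000)
  # unlikely evidence: LW has lower replicate variance than rejection
  net <- rand_net(5, 42)
  ev <- list(X5 = net$cpts$X5$levels[1], X4 = net$cpts$X4$levels[1])
  est_lw <- vapply(1:25, function(s) infer_lw(net, ev, "X1", 2000, seed = s)$prob[[1]], 0)
  est_ls <- vapply(1:25, function(s)
    infer_logic_sampling(net, ev, "X1", 2000, seed = s)$prob[[1]], 0)
  expect_lt(var(est_lw), var(est_ls))

  lev <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  net0 <- bayes_net(bn_dag(c("A", "B"), rbind(c("A", "B"))),
                    list(A = bn_cpt("A", lev$A, prob = c(1, 0)),
                         B = bn_cpt("B", lev$B, "A", lev,
                                    rbind(c(1, 0), c(0.5, 0.5)))))
  expect_error(infer_lw(net0, list(B = "b2"), "A", 1000, seed = 1), "zero")
  expect_error(infer_logic_sampling(net0, list(B = "b2"), "A", 1000, seed = 1),
               "acceptance rate")
})

test_that("likelihood-weighting error shrinks like one over root n", {
  net <- rand_net(5, 42)
  ev <- list(X5 = net$cpts$X5$levels[1], X4 = net$cpts$X4$levels[1])
  ex <- infer_exact(net, ev, "X1")[[1]]
  ns <- c(1e3, 1e4, 1e5)
  errs <- vapply(ns, function(n) {
    mean(vapply(1:20, function(s)
      abs(infer_lw(net, ev, "X1", n, seed = 1000 + s)$prob[[1]] - ex), 0))
  }, 0)
  slope <- coef(stats::lm(log(errs) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("scenario inference: empty evidence is the marginal, full evidence is exact", {
  net <- rand_net(5, 7)
  full_ev <- stats::setNames(lapply(net$dag$nodes[-1], function(nd)
    net$cpts[[nd]]$levels[1]), net$dag$nodes[-1])
  res <- scenario_inference(net, list(none = list(), all = full_ev),
                            query = "X1", n_samples = 30000, seed = 2)
  expect_equal(res$posterior[res$scenario == "none"], res$marginal[1], tolerance = 1e-9)
  ex <- infer_exact(net, full_ev, "X1")
  lev2 <- net$cpts$X1$levels[min(2, length(net$cpts$X1$levels))]
  lw_full <- infer_lw(net, full_ev, "X1", 30000, seed = 2)
  expect_lt(abs(res$posterior[res$scenario == "all"] - ex[[lev2]]),
            3 * lw_full$se[[lev2]] + 1e-3)
})

test_that("network JSON and BIF serializations round-trip / are well-formed", {
  net <- rand_net(4, 12)
  js <- bn_to_json(net)
  net2 <- bn_from_json(js)
  expect_equal(net2$dag$parents, net$dag$parents[net2$dag$nodes])
  for (nd in net$dag$nodes) {
    expect_equal(net2$cpts[[nd]]$prob, net$cpts[[nd]]$prob, tolerance = 1e-12)
  }
  bif <- file.path(tempdir(), "net.bif")
  write_bif(net, bif)
  txt <- readLines(bif)
  expect_equal(sum(grepl("^variable ", txt)), 4)
  expect_equal(sum(grepl("^probability ", txt)), 4)
})
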