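# A metabolite table is all carbon_yield needs from the network.
yield_net <- local({
  mets <- data.frame(
    id = c("G6P", "ACE", "NH4", "GLY", "ALA", "LYS", "CO2"),
    name = NA, carbon_count = c(6, 2, 0, 2, 3, 6, 1),
    is_external = TRUE, skip_carbon_check = FALSE)
  metabolic_network(mets, list(reaction("dummy", c(G6P = -1, CO2 = 6))))
})

test_that("carbon yields follow the overall-equation arithmetic", {
  # 1 G6P + 2 NH4 -> 2 Gly + 2 CO2
  expect_equal(carbon_yield(c(G6P = -1, NH4 = -2, GLY = 2, CO2 = 2),
                            "GLY", "G6P", yield_net), 2 / 3)
  # 3 acetate -> 1 Lys (no CO2): all source carbon retained
  expect_equal(carbon_yield(c(ACE = -3, LYS = 1), "LYS", c("G6P", "ACE"),
                            yield_net), 1)
  # mixed sources: 1 G6P + 1 acetate -> 2 Ala + 2 CO2
  expect_equal(carbon_yield(c(G6P = -1, ACE = -1, ALA = 2, CO2 = 2),
                            "ALA", c("G6P", "ACE"), yield_net), 3 / 4)
  expect_error(carbon_yield(c(GLY = 1), "GLY", "G6P", yield_net),
               "consumes no designated carbon source")
  expect_error(carbon_yield(c(G6P = -1, CO2 = 6), "GLY", "G6P", yield_net),
               "does not net-produce")
  expect_error(carbon_yield(c(G6P = -1, GLY = 3), "GLY", "CO2", yield_net),
               "CO2")
})

test_that("scheme summaries implement plain, knockout and weighted statistics", {
  recs <- data.frame(yield = c(0.5, 1.0), affected = c(TRUE, FALSE))
  s <- summarise_yields(recs, "weighted", 0.1)
  expect_equal(s$weighted_mean, (0.1 * 0.5 + 1 * 1.0) / 1.1)
  # with unit weight the weighted mean reduces to the plain mean
  s1 <- summarise_yields(recs, "weighted", 1)
  expect_equal(s1$weighted_mean, 0.75)
  expect_equal(s1$weighted_mean, s1$mean)

  recs5 <- data.frame(yield = seq(0.2, 1, by = 0.2), affected = FALSE)
  s <- summarise_yields(recs5, "all")
  expect_equal(s$min, 0.2)
  expect_equal(s$median, 0.6)
  expect_equal(s$max, 1.0)
  expect_equal(s$mean, 0.6)

  ko <- summarise_yields(data.frame(yield = c(0.9, 0.3, 0.2),
                                    affected = c(FALSE, TRUE, TRUE)), "knockout")
  expect_equal(ko$mean, 0.9)
  # all modes affected: the knockout distribution is infeasible (arginine case)
  inf <- summarise_yields(data.frame(yield = 0.5, affected = TRUE), "knockout")
  expect_false(inf$feasible)
  expect_equal(inf$n_modes, 0L)
  expect_true(is.na(inf$mean))
  expect_false(summarise_yields(data.frame(yield = numeric(),
                                           affected = logical()), "all")$feasible)
  expect_error(summarise_yields(recs, "weighted", 0), "w_affected")
  expect_error(summarise_yields(recs, "weighted", 1.5), "w_affected")
})

test_that("equal weights reduce the weighted mean to the plain mean", {
  withr::local_seed(101)
  for (i in 1:20) {
    n <- sample(2:50, 1)
    recs <- data.frame(yield = runif(n, 0, 2),
                       affected = runif(n) < 0.5)
    s <- summarise_yields(recs, "weighted", 1)
    expect_equal(s$weighted_mean, mean(recs$yield), tolerance = 1e-12)
  }
})

test_that("the weighted mean moves monotonically from all-mean to unaffected mean", {
  withr::local_seed(202)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    recs <- data.frame(yield = runif(n, 0, 2), affected = runif(n) < 0.5)
    if (!any(recs$affected) || all(recs$affected)) next
    ws <- c(1, 0.5, 0.2, 0.1, 0.05, 0.01)
    wm <- vapply(ws, function(w) summarise_yields(recs, "weighted", w)$weighted_mean,
                 numeric(1))
    d <- diff(wm)
    expect_true(all(d >= -1e-12) || all(d <= 1e-12))
    expect_equal(wm[1], mean(recs$yield))
    unaff_mean <- mean(recs$yield[!recs$affected])
    expect_lte(abs(wm[length(ws)] - unaff_mean),
               abs(wm[1] - unaff_mean) + 1e-12)
  }
})

test_that("weighted quantiles at w = 1/10 equal explicit 10x/1x replication", {
  withr::local_seed(303)
  for (i in 1:10) {
    n <- sample(3:60, 1)
    recs <- data.frame(yield = round(runif(n, 0, 2), 3),
                       affected = runif(n) < 0.4)
    s <- summarise_yields(recs, "weighted", 0.1)
    rep_sample <- rep(recs$yield, ifelse(recs$affected, 1L, 10L))
    q <- unname(quantile(rep_sample, c(0, 0.25, 0.5, 0.75, 1), type = 7))
    expect_equal(c(s$min, s$q1, s$median, s$q3, s$max), q, tolerance = 1e-12)
  }
})

test_that("summary invariants hold on enumerated yield distributions", {
  net <- chlamy_core_network()
  efms <- enumerate_efms(net)
  reg <- net$config$regulated_reactions
  for (tg in c("GLY", "LYS")) {
    recs <- carbon_yields(classify_by_target(efms, tg), tg, regulated = reg)
    for (sc in c("all", "knockout", "weighted")) {
      s <- summarise_yields(recs, sc)
      expect_true(s$min <= s$q1 && s$q1 <= s$median &&
                  s$median <= s$q3 && s$q3 <= s$max)
      expect_true(s$min <= s$mean && s$mean <= s$max)
      expect_true(s$min <= s$weighted_mean && s$weighted_mean <= s$max)
      expect_lte(s$n_affected, s$n_modes)
    }
  }
})

test_that("yield equals one minus the CO2 share when the target is the sole carbon product", {
  net <- chlamy_core_network()
  efms <- enumerate_efms(net)
  OV <- circaflux:::overall_matrix(efms)
  carbon <- setNames(net$metabolites$carbon_count, net$metabolites$id)
  sel <- classify_by_target(efms, "GLY")
  OVs <- circaflux:::overall_matrix(sel)
  carbon_products <- setdiff(rownames(OVs)[carbon[rownames(OVs)] > 0],
                             c("G6P", "ACE", "CO2", "GLY"))
  sole <- colSums(OVs[carbon_products, , drop = FALSE] > 0) == 0 &
          OVs["CO2", ] > 0
  expect_gt(sum(sole), 0)
  ys <- carbon_yields(sel, "GLY")$yield
  src_carbon <- colSums(pmax(-OVs[c("G6P", "ACE"), , drop = FALSE], 0) *
                        carbon[c("G6P", "ACE")])
  expect_equal(ys[sole], unname(1 - OVs["CO2", sole] / src_carbon[sole]),
               tolerance = 1e-12)
})

test_that("scenario comparison flags the mean-up/max-not-up pattern", {
  t2 <- toy_network("T2_diamond")$network
  # make the R3 branch (yield equal) regulated; means equal, max equal
  efms <- enumerate_efms(t2)
  tab <- scenario_compare(efms, "R3", targets = "Pext", carbon_sources = "Sext")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$max_not_increased[tab$scheme != "all"]))
  # a constructed case where affected modes are the poor ones
  net <- net_from_equations(
    list(R1 = "1 Sext -> 1 A", R2 = "1 A -> 1 Pext",
         R4 = "3 Sext -> 1 A + 6 CO2"),
    externals = c("Sext", "Pext", "CO2"),
    carbons = c(Sext = 3, A = 3, Pext = 3, CO2 = 1),
    config = list(carbon_sources = "Sext", targets = "Pext"))
  expect_equal(nrow(validate_carbon_balance(net)), 0)
  efms <- enumerate_efms(net)
  tab <- scenario_compare(efms, "R4", targets = "Pext")
  ko <- tab[tab$scheme == "knockout", ]
  expect_true(ko$mean_increases)
  expect_true(ko$max_not_increased)
})
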