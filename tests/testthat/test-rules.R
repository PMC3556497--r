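models <- c("no_cooperation", "substrate_activation", "product_activation")

test_that("each model's truth table has exactly the 22 canonical keys", {
  for (m in models) {
    tab <- allosteric_table(m)
    e <- tab$entries
    expect_equal(nrow(e), 22)
    for (cl in c("R1", "R2", "S1")) {
      expect_setequal(e$state[e$class == cl],
                      c("000", "010", "011", "100", "110", "111"))
    }
    expect_setequal(e$state[e$class == "R3"], c("000", "100", "110", "111"))
    expect_true(all(e$pa >= 0 & e$pa <= 1))
  }
})

test_that("general rows are shared: S1 active only at 011, R3 constant 0.7", {
  for (m in models) {
    tab <- allosteric_table(m)
    expect_equal(allosteric_parameter(tab, "S1", "011"), 1)
    for (s in c("000", "010", "100", "110", "111")) {
      expect_equal(allosteric_parameter(tab, "S1", s), 0)
    }
    for (s in c("000", "100", "110", "111")) {
      expect_equal(allosteric_parameter(tab, "R3", s), 0.7)
    }
  }
})

test_that("model-specific R1/R2 rows match the published truth tables", {
  # worked example: R2 with status {0,1,1}
  expect_equal(allosteric_parameter(allosteric_table("no_cooperation"),
                                    "R2", "011"), 1)
  expect_equal(allosteric_parameter(allosteric_table("substrate_activation"),
                                    "R2", "011"), 0.5)
  expect_equal(allosteric_parameter(allosteric_table("product_activation"),
                                    "R2", "011"), 1)
  # spot values
  expect_equal(allosteric_parameter(allosteric_table("product_activation"),
                                    "R2", "010"), 1)
  expect_equal(allosteric_parameter(allosteric_table("substrate_activation"),
                                    "R1", "000"), 0.7)
  # no cooperation: all R1/R2 entries are 1
  nc <- allosteric_table("no_cooperation")$entries
  expect_true(all(nc$pa[nc$class %in% c("R1", "R2")] == 1))
  # substrate activation: R2 non-increasing in phosphorylated R neighbours
  sa <- allosteric_table("substrate_activation")
  expect_identical(vapply(c("000", "010", "011"), function(s)
    allosteric_parameter(sa, "R2", s), numeric(1)),
    c("000" = 1, "010" = 0.7, "011" = 0.5))
  # phosphorylated RsbS neighbour blocks R2 in both interaction models
  for (m in c("substrate_activation", "product_activation")) {
    tab <- allosteric_table(m)
    for (s in c("100", "110", "111")) {
      expect_equal(allosteric_parameter(tab, "R2", s), 0)
    }
  }
  # product activation: R2 inactive with no phosphorylated neighbour
  expect_equal(allosteric_parameter(allosteric_table("product_activation"),
                                    "R2", "000"), 0)
  # unknown key errors rather than defaulting
  expect_error(allosteric_parameter(allosteric_table("product_activation"),
                                    "R3", "010"), "no allosteric entry")
})

test_that("neighbour_state canonicalizes solitary-first, pair descending", {
  g <- canonical_graph
  nd <- g$nodes
  st <- integer(60)
  # R2: solitary S unphosphorylated, both R neighbours phosphorylated -> 011
  i <- which(nd$class == "R2")[1]
  lat <- as_ca_lattice(g)
  st[c(lat$p1[i], lat$p2[i])] <- 1L
  ns <- neighbour_state(g, st, i)
  expect_identical(ns, list(class = "R2", state = "011"))
  # S1: S partner phosphorylated, both R unphosphorylated -> 100
  st <- integer(60)
  j <- which(nd$class == "S1")[1]
  st[lat$sol[j]] <- 1L
  expect_identical(neighbour_state(g, st, j), list(class = "S1", state = "100"))
  # R3: pooled sorted key, 4 possible values
  k <- which(nd$class == "R3")[1]
  nbr <- c(lat$sol[k], lat$p1[k], lat$p2[k])
  for (non in 0:3) {
    st <- integer(60)
    if (non > 0) st[nbr[seq_len(non)]] <- 1L
    expect_identical(neighbour_state(g, st, k)$state,
                     paste(c(rep(1, non), rep(0, 3 - non)), collapse = ""))
  }
  expect_error(neighbour_state(g, integer(60), 0), "unknown node")
})

test_that("every key reachable on the canonical graph is in the table", {
  g <- canonical_graph
  tab <- allosteric_table("product_activation")
  set.seed(42)
  for (rep in 1:20) {
    st <- as.integer(stats::runif(60) < 0.5)
    for (i in 1:60) {
      ns <- neighbour_state(g, st, i)
      expect_no_error(allosteric_parameter(tab, ns$class, ns$state))
    }
  }
})

test_that("reaction probabilities combine p_a with the schedule rates", {
  rates <- rate_params()
  # stressed R2 with p_a = 1 reaches probability 1
  sched <- stress_schedule(c(0.1, 1), c(0, 10))
  expect_equal(phosphorylation_probability("R", 1, rates, sched, t = 12), 1)
  # pre-stress R3: 0.7 * 0.1
  expect_equal(phosphorylation_probability("R", 0.7, rates, sched, t = 5),
               0.07)
  expect_equal(phosphorylation_probability("R", 0, rates), 0)
  expect_equal(phosphorylation_probability("S", 1, rates), 0.4)
  # dephosphorylation is neighbour-independent
  expect_equal(dephosphorylation_probability("R", rates), 0.06)
  expect_equal(dephosphorylation_probability("S", rates), 1)
  expect_equal(dephosphorylation_probability("S", rate_params(kdps = 0.6)),
               0.6)
  expect_error(rate_params(kphr = 1.5), "probability")
})

test_that("allosteric tables round-trip through CSV and accept overrides", {
  tab <- allosteric_table("substrate_activation")
  path <- withr::local_tempfile(fileext = ".csv")
  write_allosteric_csv(tab, path)
  tab2 <- read_allosteric_csv(path)
  expect_equal(tab2$entries$pa[order(tab2$entries$class, tab2$entries$state)],
               tab$entries$pa[order(tab$entries$class, tab$entries$state)])
  # reduced-cooperativity variant built on the product-activation base
  mut <- custom_allosteric_table(
    data.frame(class = "R2", state = "011", pa = 0.5),
    model = "reduced_cooperativity",
    base = allosteric_table("product_activation")
  )
  expect_equal(allosteric_parameter(mut, "R2", "011"), 0.5)
  expect_equal(allosteric_parameter(mut, "R2", "010"), 1)
  expect_error(custom_allosteric_table(
    data.frame(class = "R2", state = "012", pa = 0.5),
    base = allosteric_table("product_activation")), "unknown")
  # uniform table covers all 22 keys
  expect_equal(nrow(uniform_allosteric_table(1)$entries), 22)
})
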