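test_that("truncated icosahedron has the polyhedral identity", {
  g <- build_truncated_icosahedron()
  expect_equal(nrow(g$nodes), 60)
  expect_equal(nrow(g$dimer_edges), 30)
  expect_equal(nrow(g$contact_edges), 60)
  # 3-regular: one dimer + two distinct contacts per node
  nbrs <- cbind(g$nodes$dimer, g$nodes$contact1, g$nodes$contact2)
  expect_true(all(apply(nbrs, 1, function(x) length(unique(x)) == 3)))
  expect_false(any(nbrs == g$nodes$id))
  # contact edges decompose into exactly 12 pentagons
  pent <- contact_pentagons(g)
  expect_length(pent, 12)
  expect_true(all(lengths(pent) == 5))
  expect_setequal(unlist(pent), 1:60)
  # construction is deterministic
  g2 <- build_truncated_icosahedron()
  expect_identical(g$nodes, g2$nodes)
})

test_that("species assignment obeys the assembly rules", {
  g <- canonical_graph
  expect_equal(sum(g$nodes$species == "R"), 40)
  expect_equal(sum(g$nodes$species == "S"), 20)
  # homotypic dimers: 20 R-R and 10 S-S
  de <- g$dimer_edges
  sp <- g$nodes$species
  expect_true(all(sp[de[, 1]] == sp[de[, 2]]))
  expect_equal(sum(sp[de[, 1]] == "S"), 10)
  # no S-S contact edge
  ce <- g$contact_edges
  expect_false(any(sp[ce[, 1]] == "S" & sp[ce[, 2]] == "S"))
  expect_no_error(validate_stressosome_graph(g))
  # deterministic colouring
  expect_identical(g$nodes, assign_species(build_truncated_icosahedron())$nodes)
})

test_that("neighbourhood classification matches the species multisets", {
  g <- canonical_graph
  nd <- g$nodes
  for (i in c(which(nd$class == "R1")[1], which(nd$class == "R2")[1],
              which(nd$class == "R3")[1], which(nd$class == "S1")[1])) {
    nbr_sp <- nd$species[c(nd$dimer[i], nd$contact1[i], nd$contact2[i])]
    want <- if (nd$species[i] == "S") "S1"
            else c("R3", "R2", "R1")[sum(nbr_sp == "S") + 1]
    expect_identical(classify_neighbourhood(g, i), want)
  }
  # every S node is S1; R2 is non-empty (the published example node is R2)
  expect_true(all(nd$class[nd$species == "S"] == "S1"))
  expect_gt(sum(nd$class == "R2"), 0)
  expect_error(classify_neighbourhood(build_truncated_icosahedron(), 1),
               "uncoloured")
  expect_error(classify_neighbourhood(g, 99), "unknown node")
})

test_that("neighbourhood census satisfies the contact-edge accounting", {
  g <- canonical_graph
  cen <- neighbourhood_census(g)
  expect_equal(sum(cen), 60)
  expect_equal(unname(cen["S1"]), 20L)
  expect_equal(unname(cen["R1"] + cen["R2"] + cen["R3"]), 40L)
  # each S has two R contacts: oracle = direct count of S-R contact ends
  ce <- g$contact_edges
  sp <- g$nodes$species
  sr_ends <- sum(sp[ce[, 1]] == "S") + sum(sp[ce[, 2]] == "S")
  expect_equal(unname(2L * cen["R1"] + cen["R2"]), sr_ends)
  # brute-force census via per-node classification
  brute <- table(vapply(1:60, function(i) classify_neighbourhood(g, i),
                        character(1)))
  expect_equal(as.integer(brute[names(cen)]), unname(as.integer(cen)))
})

test_that("all colourings are valid and form two census families", {
  g0 <- build_truncated_icosahedron()
  sols <- enumerate_colourings(g0)
  expect_gt(length(sols), 0)
  nd <- g0$nodes
  censuses <- t(vapply(sols, function(sp) {
    expect_equal(sum(sp == "S"), 20)
    # homotypic + no S-S contact in every solution
    expect_true(all(sp[g0$dimer_edges[, 1]] == sp[g0$dimer_edges[, 2]]))
    expect_false(any(sp[g0$contact_edges[, 1]] == "S" &
                     sp[g0$contact_edges[, 2]] == "S"))
    cls <- vapply(1:60, function(i) {
      nbr <- c(nd$dimer[i], nd$contact1[i], nd$contact2[i])
      if (sp[i] == "S") "S1" else c("R3", "R2", "R1")[sum(sp[nbr] == "S") + 1]
    }, character(1))
    c(R1 = sum(cls == "R1"), R2 = sum(cls == "R2"), R3 = sum(cls == "R3"))
  }, c(R1 = 0, R2 = 0, R3 = 0)))
  # 2 R1 + R2 = 40 holds in every solution; the census itself is NOT
  # unique: the assembly rules admit two structural families
  expect_true(all(2 * censuses[, "R1"] + censuses[, "R2"] == 40))
  fams <- unique(censuses)
  expect_equal(nrow(fams), 2)
  expect_setequal(fams[, "R1"], c(8, 10))
  # the canonical choice is the percolating (R1 = 8) family
  expect_equal(unname(neighbourhood_census(canonical_graph)["R1"]), 8L)
})

test_that("graph CSV export/import round-trips", {
  stem <- file.path(withr::local_tempdir(), "lattice")
  write_graph_csv(canonical_graph, stem)
  g2 <- read_graph_csv(stem)
  expect_identical(g2$nodes$species, canonical_graph$nodes$species)
  expect_identical(g2$nodes$class, canonical_graph$nodes$class)
  expect_identical(g2$nodes$dimer, canonical_graph$nodes$dimer)
  expect_identical(paste(pmin(g2$nodes$contact1, g2$nodes$contact2),
                         pmax(g2$nodes$contact1, g2$nodes$contact2)),
                   paste(pmin(canonical_graph$nodes$contact1,
                              canonical_graph$nodes$contact2),
                         pmax(canonical_graph$nodes$contact1,
                              canonical_graph$nodes$contact2)))
  expect_no_error(validate_stressosome_graph(g2))
})
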