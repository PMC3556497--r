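#' Construct the bare truncated-icosahedron lattice
#'
#' Builds the 60-node, 3-regular graph underlying the stressosome core: a
#' truncated icosahedron in which every protein has one homodimer partner
#' (dimer edge) and two inter-dimer contacts (contact edges). Species are
#' left unassigned; see [assign_species()].
#'
#' The construction uses the directed edges of a regular icosahedron: each
#' of the 30 icosahedron edges yields two directed edges, one per
#' orientation, and each directed edge becomes one protein node. The two
#' orientations of an edge form a dimer pair, and the five directed edges
#' leaving a common icosahedron vertex are joined into a contact pentagon
#' in cyclic (angular) order around that vertex. This reproduces the
#' truncated icosahedron's 12 pentagons (all-contact) and 20 hexagons
#' (alternating dimer/contact) deterministically, with a fixed canonical
#' node numbering.
#'
#' @return An object of class `c("stressosome_graph", "ca_lattice")`: a list
#'   with `nodes` (data frame: `id`, `species`, `class`, `dimer`,
#'   `contact1`, `contact2`), `dimer_edges` (30 x 2 matrix) and
#'   `contact_edges` (60 x 2 matrix). `species` and `class` are `NA` until
#'   [assign_species()] is applied.
#' @seealso [stressosome_graph()] for the fully assembled, coloured lattice.
#' @export
#' @examples
#' g <- build_truncated_icosahedron()
#' nrow(g$nodes)            # 60
#' nrow(g$dimer_edges)      # 30
build_truncated_icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
    c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(phi, 0, -1), c(-phi, 0, 1), c(-phi, 0, -1)
  )
  d2 <- as.matrix(stats::dist(v))^2
  adj <- d2 > 3.9 & d2 < 4.1  # icosahedron edge length^2 = 4 at this scale

  # cyclic order of the 5 neighbours around each vertex
  ord_nbrs <- function(u) {
    nb <- which(adj[u, ])
    uhat <- v[u, ] / sqrt(sum(v[u, ]^2))
    ref <- v[nb[1], ] - sum(v[nb[1], ] * uhat) * uhat
    e1 <- ref / sqrt(sum(ref^2))
    e2 <- c(
      uhat[2] * e1[3] - uhat[3] * e1[2],
      uhat[3] * e1[1] - uhat[1] * e1[3],
      uhat[1] * e1[2] - uhat[2] * e1[1]
    )
    ang <- vapply(nb, function(w) {
      p <- v[w, ] - sum(v[w, ] * uhat) * uhat
      atan2(sum(p * e2), sum(p * e1))
    }, numeric(1))
    nb[order(ang, nb)]
  }

  # node (u, k): k-th out-edge of icosahedron vertex u in cyclic order
  out <- t(vapply(1:12, ord_nbrs, integer(5)))
  node_id <- matrix(0L, 12, 12)  # node_id[u, w] = id of directed edge u -> w
  id <- 0L
  for (u in 1:12) for (k in 1:5) {
    id <- id + 1L
    node_id[u, out[u, k]] <- id
  }

  n <- 60L
  dimer <- integer(n)
  contact1 <- integer(n)
  contact2 <- integer(n)
  for (u in 1:12) for (k in 1:5) {
    i <- node_id[u, out[u, k]]
    dimer[i] <- node_id[out[u, k], u]
    contact1[i] <- node_id[u, out[u, if (k == 1) 5 else k - 1]]
    contact2[i] <- node_id[u, out[u, if (k == 5) 1 else k + 1]]
  }

  dim_e <- t(vapply(which(seq_len(n) < dimer), function(i) c(i, dimer[i]),
                    integer(2)))
  con_e <- unique(t(apply(cbind(rep(seq_len(n), 2), c(contact1, contact2)),
                          1, sort)))
  con_e <- con_e[order(con_e[, 1], con_e[, 2]), , drop = FALSE]

  g <- list(
    nodes = data.frame(
      id = seq_len(n),
      species = NA_character_,
      class = NA_character_,
      dimer = dimer, contact1 = contact1, contact2 = contact2,
      stringsAsFactors = FALSE
    ),
    dimer_edges = dim_e,
    contact_edges = con_e
  )
  class(g) <- c("stressosome_graph", "ca_lattice")
  g
}

#' Assign RsbR/RsbS species to the bare lattice
#'
#' Colours the 60 nodes with 40 RsbR (`"R"`) and 20 RsbS (`"S"`) under the
#' assembly rules: dimer edges are homotypic (whole dimers are R-R or S-S)
#' and RsbS homodimers never touch each other, i.e. no contact edge may
#' join two S nodes. All colourings are found by exhaustive backtracking
#' over the 30 dimer pairs in canonical order (R before S).
#'
#' The assembly rules alone do not pin the structure down to one graph:
#' the solutions fall into two families that are not related by a
#' symmetry of the lattice. In one family every class-R2 RsbR (one RsbS
#' neighbour) has only R2 proteins as its RsbR neighbours, so the R2
#' population forms a closed sub-network that is kinetically isolated
#' from R1 and R3 — under neighbour-activated kinase rules it can freeze
#' in the fully dephosphorylated state, which no observed stressosome
#' behaviour shows. We therefore take the other, percolating family (also
#' the generic one: 30 of the 36 solutions), in which RsbR activity can
#' propagate between all neighbourhood classes, and return its
#' lexicographically first member, so repeated calls give the identical
#' assembly. Neighbourhood classes are filled in afterwards (see
#' [classify_neighbourhood()]).
#'
#' @param graph Uncoloured lattice from [build_truncated_icosahedron()].
#' @return The coloured graph, with `nodes$species` and `nodes$class` set.
#' @export
assign_species <- function(graph) {
  stopifnot(inherits(graph, "stressosome_graph"))
  sols <- enumerate_colourings(graph)
  keep <- !vapply(sols, function(sp) r2_isolated(graph, sp), logical(1))
  if (!any(keep)) {
    stop("no species assignment satisfies the stressosome assembly rules")
  }
  sp <- sols[[which(keep)[1]]]
  nd <- graph$nodes
  graph$nodes$species <- sp
  graph$nodes$class <- vapply(seq_len(nrow(nd)), function(i) {
    classify_node(sp[i], sp[c(nd$dimer[i], nd$contact1[i], nd$contact2[i])])
  }, character(1))
  graph
}

#' Enumerate all species colourings allowed by the assembly rules
#'
#' Exhaustive backtracking over the dimer pairs in canonical order (by
#' smaller node id, trying R before S), yielding every assignment with
#' the 2:1 RsbR:RsbS stoichiometry, homotypic dimers and no S-S contact,
#' in lexicographic order.
#'
#' @param graph Uncoloured (or coloured) `stressosome_graph`.
#' @return List of character vectors of `"R"`/`"S"`, one per node.
#' @export
enumerate_colourings <- function(graph) {
  stopifnot(inherits(graph, "stressosome_graph"))
  nd <- graph$nodes
  n <- nrow(nd)
  dm <- graph$dimer_edges
  dm <- dm[order(dm[, 1]), , drop = FALSE]
  ndim <- nrow(dm)
  dimer_of <- integer(n)
  for (d in seq_len(ndim)) dimer_of[dm[d, ]] <- d

  n_s_target <- ndim / 3  # one S-S dimer per three dimers (10 of 30)
  col <- rep(NA, ndim)    # TRUE = S dimer
  sols <- list()

  ok_S <- function(d) {
    # an S dimer may not contact another S dimer
    nodes_d <- dm[d, ]
    cn <- c(nd$contact1[nodes_d], nd$contact2[nodes_d])
    !any(col[dimer_of[cn]] %in% TRUE)
  }
  emit <- function() {
    sp <- rep("R", n)
    for (d in which(col)) sp[dm[d, ]] <- "S"
    sols[[length(sols) + 1]] <<- sp
  }
  recurse <- function(d, n_s) {
    if (n_s > n_s_target || ndim - d + 1 < n_s_target - n_s) return(invisible())
    if (d > ndim) {
      if (n_s == n_s_target) emit()
      return(invisible())
    }
    for (s in c(FALSE, TRUE)) {  # R first: lexicographic order
      if (s && !ok_S(d)) next
      col[d] <<- s
      recurse(d + 1, n_s + s)
      col[d] <<- NA
    }
  }
  recurse(1L, 0L)
  sols
}

# TRUE if, under colouring sp, the R2 nodes' RsbR neighbours are all R2
# (the kinetically isolated colouring family)
r2_isolated <- function(graph, sp) {
  nd <- graph$nodes
  cls <- vapply(seq_len(nrow(nd)), function(i) {
    classify_node(sp[i], sp[c(nd$dimer[i], nd$contact1[i], nd$contact2[i])])
  }, character(1))
  r2 <- which(cls == "R2")
  for (i in r2) {
    nbr <- c(nd$dimer[i], nd$contact1[i], nd$contact2[i])
    rn <- nbr[sp[nbr] == "R"]
    if (any(cls[rn] != "R2")) return(FALSE)
  }
  TRUE
}

# class from central species and neighbour species vector
classify_node <- function(central, nbr_species) {
  if (central == "S") return("S1")
  switch(as.character(sum(nbr_species == "S")),
         "2" = "R1", "1" = "R2", "0" = "R3",
         stop("R node with three S neighbours cannot occur in a valid lattice"))
}

.lattice_cache <- new.env(parent = emptyenv())

#' Build the canonical coloured stressosome lattice
#'
#' Convenience wrapper: [build_truncated_icosahedron()] followed by
#' [assign_species()]. The construction is deterministic, so the result
#' is memoised within the session.
#'
#' @return A coloured `stressosome_graph`.
#' @export
#' @examples
#' g <- stressosome_graph()
#' table(g$nodes$species)  # 40 R, 20 S
stressosome_graph <- function() {
  if (is.null(.lattice_cache$graph)) {
    .lattice_cache$graph <- assign_species(build_truncated_icosahedron())
  }
  .lattice_cache$graph
}

#' Neighbourhood class of a node
#'
#' Each protein sits at the centre of a triangle formed by its three
#' neighbours. The class is determined by the species composition of that
#' triangle: `R1` = central R with neighbours (R, S, S), `R2` = central R
#' with (S, R, R), `R3` = central R with (R, R, R), `S1` = central S
#' (always with (S, R, R) in a valid assembly).
#'
#' @param graph Coloured `stressosome_graph`.
#' @param node Node id (1..60).
#' @return One of `"R1"`, `"R2"`, `"R3"`, `"S1"`.
#' @export
classify_neighbourhood <- function(graph, node) {
  nd <- graph$nodes
  if (anyNA(nd$species)) stop("graph is uncoloured; call assign_species() first")
  if (!node %in% nd$id) stop("unknown node id: ", node)
  i <- match(node, nd$id)
  classify_node(nd$species[i],
                nd$species[match(c(nd$dimer[i], nd$contact1[i], nd$contact2[i]),
                                 nd$id)])
}

#' Census of neighbourhood classes
#'
#' @param graph Coloured `stressosome_graph`.
#' @return Named integer vector of counts over `R1`, `R2`, `R3`, `S1`.
#' @export
neighbourhood_census <- function(graph) {
  nd <- graph$nodes
  if (anyNA(nd$class)) stop("graph is uncoloured; call assign_species() first")
  out <- c(R1 = 0L, R2 = 0L, R3 = 0L, S1 = 0L)
  tb <- table(nd$class)
  out[names(tb)] <- as.integer(tb)
  out
}

#' Decompose the contact edges into pentagons
#'
#' The contact edges of a valid lattice form 12 disjoint 5-cycles, the
#' pentagonal faces of the truncated icosahedron. Used for structural
#' validation.
#'
#' @param graph A `stressosome_graph` (coloured or not).
#' @return List of integer vectors, each a cycle of node ids.
#' @export
contact_pentagons <- function(graph) {
  nd <- graph$nodes
  seen <- logical(nrow(nd))
  cycles <- list()
  for (start in nd$id) {
    if (seen[start]) next
    cyc <- start
    seen[start] <- TRUE
    prev <- NA_integer_
    cur <- start
    repeat {
      nxt <- setdiff(c(nd$contact1[cur], nd$contact2[cur]), prev)[1]
      if (nxt == start) break
      cyc <- c(cyc, nxt)
      seen[nxt] <- TRUE
      prev <- cur
      cur <- nxt
    }
    cycles[[length(cycles) + 1]] <- cyc
  }
  cycles
}

#' Validate the structural invariants of a stressosome lattice
#'
#' Checks the polyhedral identity (60 nodes, 30 dimer + 60 contact edges,
#' 3-regularity, connectivity, 12 contact pentagons) and, if coloured, the
#' assembly rules (40 R / 20 S, homotypic dimers, no S-S contact).
#'
#' @param graph A `stressosome_graph`.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_stressosome_graph <- function(graph) {
  nd <- graph$nodes
  n <- nrow(nd)
  if (n != 60) stop("expected 60 nodes, found ", n)
  if (nrow(graph$dimer_edges) != 30) stop("expected 30 dimer edges")
  if (nrow(graph$contact_edges) != 60) stop("expected 60 contact edges")
  nbrs <- cbind(nd$dimer, nd$contact1, nd$contact2)
  if (any(apply(nbrs, 1, function(x) length(unique(x)) != 3)) ||
      any(nbrs == nd$id)) {
    stop("every node must have 3 distinct neighbours")
  }
  # symmetry
  for (i in seq_len(n)) {
    if (nd$dimer[nd$dimer[i]] != i) stop("dimer pairing is not symmetric")
    for (cj in c(nd$contact1[i], nd$contact2[i])) {
      if (!i %in% c(nd$contact1[cj], nd$contact2[cj])) {
        stop("contact edges are not symmetric")
      }
    }
  }
  # connectivity (BFS over all edges)
  reach <- logical(n)
  reach[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- unique(as.vector(nbrs[frontier, ]))
    frontier <- nxt[!reach[nxt]]
    reach[frontier] <- TRUE
  }
  if (!all(reach)) stop("lattice is not connected")
  pent <- contact_pentagons(graph)
  if (length(pent) != 12 || !all(lengths(pent) == 5)) {
    stop("contact edges must form 12 pentagons")
  }
  if (!anyNA(nd$species)) {
    if (sum(nd$species == "R") != 40 || sum(nd$species == "S") != 20) {
      stop("expected 40 RsbR and 20 RsbS nodes")
    }
    if (any(nd$species != nd$species[nd$dimer])) {
      stop("dimer edges must be homotypic")
    }
    ce <- graph$contact_edges
    if (any(nd$species[ce[, 1]] == "S" & nd$species[ce[, 2]] == "S")) {
      stop("RsbS homodimers must not contact each other")
    }
  }
  invisible(TRUE)
}

#' @export
print.stressosome_graph <- function(x, ...) {
  nd <- x$nodes
  cat("Stressosome lattice: ", nrow(nd), " nodes, ",
      nrow(x$dimer_edges), " dimer + ", nrow(x$contact_edges),
      " contact edges\n", sep = "")
  if (!anyNA(nd$species)) {
    cat("  species: ", sum(nd$species == "R"), " RsbR / ",
        sum(nd$species == "S"), " RsbS\n", sep = "")
    cen <- neighbourhood_census(x)
    cat("  classes: ", paste(names(cen), cen, sep = "=", collapse = ", "),
        "\n", sep = "")
  } else {
    cat("  species unassigned (call assign_species())\n")
  }
  invisible(x)
}

#' Export a lattice to edge-list and node-table CSV files
#'
#' Writes `<stem>_edges.csv` with columns `node_a`, `node_b`, `edge_type`
#' (`dimer` or `contact`) and `<stem>_nodes.csv` with columns `id`,
#' `species`, `class`.
#'
#' @param graph A `stressosome_graph`.
#' @param stem File path stem (without the `_edges.csv` suffix).
#' @return Invisibly, the two file paths.
#' @export
write_graph_csv <- function(graph, stem) {
  edges <- rbind(
    data.frame(node_a = graph$dimer_edges[, 1],
               node_b = graph$dimer_edges[, 2], edge_type = "dimer"),
    data.frame(node_a = graph$contact_edges[, 1],
               node_b = graph$contact_edges[, 2], edge_type = "contact")
  )
  ep <- paste0(stem, "_edges.csv")
  np <- paste0(stem, "_nodes.csv")
  utils::write.csv(edges, ep, row.names = FALSE, quote = FALSE)
  utils::write.csv(graph$nodes[, c("id", "species", "class")], np,
                   row.names = FALSE, quote = FALSE)
  invisible(c(edges = ep, nodes = np))
}

#' Import a lattice from CSV files written by [write_graph_csv()]
#'
#' @param stem File path stem used at export time.
#' @return A `stressosome_graph`.
#' @export
read_graph_csv <- function(stem) {
  edges <- utils::read.csv(paste0(stem, "_edges.csv"),
                           stringsAsFactors = FALSE)
  nodes <- utils::read.csv(paste0(stem, "_nodes.csv"),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("node_a", "node_b", "edge_type") %in% names(edges)),
            all(c("id", "species", "class") %in% names(nodes)))
  n <- nrow(nodes)
  dimer <- integer(n)
  contact <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges$node_a[k]; b <- edges$node_b[k]
    if (edges$edge_type[k] == "dimer") {
      dimer[a] <- b; dimer[b] <- a
    } else {
      contact[[a]] <- c(contact[[a]], b)
      contact[[b]] <- c(contact[[b]], a)
    }
  }
  contact <- lapply(contact, sort)
  g <- list(
    nodes = data.frame(
      id = nodes$id, species = nodes$species, class = nodes$class,
      dimer = dimer,
      contact1 = vapply(contact, `[`, integer(1), 1),
      contact2 = vapply(contact, `[`, integer(1), 2),
      stringsAsFactors = FALSE
    ),
    dimer_edges = {
      de <- edges[edges$edge_type == "dimer", c("node_a", "node_b")]
      unname(as.matrix(de))
    },
    contact_edges = {
      ce <- edges[edges$edge_type == "contact", c("node_a", "node_b")]
      unname(as.matrix(ce))
    }
  )
  class(g) <- c("stressosome_graph", "ca_lattice")
  g
}
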