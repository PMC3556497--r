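#' Reaction probabilities for the stressosome automaton
#'
#' Per-step probabilities of the four reactions: phosphorylation of RsbR
#' (`kphr`, the stress input: 0.1 stress-free, 1 under full stress),
#' dephosphorylation of RsbR-P (`kdpr`), phosphorylation of RsbS (`kphs`)
#' and dephosphorylation of RsbS-P (`kdps`, the RsbX phosphatase
#' activity). Defaults are the published reference values.
#'
#' @param kphr,kdpr,kphs,kdps Probabilities in `[0, 1]`.
#' @return An object of class `rate_params`.
#' @export
#' @examples
#' rate_params()                 # stress-free defaults
#' rate_params(kdps = 0.6)       # reduced RsbX phosphatase
rate_params <- function(kphr = 0.1, kdpr = 0.06, kphs = 0.4, kdps = 1) {
  p <- list(kphr = kphr, kdpr = kdpr, kphs = kphs, kdps = kdps)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(nm, " must be a single probability in [0, 1]")
    }
  }
  structure(p, class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Reaction probabilities per step:\n")
  cat(sprintf("  kphr = %g  (RsbR phosphorylation maximum)\n", x$kphr))
  cat(sprintf("  kdpr = %g  (RsbR-P dephosphorylation)\n", x$kdpr))
  cat(sprintf("  kphs = %g  (RsbS phosphorylation maximum)\n", x$kphs))
  cat(sprintf("  kdps = %g  (RsbS-P dephosphorylation)\n", x$kdps))
  invisible(x)
}

# canonical neighbour-state keys: first character = solitary neighbour's
# bit, then the same-species pair sorted descending (matching the
# published truth-table column order); R3 pools all three bits.
.state_keys <- c("000", "010", "011", "100", "110", "111")
.state_keys_r3 <- c("000", "100", "110", "111")

.model_names <- c("no_cooperation", "substrate_activation",
                  "product_activation")

#' Allosteric-parameter truth table for an interaction model
#'
#' Returns the full map from (neighbourhood class, canonical neighbour
#' phosphorylation state) to the allosteric parameter `p_a` in `[0, 1]`,
#' the multiplier on the maximum phosphorylation probability that encodes
#' how a triangle's phosphorylation pattern stimulates the RsbT kinase.
#'
#' All three models share the general rows: `S1` is active (`p_a = 1`)
#' only when its two RsbR contacts are phosphorylated and its RsbS dimer
#' partner is not (state `"011"`); `R3`, which has no adjacent RsbT, is a
#' constant 0.7 regardless of neighbours. The models differ on `R1` and
#' `R2`: `no_cooperation` sets every entry to 1 (neighbour-independent
#' kinase activity); `substrate_activation` increases `p_a` with the
#' number of *un*phosphorylated RsbR neighbours; `product_activation`
#' increases it with the number of *phosphorylated* RsbR neighbours. In
#' the latter two models a phosphorylated RsbS neighbour of R2 forces
#' `p_a = 0` (its RsbT has dissociated).
#'
#' There are exactly 22 keys: 6 each for R1, R2 and S1, and 4 for R3
#' (whose three same-species neighbour bits are pooled).
#'
#' @param model One of `"product_activation"`, `"substrate_activation"`,
#'   `"no_cooperation"`.
#' @return An object of class `allosteric_table`: list with `model` and
#'   `entries`, a data frame with columns `class`, `state`, `pa`.
#' @export
#' @examples
#' tab <- allosteric_table("product_activation")
#' allosteric_parameter(tab, "R2", "011")  # 1: both RsbR neighbours active
allosteric_table <- function(model = .model_names) {
  model <- match.arg(model)
  general <- rbind(
    data.frame(class = "R3", state = .state_keys_r3, pa = 0.7),
    data.frame(class = "S1", state = .state_keys,
               pa = as.numeric(.state_keys == "011"))
  )
  r12 <- switch(model,
    no_cooperation = rbind(
      data.frame(class = "R1", state = .state_keys, pa = 1),
      data.frame(class = "R2", state = .state_keys, pa = 1)
    ),
    substrate_activation = rbind(
      data.frame(class = "R1", state = .state_keys,
                 pa = c(0.7, 0.7, 0, 0.5, 0.5, 0)),
      data.frame(class = "R2", state = .state_keys,
                 pa = c(1, 0.7, 0.5, 0, 0, 0))
    ),
    product_activation = rbind(
      data.frame(class = "R1", state = .state_keys,
                 pa = c(0, 1, 0, 1, 1, 0)),
      data.frame(class = "R2", state = .state_keys,
                 pa = c(0, 1, 1, 0, 0, 0))
    )
  )
  structure(list(model = model, entries = rbind(r12, general)),
            class = "allosteric_table")
}

#' Uniform allosteric table
#'
#' All 22 (class, state) entries set to a single value; with `value = 1`
#' this removes every neighbour dependence from phosphorylation, giving
#' independent two-state dynamics per node (useful as an analytic control:
#' the stationary phosphorylation is then `kph / (kph + kdp)`).
#'
#' @param value Allosteric parameter in `[0, 1]` for every entry.
#' @param model Label stored on the table.
#' @return An `allosteric_table`.
#' @export
uniform_allosteric_table <- function(value = 1, model = "uniform") {
  stopifnot(is.numeric(value), length(value) == 1, value >= 0, value <= 1)
  entries <- rbind(
    data.frame(class = rep(c("R1", "R2", "S1"), each = 6),
               state = rep(.state_keys, 3), pa = value),
    data.frame(class = "R3", state = .state_keys_r3, pa = value)
  )
  structure(list(model = model, entries = entries),
            class = "allosteric_table")
}

#' Build a custom allosteric table from a (class, state, pa) data frame
#'
#' Lets users express mutant phenotypes (e.g. reduced cooperativity of an
#' RsbR paralogue) by overriding individual rows of a base table. All 22
#' canonical keys must be present after the override.
#'
#' @param entries Data frame with columns `class`, `state`, `pa`.
#' @param model Label for the table.
#' @param base Optional `allosteric_table` whose entries are the starting
#'   point; rows in `entries` replace matching (class, state) rows.
#' @return An `allosteric_table`.
#' @export
custom_allosteric_table <- function(entries, model = "custom", base = NULL) {
  stopifnot(all(c("class", "state", "pa") %in% names(entries)))
  if (!is.null(base)) {
    stopifnot(inherits(base, "allosteric_table"))
    e <- base$entries
    key <- paste(e$class, e$state)
    for (k in seq_len(nrow(entries))) {
      i <- match(paste(entries$class[k], entries$state[k]), key)
      if (is.na(i)) stop("unknown (class, state) key: ",
                         entries$class[k], " ", entries$state[k])
      e$pa[i] <- entries$pa[k]
    }
    entries <- e
  }
  want <- c(paste("R1", .state_keys), paste("R2", .state_keys),
            paste("S1", .state_keys), paste("R3", .state_keys_r3))
  have <- paste(entries$class, entries$state)
  if (!setequal(want, have) || anyDuplicated(have)) {
    stop("entries must cover the 22 canonical (class, state) keys exactly once")
  }
  if (any(entries$pa < 0 | entries$pa > 1)) stop("pa values must be in [0, 1]")
  structure(list(model = model, entries = entries),
            class = "allosteric_table")
}

#' @export
print.allosteric_table <- function(x, ...) {
  cat("Allosteric parameters (model: ", x$model, ")\n", sep = "")
  for (cl in c("R1", "R2", "R3", "S1")) {
    e <- x$entries[x$entries$class == cl, ]
    cat(sprintf("  %s: %s\n", cl,
                paste(e$state, e$pa, sep = "=", collapse = "  ")))
  }
  invisible(x)
}

#' Look up an allosteric parameter
#'
#' @param table An `allosteric_table`.
#' @param class Neighbourhood class (`"R1"`, `"R2"`, `"R3"`, `"S1"`).
#' @param state Canonical neighbour-state string (see
#'   [neighbour_state()]).
#' @return `p_a` in `[0, 1]`. Errors on a key not in the table, which
#'   signals a neighbourhood impossible on a valid lattice.
#' @export
allosteric_parameter <- function(table, class, state) {
  stopifnot(inherits(table, "allosteric_table"))
  i <- which(table$entries$class == class & table$entries$state == state)
  if (length(i) != 1) {
    stop("no allosteric entry for class ", class, ", state ", state)
  }
  table$entries$pa[i]
}

#' Canonical neighbour phosphorylation state of a node
#'
#' Builds the truth-table key for a node given the current 0/1
#' phosphorylation vector: the first character is the bit of the solitary
#' neighbour (the one whose species occurs once in the triangle: the R
#' dimer partner for R1, the RsbS contact for R2, the RsbS dimer partner
#' for S1), followed by the same-species pair's bits sorted descending.
#' For R3, whose neighbours are all RsbR, the three bits are pooled and
#' sorted descending, giving 4 possible keys.
#'
#' @param graph Coloured `stressosome_graph` (or any `ca_lattice`).
#' @param state_vector Integer 0/1 vector indexed by node id.
#' @param node Node id.
#' @return List with elements `class` and `state`.
#' @export
neighbour_state <- function(graph, state_vector, node) {
  lat <- as_ca_lattice(graph)
  n <- length(lat$species)
  if (!is.numeric(node) || length(node) != 1 || is.na(node) ||
      node < 1 || node > n) {
    stop("unknown node id: ", node)
  }
  stopifnot(length(state_vector) == n, all(state_vector %in% c(0, 1)))
  bit <- function(i) if (i > 0) state_vector[i] else 0L
  cl <- lat$class[node]
  if (cl == "R3") {
    bits <- sort(c(bit(lat$sol[node]), bit(lat$p1[node]), bit(lat$p2[node])),
                 decreasing = TRUE)
  } else {
    bits <- c(bit(lat$sol[node]),
              sort(c(bit(lat$p1[node]), bit(lat$p2[node])),
                   decreasing = TRUE))
  }
  list(class = cl, state = paste(bits, collapse = ""))
}

#' Per-step phosphorylation probability of an unphosphorylated node
#'
#' The allosteric parameter times the species' maximum phosphorylation
#' probability: `p_a * kphr(t)` for RsbR (with `kphr` read from the stress
#' schedule when one is given) and `p_a * kphs` for RsbS.
#'
#' @param species `"R"` or `"S"`.
#' @param p_a Allosteric parameter in `[0, 1]`.
#' @param rates A `rate_params`.
#' @param schedule Optional [stress_schedule()]; if supplied, `kphr` at
#'   minute `t` replaces `rates$kphr`.
#' @param t Time in minutes (used with `schedule`).
#' @return Probability in `[0, 1]`.
#' @export
phosphorylation_probability <- function(species, p_a, rates,
                                        schedule = NULL, t = 0) {
  stopifnot(species %in% c("R", "S"), p_a >= 0, p_a <= 1)
  kph <- if (species == "S") {
    rates$kphs
  } else if (is.null(schedule)) {
    rates$kphr
  } else {
    kphr_at(schedule, t)
  }
  p_a * kph
}

#' Per-step dephosphorylation probability of a phosphorylated node
#'
#' Neighbour-independent: `kdpr` for RsbR-P, `kdps` for RsbS-P.
#'
#' @inheritParams phosphorylation_probability
#' @return Probability in `[0, 1]`.
#' @export
dephosphorylation_probability <- function(species, rates) {
  stopifnot(species %in% c("R", "S"))
  if (species == "R") rates$kdpr else rates$kdps
}

#' Write an allosteric table to CSV
#'
#' Columns `model`, `class`, `state`, `pa`; readable back with
#' [read_allosteric_csv()], enabling user-defined model variants.
#'
#' @param table An `allosteric_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_allosteric_csv <- function(table, path) {
  df <- cbind(model = table$model, table$entries)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an allosteric table from CSV
#'
#' @param path File written by [write_allosteric_csv()] (or hand-edited
#'   with the same columns).
#' @return An `allosteric_table`.
#' @export
read_allosteric_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(state = "character"))
  custom_allosteric_table(df[, c("class", "state", "pa")],
                          model = as.character(df$model[1]))
}

# lower an allosteric table to the 4 x 6 matrix used by the C++ kernel:
# rows R1, R2, R3, S1; columns keyed by solitary_bit * 3 + pair bit sum
# (R3: pooled bit sum in columns 1..4)
as_pa_matrix <- function(table) {
  m <- matrix(NA_real_, 4, 6,
              dimnames = list(c("R1", "R2", "R3", "S1"), NULL))
  key6 <- function(s) {
    b <- as.integer(strsplit(s, "")[[1]])
    b[1] * 3 + b[2] + b[3] + 1
  }
  e <- table$entries
  for (k in seq_len(nrow(e))) {
    if (e$class[k] == "R3") {
      m["R3", sum(as.integer(strsplit(e$state[k], "")[[1]])) + 1] <- e$pa[k]
    } else {
      m[e$class[k], key6(e$state[k])] <- e$pa[k]
    }
  }
  if (anyNA(m[c("R1", "R2", "S1"), ]) || anyNA(m["R3", 1:4])) {
    stop("allosteric table is incomplete")
  }
  m["R3", 5:6] <- 0  # unreachable keys for the pooled class
  m
}
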