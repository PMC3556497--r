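#' Toy lattices for exact-oracle testing
#'
#' Small synthetic lattices on which the stochastic dynamics can be
#' verified against an exactly enumerated Markov chain (2^n joint
#' states, transition matrix averaged over all update permutations) —
#' infeasible on the 2^60 states of the real stressosome. These are not
#' stressosomes: absent neighbour slots contribute a fixed 0 bit.
#'
#' * `triangle`: 4 nodes — a central R2-class RsbR with its solitary
#'   RsbS neighbour and an RsbR pair; the outer nodes close over each
#'   other so every node updates.
#' * `ring6`: 6 nodes alternating R/S around a ring; R nodes are class
#'   R1 (two RsbS contacts, absent dimer slot), S nodes class S1. No
#'   S-S contact.
#' * `mini8`: 8 nodes (three R-R dimers + one S-S dimer) containing at
#'   least one node of each of the classes R1, R2, R3 and S1.
#'
#' @param kind `"triangle"`, `"ring6"` or `"mini8"`.
#' @return A [ca_lattice()].
#' @export
#' @examples
#' make_fixture("triangle")$class
make_fixture <- function(kind = c("triangle", "ring6", "mini8")) {
  kind <- match.arg(kind)
  switch(kind,
    triangle = ca_lattice(
      species = c("R", "S", "R", "R"),
      class   = c("R2", "S1", "R3", "R3"),
      sol = c(2, 0, 1, 1),
      p1  = c(3, 3, 2, 2),
      p2  = c(4, 4, 4, 3)
    ),
    ring6 = ca_lattice(
      # ring order 1(R) 2(S) 3(R) 4(S) 5(R) 6(S)
      species = c("R", "S", "R", "S", "R", "S"),
      class   = c("R1", "S1", "R1", "S1", "R1", "S1"),
      sol = c(0, 0, 0, 0, 0, 0),
      p1  = c(2, 1, 2, 3, 4, 5),
      p2  = c(6, 3, 4, 5, 6, 1)
    ),
    mini8 = ca_lattice(
      # dimers: (1,2) S-S, (3,4) (5,6) (7,8) R-R
      # contacts: 1-3 1-5 2-4 2-5 3-7 4-8 6-7 6-8
      species = c("S", "S", "R", "R", "R", "R", "R", "R"),
      class   = c("S1", "S1", "R2", "R2", "R1", "R3", "R3", "R3"),
      sol = c(2, 1, 1, 2, 6, 5, 8, 7),
      p1  = c(3, 4, 4, 3, 1, 7, 3, 4),
      p2  = c(5, 5, 7, 8, 2, 8, 6, 6)
    )
  )
}

#' Write a run manifest
#'
#' Records everything needed to reproduce an output set bit-identically:
#' the resolved configuration, master seed, package version, timestamp
#' and the produced files.
#'
#' @param path Manifest file path (JSON).
#' @param config A [sim_config()] (or any named list of settings).
#' @param files Character vector of output files produced by the run.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, config, files = character()) {
  cfg <- if (inherits(config, "sim_config")) {
    list(model = config$model,
         rates = unclass(config$rates)[c("kphr", "kdpr", "kphs", "kdps")],
         schedule = list(kphr = config$schedule$kphr,
                         at_min = config$schedule$at_min),
         n_steps = config$n_steps, n_replicates = config$n_replicates,
         seed = config$seed, p0 = config$p0, burn_in = config$burn_in,
         steps_per_min = config$steps_per_min,
         synchronous = config$synchronous,
         allosteric = config$table$entries)
  } else {
    config
  }
  jsonlite::write_json(
    list(package = "stressosim",
         version = as.character(utils::packageVersion("stressosim")),
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
         config = cfg, files = files),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a run manifest
#'
#' @param path Manifest JSON path.
#' @return Parsed manifest list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
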