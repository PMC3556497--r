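#' Minimal lattice interface for the update engine
#'
#' A `ca_lattice` is the engine-facing view of a lattice: per node its
#' species (`"R"`/`"S"`), neighbourhood class, and three neighbour slots
#' split into the solitary neighbour (`sol`) and the same-species pair
#' (`p1`, `p2`). A slot of `0` means "absent" and contributes a fixed 0
#' bit; the canonical stressosome has no absent slots, toy fixtures may.
#'
#' @param species Character vector of `"R"`/`"S"`.
#' @param class Character vector of classes `R1`/`R2`/`R3`/`S1`.
#' @param sol,p1,p2 Integer neighbour indices (0 = absent).
#' @return An object of class `ca_lattice`.
#' @export
ca_lattice <- function(species, class, sol, p1, p2) {
  n <- length(species)
  stopifnot(all(species %in% c("R", "S")),
            all(class %in% c("R1", "R2", "R3", "S1")),
            length(class) == n, length(sol) == n,
            length(p1) == n, length(p2) == n,
            all(c(sol, p1, p2) %in% 0:n))
  structure(list(species = species, class = class,
                 sol = as.integer(sol), p1 = as.integer(p1),
                 p2 = as.integer(p2)),
            class = "ca_lattice")
}

#' Coerce a lattice-like object to the engine interface
#'
#' For a `stressosome_graph` the solitary slot of each node is the
#' neighbour whose species occurs once in the triangle (R1: the R dimer
#' partner; R2 and S1: the RsbS neighbour); for R3 the split is
#' immaterial since its bits are pooled.
#'
#' @param x A `ca_lattice` or coloured `stressosome_graph`.
#' @return A `ca_lattice`.
#' @export
as_ca_lattice <- function(x) {
  if (inherits(x, "ca_lattice") && !inherits(x, "stressosome_graph")) {
    return(x)
  }
  stopifnot(inherits(x, "stressosome_graph"))
  nd <- x$nodes
  if (anyNA(nd$species)) stop("graph is uncoloured; call assign_species() first")
  n <- nrow(nd)
  sol <- integer(n); p1 <- integer(n); p2 <- integer(n)
  for (i in seq_len(n)) {
    nbr <- c(nd$dimer[i], nd$contact1[i], nd$contact2[i])
    sp <- nd$species[nbr]
    solitary <- which(sp == names(which(table(sp) == 1))[1])
    if (length(solitary) == 0) {  # R3 or (impossible) all-same S
      sol[i] <- nbr[1]; p1[i] <- nbr[2]; p2[i] <- nbr[3]
    } else {
      sol[i] <- nbr[solitary]
      pr <- nbr[-solitary]
      p1[i] <- pr[1]; p2[i] <- pr[2]
    }
  }
  ca_lattice(nd$species, nd$class, sol, p1, p2)
}

#' Piecewise-constant stress schedule for kphr
#'
#' Stress enters the model as the maximum RsbR phosphorylation
#' probability `kphr`: 0.1 stress-free, 1 under full stress. A schedule
#' is a step function of time in minutes; `kphr[i]` applies from
#' `at_min[i]` until the next change point.
#'
#' @param kphr Numeric vector of probabilities.
#' @param at_min Change points in minutes; must start at 0 and increase.
#' @return An object of class `stress_schedule`.
#' @export
#' @examples
#' stress_schedule(0.1)                        # constant stress-free
#' stress_schedule(c(0.1, 1, 0.1), c(0, 10, 15))  # 5-min stress pulse
stress_schedule <- function(kphr, at_min = 0) {
  stopifnot(is.numeric(kphr), is.numeric(at_min),
            length(kphr) == length(at_min), length(kphr) >= 1,
            all(kphr >= 0 & kphr <= 1),
            at_min[1] == 0, !is.unsorted(at_min, strictly = TRUE))
  structure(list(kphr = kphr, at_min = at_min), class = "stress_schedule")
}

#' kphr value of a schedule at a time point
#'
#' @param schedule A [stress_schedule()].
#' @param t_min Time in minutes (vectorised).
#' @return kphr value(s).
#' @export
kphr_at <- function(schedule, t_min) {
  stopifnot(inherits(schedule, "stress_schedule"))
  idx <- findInterval(t_min, schedule$at_min)
  schedule$kphr[pmax(idx, 1L)]
}

#' @export
print.stress_schedule <- function(x, ...) {
  cat("Stress schedule (kphr):\n")
  for (i in seq_along(x$kphr)) {
    cat(sprintf("  from %g min: kphr = %g\n", x$at_min[i], x$kphr[i]))
  }
  invisible(x)
}

is_constant_schedule <- function(schedule) length(unique(schedule$kphr)) == 1

# per-step kphr vector for recorded steps 1..n_steps (step s covers
# minutes [(s-1)/spm, s/spm); its kphr is the schedule value at its start)
expand_schedule <- function(schedule, n_steps, steps_per_min) {
  kphr_at(schedule, (seq_len(n_steps) - 1) / steps_per_min)
}

#' Simulation configuration
#'
#' Bundles everything a run needs: the interaction model, reaction
#' probabilities, stress schedule, horizon and ensemble settings. The
#' automaton evolves in discrete steps; `steps_per_min` converts schedule
#' minutes to steps (default 1 step = 1 minute). Before recording starts
#' the state is equilibrated for `burn_in` steps at the schedule's
#' initial kphr.
#'
#' @param model Interaction model name, or `NULL` when a custom `table`
#'   is supplied.
#' @param rates A [rate_params()].
#' @param schedule A [stress_schedule()].
#' @param n_steps Recorded steps after burn-in.
#' @param n_replicates Ensemble size (default 50).
#' @param seed Integer master seed; replicate seeds derive from it.
#' @param p0 Initial per-node phosphorylation probability (default 0.5).
#' @param burn_in Equilibration steps before recording (default 200).
#' @param steps_per_min Steps per simulated minute (default 1).
#' @param synchronous If `TRUE`, all updates in a step read the state
#'   frozen at the step's start instead of seeing earlier flips.
#' @param table Optional [allosteric_table()] overriding `model`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model = "product_activation",
                       rates = rate_params(),
                       schedule = stress_schedule(rates$kphr),
                       n_steps = 1000, n_replicates = 50, seed = 1,
                       p0 = 0.5, burn_in = 200, steps_per_min = 1,
                       synchronous = FALSE, table = NULL) {
  if (is.null(table)) {
    table <- allosteric_table(model)
  } else {
    stopifnot(inherits(table, "allosteric_table"))
    model <- table$model
  }
  stopifnot(inherits(rates, "rate_params"),
            inherits(schedule, "stress_schedule"),
            n_steps >= 0, n_replicates >= 1,
            p0 >= 0, p0 <= 1, burn_in >= 0, steps_per_min > 0)
  structure(list(model = model, table = table, rates = rates,
                 schedule = schedule, n_steps = as.integer(n_steps),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), p0 = p0,
                 burn_in = as.integer(burn_in),
                 steps_per_min = steps_per_min,
                 synchronous = isTRUE(synchronous)),
            class = "sim_config")
}

#' Random initial phosphorylation state
#'
#' Each node is phosphorylated independently with probability `p0`
#' (default 50%, allowing rapid equilibration). Uses the current RNG
#' state; call `set.seed()` beforehand for reproducibility.
#'
#' @param graph A lattice (`ca_lattice` or `stressosome_graph`).
#' @param p0 Probability in `[0, 1]`.
#' @return Integer 0/1 vector, one bit per node.
#' @export
initialize_state <- function(graph, p0 = 0.5) {
  stopifnot(p0 >= 0, p0 <= 1)
  lat <- as_ca_lattice(graph)
  as.integer(stats::runif(length(lat$species)) < p0)
}

#' Advance the automaton by one step
#'
#' Visits all nodes in a fresh uniform random permutation; an
#' unphosphorylated node flips on with probability `p_a * kph`, a
#' phosphorylated one flips off with probability `kdp`. By default the
#' update is in place (later nodes in the permutation see earlier flips).
#'
#' @param state Integer 0/1 vector.
#' @param graph Lattice.
#' @param table An `allosteric_table`.
#' @param rates A `rate_params`.
#' @param kphr kphr for this step (defaults to `rates$kphr`).
#' @param synchronous Freeze the state read by all updates this step.
#' @return The updated 0/1 state vector.
#' @export
sim_step <- function(state, graph, table, rates, kphr = rates$kphr,
                     synchronous = FALSE) {
  lat <- as_ca_lattice(graph)
  stopifnot(length(state) == length(lat$species))
  res <- sim_run_cpp(as.integer(lat$species == "S"),
                     match(lat$class, c("R1", "R2", "R3", "S1")),
                     lat$sol, lat$p1, lat$p2, as_pa_matrix(table),
                     kphr, rates$kphs, rates$kdpr, rates$kdps,
                     as.integer(state), synchronous, FALSE)
  res$final
}

# internal: one replicate, burn-in included, from the current RNG state
run_one <- function(lat, config, record_bits = FALSE) {
  init <- as.integer(stats::runif(length(lat$species)) < config$p0)
  kphr0 <- kphr_at(config$schedule, 0)
  kphr_steps <- c(rep(kphr0, config$burn_in),
                  expand_schedule(config$schedule, config$n_steps,
                                  config$steps_per_min))
  res <- sim_run_cpp(as.integer(lat$species == "S"),
                     match(lat$class, c("R1", "R2", "R3", "S1")),
                     lat$sol, lat$p1, lat$p2, as_pa_matrix(config$table),
                     kphr_steps, config$rates$kphs, config$rates$kdpr,
                     config$rates$kdps, init, config$synchronous,
                     record_bits)
  keep <- (config$burn_in + 1):(config$burn_in + config$n_steps + 1)
  out <- list(frac = res$frac[keep, , drop = FALSE], final = res$final)
  if (record_bits) out$bits <- res$bits[keep, , drop = FALSE]
  out
}

replicate_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a single replicate trajectory
#'
#' One Monte-Carlo realisation: equilibrates for `config$burn_in` steps
#' at the initial kphr, then records the fractional phosphorylation of
#' RsbR and RsbS at every step. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param graph Lattice (default: the canonical stressosome).
#' @param record_bits Also return the full 0/1 state at every recorded
#'   step (column per node).
#' @return A data frame with columns `step`, `minutes`, `frac_R_P`,
#'   `frac_S_P` (and attribute `bits` if requested). Row 1 is the state
#'   at the end of burn-in (step 0).
#' @export
run_sim <- function(config, graph = stressosome_graph(),
                    record_bits = FALSE) {
  lat <- as_ca_lattice(graph)
  set.seed(config$seed)
  r <- run_one(lat, config, record_bits)
  steps <- 0:config$n_steps
  out <- data.frame(step = steps, minutes = steps / config$steps_per_min,
                    frac_R_P = r$frac[, 1], frac_S_P = r$frac[, 2])
  if (record_bits) attr(out, "bits") <- r$bits
  out
}

#' Run a replicate ensemble
#'
#' Repeats the simulation `config$n_replicates` times (default 50) with
#' independent initial states and update draws; replicate `r` uses a
#' child seed derived deterministically from the master seed. Returns
#' the per-step ensemble mean and variance of the fractional
#' phosphorylation of RsbR and RsbS.
#'
#' @inheritParams run_sim
#' @param keep_replicates Keep the per-replicate fraction matrices.
#' @return An object of class `replicate_summary`: data frame columns
#'   `step`, `minutes`, `mean_R_P`, `var_R_P`, `mean_S_P`, `var_S_P`;
#'   attributes `config` and (optionally) `replicates`.
#' @export
run_replicates <- function(config, graph = stressosome_graph(),
                           keep_replicates = FALSE) {
  lat <- as_ca_lattice(graph)
  seeds <- replicate_seeds(config$seed, config$n_replicates)
  nr <- config$n_steps + 1
  fr <- matrix(NA_real_, nr, config$n_replicates)
  fs <- matrix(NA_real_, nr, config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    set.seed(seeds[r])
    res <- run_one(lat, config)
    fr[, r] <- res$frac[, 1]
    fs[, r] <- res$frac[, 2]
  }
  steps <- 0:config$n_steps
  out <- data.frame(
    step = steps, minutes = steps / config$steps_per_min,
    mean_R_P = rowMeans(fr),
    var_R_P = apply(fr, 1, stats::var),
    mean_S_P = rowMeans(fs),
    var_S_P = apply(fs, 1, stats::var)
  )
  if (config$n_replicates == 1) out$var_R_P <- out$var_S_P <- 0
  attr(out, "config") <- config
  if (keep_replicates) attr(out, "replicates") <- list(R = fr, S = fs)
  class(out) <- c("replicate_summary", "data.frame")
  out
}

#' @export
print.replicate_summary <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Stressosome ensemble (", cfg$model, "): ",
      cfg$n_replicates, " replicates, ", nrow(x) - 1, " recorded steps\n",
      sep = "")
  cat(sprintf("  final mean RsbR-P = %.3f, mean RsbS-P = %.3f\n",
              x$mean_R_P[nrow(x)], x$mean_S_P[nrow(x)]))
  invisible(x)
}

#' @export
summary.replicate_summary <- function(object, ...) {
  cfg <- attr(object, "config")
  cat("Model:", cfg$model, " replicates:", cfg$n_replicates,
      " steps:", nrow(object) - 1, "\n")
  print(summary(object[, c("mean_R_P", "mean_S_P")]))
  invisible(object)
}

#' @export
plot.replicate_summary <- function(x, ...) {
  graphics::matplot(x$minutes, cbind(x$mean_R_P, x$mean_S_P), type = "l",
                    lty = 1, col = c("black", "grey50"),
                    xlab = "time (min)",
                    ylab = "fractional phosphorylation", ...)
  graphics::legend("topright", c("RsbR-P", "RsbS-P"), lty = 1,
                   col = c("black", "grey50"), bty = "n")
  invisible(x)
}

#' Steady-state phosphorylation under a constant schedule
#'
#' Time-averages the recorded (post burn-in) fractional phosphorylation
#' over all steps and replicates.
#'
#' @inheritParams run_sim
#' @return Named numeric vector `c(R = ..., S = ...)`.
#' @export
steady_state <- function(config, graph = stressosome_graph()) {
  if (!is_constant_schedule(config$schedule)) {
    stop("steady_state requires a constant stress schedule")
  }
  if (config$n_steps < 1) {
    stop("n_steps must exceed the burn-in to average a steady state")
  }
  s <- run_replicates(config, graph)
  c(R = mean(s$mean_R_P), S = mean(s$mean_S_P))
}

#' Write a trajectory summary to CSV
#'
#' Columns `step`, `minutes`, `mean_R_P`, `var_R_P`, `mean_S_P`,
#' `var_S_P`.
#'
#' @param summary A `replicate_summary`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}
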