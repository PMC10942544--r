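#' Scaled-down CA3-like demonstration network
#'
#' An eight-type CA3-style circuit: one excitatory Pyramidal population
#' and seven inhibitory interneuron populations (Axo-axonic, Basket,
#' Basket CCK+, Bistratified, Ivy, MFA ORDEN, QuadD-LM), fully connected
#' at the type level and wired with the class-averaged default
#' probabilities. Izhikevich parameters are the regular- and fast-spiking
#' archetypes; synapses use the engine defaults. At the default scale the
#' network holds about 3.5 thousand cells — a desk-scale analogue of a
#' resting-state hippocampal simulation, not a real-scale model.
#'
#' @param n_pyramidal Pyramidal cell count (default 2800).
#' @param n_interneuron Cells per interneuron type (default 100).
#' @return List with `populations` (list of [population_spec()]),
#'   `projections` (resolved [projection_spec()]s), and `drive`
#'   (per-population noisy current specs, pA).
#' @export
ca3_demo_spec <- function(n_pyramidal = 2800, n_interneuron = 100) {
  rs <- izhikevich_preset("regular_spiking")
  fs <- izhikevich_preset("fast_spiking")
  int_names <- c("CA3 Axo-axonic", "CA3 Basket", "CA3 Basket CCK+",
                 "CA3 Bistratified", "CA3 Ivy", "CA3 MFA ORDEN",
                 "CA3 QuadD-LM")
  populations <- c(
    list(population_spec(structure("CA3 Pyramidal", class_label = "excitatory"),
                         n = n_pyramidal, izhikevich = rs)),
    lapply(int_names, function(nm)
      population_spec(structure(nm, class_label = "inhibitory"),
                      n = n_interneuron, izhikevich = fs))
  )
  names(populations) <- vapply(populations, `[[`, character(1), "name")
  cls <- vapply(populations, `[[`, character(1), "class")

  projections <- list()
  for (pre in names(populations)) {
    for (post in names(populations)) {
      projections[[length(projections) + 1L]] <- resolve_missing(
        projection_spec(pre, post), cls[[pre]], cls[[post]])
    }
  }

  drive <- c(
    list(`CA3 Pyramidal` = list(mean = 90, sd = 60)),
    stats::setNames(rep(list(list(mean = 130, sd = 50)), length(int_names)),
                    int_names)
  )
  list(populations = populations, projections = projections, drive = drive)
}

#' Run the CA3-like demonstration network
#'
#' Instantiates and runs [ca3_demo_spec()] and band-filters the LFP proxy
#' into the theta, gamma and ripple bands.
#'
#' @param seed Integer seed (wiring and drive streams derive from it).
#' @param T Simulated span (ms).
#' @param dt Time step (ms).
#' @param ... Passed to [ca3_demo_spec()].
#' @return List with `run` (a `network_run`), `band_power` (named theta/
#'   gamma/ripple mean squared amplitudes of the filtered LFP proxy), and
#'   `network`.
#' @export
run_ca3_demo <- function(seed = 1L, T = 1000, dt = 0.1, ...) {
  spec <- ca3_demo_spec(...)
  net <- instantiate_network(spec$populations, spec$projections, seed = seed)
  run <- run_network(net, drive = spec$drive, dt = dt, T = T,
                     seed = seed + 1L)
  bp <- vapply(lfp_bands(), function(b) band_power(run$lfp, b, dt),
               numeric(1))
  list(run = run, band_power = bp, network = net)
}

#' Read a network configuration file
#'
#' YAML layout: `populations` (list of `name`, `class`, `n` or `scale`,
#'   `izhikevich` preset name or the nine parameters), `projections`
#'   (`pre`, `post` plus any known fields; the rest resolved from
#'   defaults), `drive` (`name: {mean, sd}`), `dt`, `T`, `seed`.
#'
#' @param path YAML file.
#' @return List ready for [instantiate_network()] / [run_network()]:
#'   `populations`, `projections`, `drive`, `dt`, `T`, `seed`.
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  populations <- lapply(cfg$populations, function(p) {
    izh <- if (is.character(p$izhikevich)) izhikevich_preset(p$izhikevich)
           else do.call(izhikevich_params, p$izhikevich)
    population_spec(structure(p$name, class_label = p$class),
                    n = p$n, izhikevich = izh)
  })
  cls <- stats::setNames(
    vapply(populations, `[[`, character(1), "class"),
    vapply(populations, `[[`, character(1), "name"))
  projections <- lapply(cfg$projections, function(pr) {
    args <- pr[intersect(names(pr), c("pre", "post", .conn_num_fields))]
    spec <- do.call(projection_spec, args)
    resolve_missing(spec, cls[[pr$pre]], cls[[pr$post]])
  })
  list(
    populations = populations,
    projections = projections,
    drive = cfg$drive,
    dt = if (is.null(cfg$dt)) 0.1 else cfg$dt,
    T = if (is.null(cfg$T)) 1000 else cfg$T,
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  )
}
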