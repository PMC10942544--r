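#' Generate a synthetic knowledge base
#'
#' A seeded stand-in for a curated neuron-type knowledge base, used for
#' tests, examples and demonstration networks. The generator emulates the
#' structure of real exports: types with laminar codes over the parcel
#' registry (one "hub" layer per subregion is set to axons-plus-dendrites
#' for every resident type, guaranteeing at least one potential
#' connection), Izhikevich parameters jittered around the regular- and
#' fast-spiking archetypes within physiological ranges, positive TPM
#' constants, census counts consistent with the constraint set it also
#' returns, and a configurable fraction of projection fields blanked to
#' exercise default substitution. Fully reproducible per seed.
#'
#' @param seed Integer seed.
#' @param n_types Number of types (>= 2).
#' @param subregions Subregions to populate (round-robin).
#' @param missing_rate Fraction of connection-level numeric fields blanked
#'   (`NA`) in the returned projections, in \[0, 1\].
#' @param p_range Range the per-pair connection probabilities are drawn
#'   from.
#' @return A list with `kb` (list `types`, `izhikevich`, `projections`),
#'   `constraints` (a consistent full-rank [build_constraint()] set),
#'   `truth_counts` (the census the constraints encode), and
#'   `measurements` (an anatomy table for the contact-model pathway).
#' @examples
#' fx <- generate_fixture_kb(seed = 1, n_types = 6)
#' length(fx$kb$types)
#' @export
generate_fixture_kb <- function(seed, n_types = 8,
                                subregions = c("DG", "CA3", "CA1"),
                                missing_rate = 0.1,
                                p_range = c(0.005, 0.03)) {
  if (n_types < 2L) stop("n_types must be >= 2", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed)

  home <- rep_len(subregions, n_types)
  # first type per subregion is the excitatory principal type
  class <- ifelse(!duplicated(home), "excitatory", "inhibitory")
  truth <- ifelse(class == "excitatory",
                  round(stats::runif(n_types, 3000, 8000)),
                  round(stats::runif(n_types, 150, 900)))

  types <- vector("list", n_types)
  izh <- list()
  for (i in seq_len(n_types)) {
    sub <- home[i]
    layers <- subregion_layers(sub)
    digits <- sample(0:3, length(layers), replace = TRUE)
    hub <- 1L + (match(sub, subregions()) %% length(layers))
    digits[hub] <- 3L            # shared axon+dendrite layer per subregion
    if (!any(digits %in% c(2L, 3L))) digits[1L] <- 2L
    code <- paste(digits, collapse = "")
    soma <- paste(sub, layers[hub], sep = ".")
    name <- sprintf("%s %s type %d", sub,
                    if (class[i] == "excitatory") "principal" else "interneuron",
                    i)
    pat <- parse_laminar_code(code, sub, soma_parcel = soma)
    types[[i]] <- neuron_type(name, pat, class = class[i],
                              census_count = truth[i],
                              rank = sample(1:5, 1L))
    base <- izhikevich_preset(
      if (class[i] == "excitatory") "regular_spiking" else "fast_spiking")
    jit <- function(x) x * stats::runif(1L, 0.9, 1.1)
    izh[[name]] <- izhikevich_params(
      C = jit(base$C), k = jit(base$k),
      v_r = base$v_r + stats::runif(1L, -3, 3),
      v_t = base$v_t + stats::runif(1L, -2, 2),
      v_peak = base$v_peak, v_min = base$v_min,
      a = jit(base$a), b = base$b * stats::runif(1L, 0.8, 1.2),
      d = jit(base$d))
  }
  nm <- vapply(types, `[[`, character(1), "name")

  # projections from the potential connectome
  graph <- build_connectome(types)
  projections <- lapply(seq_len(nrow(graph$edges)), function(e) {
    pre_class <- class[match(graph$edges$pre[e], nm)]
    exc <- pre_class == "excitatory"
    pr <- projection_spec(
      graph$edges$pre[e], graph$edges$post[e],
      p = stats::runif(1L, p_range[1L], p_range[2L]),
      n_contacts = stats::runif(1L, 1, 3),
      g = stats::runif(1L, 0.2, 2),
      tau_d = if (exc) stats::runif(1L, 3, 15) else stats::runif(1L, 5, 20),
      tau_r = stats::runif(1L, 200, 800),
      tau_f = stats::runif(1L, 20, 200),
      U = stats::runif(1L, 0.1, 0.5),
      E_rev = if (exc) 0 else -70,
      delay = sample(c(1, 1.5, 2), 1L))
    if (missing_rate > 0) {
      blank <- stats::runif(length(.conn_num_fields)) < missing_rate
      for (f in .conn_num_fields[blank]) {
        pr[[f]] <- NA_real_
        pr$provenance[[f]] <- NA_character_
      }
    }
    pr
  })

  # consistent, full-rank constraint set encoding `truth`
  constraints <- list()
  for (sub in unique(home)) {
    members <- nm[home == sub]
    constraints[[length(constraints) + 1L]] <-
      build_constraint("layer_total", total = sum(truth[home == sub]),
                       members = members,
                       note = paste("synthetic layer total", sub))
    if (length(members) > 1L) {
      for (m in members[-1L]) {
        constraints[[length(constraints) + 1L]] <-
          build_constraint("morphology_fraction",
                           fraction = truth[match(m, nm)] /
                             sum(truth[home == sub]),
                           members = m, group = members,
                           note = "synthetic sampled fraction")
      }
    }
  }

  # anatomy table for one pathway per projection's first overlap parcel
  meas <- data.frame(
    pre_type = graph$edges$pre,
    post_type = graph$edges$post,
    parcel = vapply(strsplit(graph$edges$overlap_parcels, ";"),
                    `[`, character(1), 1L),
    L_a = stats::runif(nrow(graph$edges), 2000, 12000),
    d_ib = stats::runif(nrow(graph$edges), 3, 10),
    L_d = stats::runif(nrow(graph$edges), 1000, 6000),
    V = stats::runif(nrow(graph$edges), 1e8, 5e8),
    stringsAsFactors = FALSE
  )
  meas$V_hull <- meas$V * stats::runif(nrow(meas), 0.2, 0.8)
  meas$r <- 1

  list(
    kb = list(types = types, izhikevich = izh, projections = projections),
    constraints = constraints,
    truth_counts = stats::setNames(truth, nm),
    measurements = meas
  )
}
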