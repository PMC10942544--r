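#' Class-averaged default connection probabilities
#'
#' Probabilities per ordered cell pair substituted when a projection's own
#' probability is unknown, averaged by connection class:
#' excitatory-excitatory 0.0117, excitatory-inhibitory 0.0237,
#' inhibitory-excitatory 0.00684, inhibitory-inhibitory 0.00423.
#'
#' @return Named numeric vector over `E-E`, `E-I`, `I-E`, `I-I`.
#' @export
class_default_probabilities <- function() {
  c("E-E" = 0.0117, "E-I" = 0.0237, "I-E" = 0.00684, "I-I" = 0.00423)
}

#' Engine defaults for missing synaptic and wiring parameters
#'
#' Substituted (and flagged `default`) when a projection lacks a measured
#' value. Conductance and kinetics are generic fast AMPA-like /
#' GABA-A-like values; delay is a uniform 1 ms; contacts default to 1.
#'
#' @param class Presynaptic class, `"excitatory"` or `"inhibitory"`.
#' @return Named list: `g`, `tau_d`, `tau_r`, `tau_f`, `U`, `E_rev`,
#'   `delay`, `n_contacts`.
#' @export
engine_defaults <- function(class = c("excitatory", "inhibitory")) {
  class <- match.arg(class)
  if (class == "excitatory") {
    list(g = 1.0, tau_d = 6, tau_r = 400, tau_f = 50, U = 0.25,
         E_rev = 0, delay = 1, n_contacts = 1)
  } else {
    list(g = 1.0, tau_d = 8, tau_r = 400, tau_f = 50, U = 0.32,
         E_rev = -70, delay = 1, n_contacts = 1)
  }
}

#' Construct a projection specification
#'
#' A directed type pair with its wiring probability, mean contacts per
#' connected pair, TPM synapse constants, and conduction delay. Any numeric
#' field may be `NA` (unknown); [resolve_missing()] fills those from
#' documented defaults and flags them. Provenance flags (`measured` /
#' `default`) are tracked per field.
#'
#' @param pre,post Type names.
#' @param p Connection probability per ordered cell pair, or `NA`.
#' @param n_contacts Mean contacts per connected pair (>= 1), or `NA`.
#' @param g,tau_d,tau_r,tau_f,U TPM constants, or `NA`.
#' @param E_rev Reversal potential (mV), or `NA`.
#' @param delay Conduction delay (ms), or `NA`.
#' @return A `projection_spec` object; `$provenance` marks every numeric
#'   field currently `measured` (present) or `NA`-pending.
#' @export
projection_spec <- function(pre, post, p = NA_real_, n_contacts = NA_real_,
                            g = NA_real_, tau_d = NA_real_, tau_r = NA_real_,
                            tau_f = NA_real_, U = NA_real_, E_rev = NA_real_,
                            delay = NA_real_) {
  fields <- list(p = p, n_contacts = n_contacts, g = g, tau_d = tau_d,
                 tau_r = tau_r, tau_f = tau_f, U = U, E_rev = E_rev,
                 delay = delay)
  if (!is.na(p) && (p < 0 || p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (!is.na(n_contacts) && n_contacts < 1) {
    stop("n_contacts must be >= 1", call. = FALSE)
  }
  prov <- vapply(fields, function(x) if (is.na(x)) NA_character_ else
    "measured", character(1))
  structure(
    c(list(pre = pre, post = post), fields, list(provenance = prov)),
    class = "projection_spec"
  )
}

#' Fill a projection's missing fields from documented defaults
#'
#' Missing probability is replaced by the class-averaged default for the
#' pair's connection class ([class_default_probabilities()]); missing
#' synaptic constants, delay and contacts by [engine_defaults()] for the
#' presynaptic class. Every substituted field is flagged `default`;
#' nothing is filled silently.
#'
#' @param spec A [projection_spec()].
#' @param pre_class,post_class `"excitatory"` or `"inhibitory"`.
#' @param class_defaults Named probability defaults (overridable).
#' @return The completed `projection_spec`, all provenance flags set.
#' @examples
#' s <- projection_spec("A", "B")  # everything unknown
#' r <- resolve_missing(s, "excitatory", "excitatory")
#' r$p               # 0.0117
#' r$provenance["p"] # "default"
#' @export
resolve_missing <- function(spec, pre_class, post_class,
                            class_defaults = class_default_probabilities()) {
  stopifnot(inherits(spec, "projection_spec"))
  pre_class <- match.arg(pre_class, c("excitatory", "inhibitory"))
  post_class <- match.arg(post_class, c("excitatory", "inhibitory"))
  key <- paste(ifelse(pre_class == "excitatory", "E", "I"),
               ifelse(post_class == "excitatory", "E", "I"), sep = "-")
  if (!key %in% names(class_defaults)) {
    stop("no class default for ", key, call. = FALSE)
  }
  eng <- engine_defaults(pre_class)
  fill <- function(field, value) {
    if (is.na(spec[[field]])) {
      spec[[field]] <<- value
      spec$provenance[[field]] <<- "default"
    }
  }
  fill("p", unname(class_defaults[[key]]))
  for (f in c("g", "tau_d", "tau_r", "tau_f", "U", "E_rev", "delay",
              "n_contacts")) {
    fill(f, eng[[f]])
  }
  spec
}

#' Population specification
#'
#' @param type A `neuron_type` (its `census_count` supplies the full-scale
#'   population size) or a bare name when `n` is given directly.
#' @param scale Fraction of the census to instantiate, in (0, 1].
#' @param n Direct instantiated count (overrides `scale`).
#' @param izhikevich An [izhikevich_params()] object for the population's
#'   dynamics.
#' @return A `population_spec` with `name`, `class`, `n >= 1`,
#'   `izhikevich`.
#' @export
population_spec <- function(type, scale = NULL, n = NULL, izhikevich) {
  if (inherits(type, "neuron_type")) {
    name <- type$name
    class <- type$class
    if (is.null(n)) {
      if (is.null(scale) || scale <= 0 || scale > 1) {
        stop("`scale` must lie in (0, 1] when `n` is not given",
             call. = FALSE)
      }
      if (is.na(type$census_count)) {
        stop("type has no census count; give `n` directly", call. = FALSE)
      }
      n <- max(1L, as.integer(round(type$census_count * scale)))
    }
  } else {
    name <- as.character(type)
    class <- attr(type, "class_label")
    if (is.null(n)) stop("give `n` when `type` is a bare name", call. = FALSE)
    if (is.null(class)) class <- "excitatory"
  }
  stopifnot(inherits(izhikevich, "izhikevich_params"))
  structure(
    list(name = name, class = class, n = as.integer(n),
         izhikevich = izhikevich),
    class = "population_spec"
  )
}

#' Instantiate a spiking network
#'
#' Assigns contiguous global cell index ranges to the populations, then
#' wires every projection stochastically: each ordered cell pair of the
#' pre and post populations is connected independently with the
#' projection's probability (cell-level autapses excluded for within-type
#' projections), and each realized synapse draws its contact count from a
#' shifted Poisson, `1 + Poisson(n_contacts - 1)`, so the minimum is 1 and
#' the mean matches. Wiring uses its own RNG stream: the same seed always
#' yields the same adjacency regardless of later drive randomness.
#'
#' @param populations List of [population_spec()]s (unique names).
#' @param projections List of resolved [projection_spec()]s (no `NA`
#'   fields; see [resolve_missing()]).
#' @param seed Integer seed for the wiring stream.
#' @return A `network` object: populations, index `ranges` (data frame
#'   with `name`, `from`, `to`), per-projection synapse arrays, and
#'   `n_cells`.
#' @export
instantiate_network <- function(populations, projections, seed) {
  if (length(populations) == 0L) stop("empty populations", call. = FALSE)
  stopifnot(all(vapply(populations, inherits, logical(1), "population_spec")))
  nm <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate population names", call. = FALSE)
  ns <- vapply(populations, `[[`, integer(1), "n")
  to <- cumsum(ns)
  from <- c(1L, utils::head(to, -1L) + 1L)
  ranges <- data.frame(name = nm, from = from, to = to,
                       stringsAsFactors = FALSE)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(seed %% 2147483647L)

  synapses <- vector("list", length(projections))
  for (k in seq_along(projections)) {
    pr <- projections[[k]]
    stopifnot(inherits(pr, "projection_spec"))
    if (anyNA(unlist(pr[c("p", "n_contacts", "g", "tau_d", "tau_r", "tau_f",
                          "U", "E_rev", "delay")]))) {
      stop(sprintf("projection %s->%s has unresolved fields; run resolve_missing()",
                   pr$pre, pr$post), call. = FALSE)
    }
    i_pre <- match(pr$pre, nm)
    i_post <- match(pr$post, nm)
    if (is.na(i_pre) || is.na(i_post)) {
      stop(sprintf("projection %s->%s references unknown population",
                   pr$pre, pr$post), call. = FALSE)
    }
    n_pre <- ns[i_pre]; n_post <- ns[i_post]
    same <- i_pre == i_post
    M <- if (same) as.double(n_pre) * (n_post - 1L) else
      as.double(n_pre) * n_post
    if (M <= 0 || pr$p <= 0) {
      synapses[[k]] <- list(pre_local = integer(0), post_local = integer(0),
                            contacts = integer(0), projection = pr,
                            i_pre = i_pre, i_post = i_post)
      next
    }
    n_syn <- stats::rbinom(1L, M, pr$p)
    idx <- if (n_syn > 0L) sort(sample.int(M, n_syn)) else integer(0)
    if (same) {
      # enumerate ordered pairs without the diagonal
      pre_local <- (idx - 1L) %/% (n_post - 1L) + 1L
      jj <- (idx - 1L) %% (n_post - 1L) + 1L
      post_local <- jj + (jj >= pre_local)
    } else {
      pre_local <- (idx - 1L) %/% n_post + 1L
      post_local <- (idx - 1L) %% n_post + 1L
    }
    contacts <- 1L + stats::rpois(n_syn, max(pr$n_contacts - 1, 0))
    synapses[[k]] <- list(pre_local = as.integer(pre_local),
                          post_local = as.integer(post_local),
                          contacts = contacts,
                          projection = pr, i_pre = i_pre, i_post = i_post)
  }

  structure(
    list(populations = populations, ranges = ranges,
         synapses = synapses, n_cells = sum(ns)),
    class = "network"
  )
}

#' @export
print.network <- function(x, ...) {
  n_syn <- sum(vapply(x$synapses, function(s) length(s$pre_local), numeric(1)))
  cat("<network> ", length(x$populations), " populations, ",
      x$n_cells, " cells, ", n_syn, " synapses\n", sep = "")
  invisible(x)
}

#' Run a spiking network
#'
#' Clock-driven simulation of the coupled system: per step, delayed
#' synaptic releases arrive on per-projection conductance accumulators
#' (exponential decay `tau_d`), synaptic plus external drive currents are
#' injected, all Izhikevich neurons advance one forward-Euler step, and
#' spikes trigger event-driven analytic TPM updates on each outgoing
#' synapse (release amplitude `g * release * contacts`, scheduled after
#' the projection's delay). Drive noise uses its own RNG stream, separate
#' from wiring.
#'
#' @param network An [instantiate_network()] result.
#' @param drive Named list per population: each entry `list(mean, sd)` in
#'   pA (`sd` optional, step-wise Gaussian noise), or a single number.
#'   Unnamed populations receive no drive.
#' @param dt Time step (ms).
#' @param T Simulated span (ms).
#' @param seed Integer seed for the drive stream.
#' @param record_traces Number of sample cells per population whose
#'   voltage traces are kept (default 1).
#' @return A `network_run`: `spikes` (data frame `cell`, `t`,
#'   `population`), `traces` (list per population: matrix steps x cells,
#'   mV), `lfp` (summed |synaptic current| onto excitatory cells, pA, per
#'   step), `pop_rates` (Hz per population), `t` (step times), `dt`.
#' @export
run_network <- function(network, drive = list(), dt = 0.1, T = 1000,
                        seed = 1L, record_traces = 1L) {
  stopifnot(inherits(network, "network"))
  n_steps <- as.integer(round(T / dt))
  pops <- network$populations
  ranges <- network$ranges
  N <- network$n_cells

  # per-cell parameter vectors
  par <- list()
  for (f in c("C", "k", "v_r", "v_t", "v_peak", "v_min", "a", "b", "d")) {
    par[[f]] <- unlist(lapply(pops, function(p) rep(p$izhikevich[[f]], p$n)))
  }
  exc_cells <- unlist(lapply(seq_along(pops), function(i) {
    if (pops[[i]]$class == "excitatory") ranges$from[i]:ranges$to[i] else integer(0)
  }))

  # drive
  drive_mean <- numeric(N); drive_sd <- numeric(N)
  for (nm in names(drive)) {
    i <- match(nm, ranges$name)
    if (is.na(i)) stop("drive names unknown population: ", nm, call. = FALSE)
    dd <- drive[[nm]]
    if (is.numeric(dd)) dd <- list(mean = dd, sd = 0)
    sel <- ranges$from[i]:ranges$to[i]
    drive_mean[sel] <- dd$mean
    drive_sd[sel] <- if (is.null(dd$sd)) 0 else dd$sd
  }
  noisy <- any(drive_sd > 0)

  # per-projection working state; environments so ring buffers and synapse
  # state mutate in place inside the step loop
  syn <- network$synapses
  K <- length(syn)
  proj_state <- vector("list", K)
  for (k in seq_len(K)) {
    s <- syn[[k]]
    pr <- s$projection
    n_post <- pops[[s$i_post]]$n
    ds <- max(1L, as.integer(round(pr$delay / dt)))
    # group synapses by presynaptic local cell for event delivery
    by_pre <- split(seq_along(s$pre_local), s$pre_local)
    proj_state[[k]] <- list2env(list(
      decay = exp(-dt / pr$tau_d),
      f_decay_rate = 1 / pr$tau_f,
      r_decay_rate = 1 / pr$tau_r,
      E_rev = pr$E_rev, g = pr$g,
      U = pr$U,
      ds = ds,
      ring = matrix(0, ds, n_post),
      g_acc = numeric(n_post),
      u_s = numeric(length(s$pre_local)),
      R_s = rep(1, length(s$pre_local)),
      t_last = rep(0, length(s$pre_local)),
      by_pre = by_pre,
      post_from = ranges$from[s$i_post],
      pre_from = ranges$from[s$i_pre],
      pre_to = ranges$to[s$i_pre],
      post_exc = pops[[s$i_post]]$class == "excitatory"
    ), parent = emptyenv())
  }

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed((seed + 1013904223) %% 2147483647L)

  v <- par$v_r
  u <- numeric(N)
  spike_cell <- vector("list", n_steps)
  lfp <- numeric(n_steps)

  rec_idx <- unlist(lapply(seq_along(pops), function(i) {
    ranges$from[i]:min(ranges$to[i], ranges$from[i] + record_traces - 1L)
  }))
  traces <- matrix(NA_real_, n_steps, length(rec_idx))

  for (s_i in seq_len(n_steps)) {
    t_now <- s_i * dt
    I <- if (noisy) drive_mean + drive_sd * stats::rnorm(N) else drive_mean
    I_abs_exc <- 0

    for (k in seq_len(K)) {
      ps <- proj_state[[k]]
      slot <- (s_i - 1L) %% ps$ds + 1L
      g_acc <- ps$g_acc * ps$decay + ps$ring[slot, ]
      ps$ring[slot, ] <- 0
      ps$g_acc <- g_acc
      sel <- ps$post_from:(ps$post_from + length(g_acc) - 1L)
      I_k <- g_acc * (ps$E_rev - v[sel])
      I[sel] <- I[sel] + I_k
      if (ps$post_exc) I_abs_exc <- I_abs_exc + sum(abs(I_k))
    }
    lfp[s_i] <- I_abs_exc

    dv <- (par$k * (v - par$v_r) * (v - par$v_t) - u + I) / par$C
    du <- par$a * (par$b * (v - par$v_r) - u)
    v <- v + dt * dv
    u <- u + dt * du
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1L]
      stop(sprintf("instability (non-finite voltage) at cell %d, t = %g ms",
                   bad, t_now), call. = FALSE)
    }
    fired <- which(v >= par$v_peak)
    v_rec <- v
    if (length(fired) > 0L) {
      v_rec[fired] <- par$v_peak[fired]
      v[fired] <- par$v_min[fired]
      u[fired] <- u[fired] + par$d[fired]
      spike_cell[[s_i]] <- fired

      for (k in seq_len(K)) {
        ps <- proj_state[[k]]
        in_pre <- fired[fired >= ps$pre_from & fired <= ps$pre_to]
        if (length(in_pre) == 0L) next
        local <- as.character(in_pre - ps$pre_from + 1L)
        sids <- unlist(ps$by_pre[local], use.names = FALSE)
        if (is.null(sids) || length(sids) == 0L) next
        dtt <- t_now - ps$t_last[sids]
        u_s <- ps$u_s[sids] * exp(-dtt * ps$f_decay_rate)
        R_s <- 1 - (1 - ps$R_s[sids]) * exp(-dtt * ps$r_decay_rate)
        u_plus <- u_s + ps$U * (1 - u_s)
        release <- u_plus * R_s
        ps$u_s[sids] <- u_plus
        ps$R_s[sids] <- R_s - release
        ps$t_last[sids] <- t_now
        amp <- ps$g * release * syn[[k]]$contacts[sids]
        slot_out <- (s_i - 1L + ps$ds) %% ps$ds + 1L
        add <- rowsum(amp, group = syn[[k]]$post_local[sids])
        dest <- as.integer(rownames(add))
        ps$ring[slot_out, dest] <- ps$ring[slot_out, dest] + as.vector(add)
      }
    }
    traces[s_i, ] <- v_rec[rec_idx]
  }

  n_per_step <- lengths(spike_cell)
  cells <- unlist(spike_cell, use.names = FALSE)
  tt <- rep(seq_len(n_steps) * dt, n_per_step)
  pop_of <- function(cell) {
    ranges$name[findInterval(cell, ranges$from)]
  }
  spikes <- data.frame(
    cell = if (is.null(cells)) integer(0) else cells,
    t = if (is.null(cells)) numeric(0) else tt,
    population = if (is.null(cells)) character(0) else pop_of(cells),
    stringsAsFactors = FALSE
  )
  pop_rates <- vapply(seq_along(pops), function(i) {
    n_sp <- sum(spikes$population == ranges$name[i])
    n_sp / pops[[i]]$n / (T / 1000)
  }, numeric(1))
  names(pop_rates) <- ranges$name

  trace_list <- list()
  off <- 0L
  for (i in seq_along(pops)) {
    nrec <- min(pops[[i]]$n, record_traces)
    trace_list[[ranges$name[i]]] <-
      traces[, off + seq_len(nrec), drop = FALSE]
    off <- off + nrec
  }

  structure(
    list(spikes = spikes, traces = trace_list, lfp = lfp,
         pop_rates = pop_rates, t = seq_len(n_steps) * dt, dt = dt),
    class = "network_run"
  )
}

#' @export
print.network_run <- function(x, ...) {
  cat("<network_run> ", length(x$t) * x$dt, " ms, ",
      nrow(x$spikes), " spikes\n", sep = "")
  print(round(x$pop_rates, 2))
  invisible(x)
}

#' Preset frequency bands for LFP filtering
#'
#' @return Named list of `c(lo, hi)` Hz pairs: theta (4-12), gamma
#'   (25-100), ripple (150-200).
#' @export
lfp_bands <- function() {
  list(theta = c(4, 12), gamma = c(25, 100), ripple = c(150, 200))
}

#' Band-filter an LFP proxy signal
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass. Because
#' narrow low-frequency bands are numerically ill-conditioned at high
#' sampling rates, the signal is first decimated (anti-aliased) to a
#' working rate of about 40x the band's upper edge, filtered there, and
#' linearly interpolated back to the original sampling grid, preserving
#' length.
#'
#' @param x Signal (e.g. the `lfp` component of [run_network()]).
#' @param band `c(lo, hi)` Hz, a name from [lfp_bands()], or one of its
#'   entries.
#' @param dt Sampling step of `x` (ms).
#' @return Filtered signal, same length as `x`.
#' @examples
#' dt <- 0.1
#' tt <- seq(0, 2000, by = dt)
#' theta_in <- sin(2 * pi * 8 * tt / 1000)
#' out <- lfp_filter(theta_in, "theta", dt)
#' @export
lfp_filter <- function(x, band, dt) {
  if (is.character(band)) {
    band <- lfp_bands()[[match.arg(band, names(lfp_bands()))]]
  }
  fs <- 1000 / dt
  if (band[2L] <= band[1L] || band[1L] <= 0) {
    stop("band must be c(lo, hi) with 0 < lo < hi", call. = FALSE)
  }
  if (band[2L] >= fs / 2) {
    stop(sprintf("band upper edge %g Hz reaches the Nyquist rate %g Hz",
                 band[2L], fs / 2), call. = FALSE)
  }
  n <- length(x)
  q_total <- max(1L, floor(fs / (40 * band[2L])))
  y <- x
  fs_work <- fs
  q_left <- q_total
  while (q_left > 1L) {
    q <- min(q_left, 10L)
    y <- signal::decimate(y, q)
    fs_work <- fs_work / q
    q_left <- q_left %/% q
  }
  bf <- signal::butter(4, band / (fs_work / 2), type = "pass")
  y <- signal::filtfilt(bf, y)
  if (fs_work < fs) {
    t_work <- seq(0, by = 1 / fs_work, length.out = length(y))
    t_full <- seq(0, by = 1 / fs, length.out = n)
    y <- stats::approx(t_work, y, xout = t_full, rule = 2)$y
  }
  y[seq_len(n)]
}

#' Band power of a signal
#'
#' Mean squared amplitude of the band-filtered signal; a scalar summary
#' used to check that an oscillatory band carries finite, nonzero power.
#'
#' @inheritParams lfp_filter
#' @return Mean of the squared filtered signal.
#' @export
band_power <- function(x, band, dt) {
  mean(lfp_filter(x, band, dt)^2)
}
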