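#' Census constraints
#'
#' The neuron-type census is solved from linear relations extracted from
#' the literature: layer totals (density x volume over the types resident
#' in a layer), marker or morphology fractions (a subset is a stated
#' fraction of a group), and direct counts. Each relation is one weighted
#' linear row `sum_i a_i x_i = b`.
#'
#' @param kind One of `"layer_total"`, `"marker_fraction"`,
#'   `"morphology_fraction"`, `"direct_count"`.
#' @param ... Kind-specific inputs:
#'   * `layer_total`: `density` (cells/mm^3), `volume` (mm^3), `members`
#'     (character vector of type names); the target is their product.
#'     Alternatively pass `total` directly.
#'   * `*_fraction`: `fraction` in \[0, 1\], `members` (the subset),
#'     `group` (the reference set, a superset of members). Encoded as the
#'     homogeneous row `x_members - fraction * x_group = 0`, i.e.
#'     coefficient `1 - fraction` on members inside the group and
#'     `-fraction` on the rest of the group.
#'   * `direct_count`: `type` (single name), `count`.
#' @param weight Positive weight of the row in the least-squares objective.
#' @param note Free-text provenance note.
#' @return A `census_constraint`: list with `kind`, `coefficients` (named
#'   numeric), `target`, `weight`, `note`.
#' @examples
#' build_constraint("layer_total", density = 1e3, volume = 0.05,
#'                  members = c("A", "B"))
#' build_constraint("morphology_fraction", fraction = 0.3,
#'                  members = "A", group = c("A", "B"))
#' @export
build_constraint <- function(kind = c("layer_total", "marker_fraction",
                                      "morphology_fraction", "direct_count"),
                             ..., weight = 1, note = "") {
  kind <- match.arg(kind)
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0) {
    stop("`weight` must be a positive scalar", call. = FALSE)
  }
  args <- list(...)
  if (kind == "layer_total") {
    members <- args$members
    if (is.null(members) || length(members) == 0L) {
      stop("layer_total needs a non-empty `members` set", call. = FALSE)
    }
    total <- if (!is.null(args$total)) args$total else {
      if (is.null(args$density) || is.null(args$volume)) {
        stop("layer_total needs `density` and `volume` (or `total`)",
             call. = FALSE)
      }
      args$density * args$volume
    }
    if (total < 0) stop("layer total must be >= 0", call. = FALSE)
    coef <- stats::setNames(rep(1, length(members)), members)
    target <- total
  } else if (kind %in% c("marker_fraction", "morphology_fraction")) {
    f <- args$fraction
    members <- args$members
    group <- args$group
    if (is.null(f) || f < 0 || f > 1) {
      stop("`fraction` must lie in [0, 1]", call. = FALSE)
    }
    if (is.null(members) || length(members) == 0L) {
      stop("fraction constraints need a non-empty `members` set",
           call. = FALSE)
    }
    if (is.null(group) || !all(members %in% group)) {
      stop("`group` must contain all of `members`", call. = FALSE)
    }
    coef <- stats::setNames(rep(-f, length(group)), group)
    coef[members] <- coef[members] + 1
    coef <- coef[coef != 0]
    if (length(coef) == 0L) {
      stop("degenerate fraction constraint (all coefficients zero)",
           call. = FALSE)
    }
    target <- 0
  } else {
    if (is.null(args$type) || length(args$type) != 1L) {
      stop("direct_count needs a single `type`", call. = FALSE)
    }
    if (is.null(args$count) || args$count < 0) {
      stop("direct_count needs `count` >= 0", call. = FALSE)
    }
    coef <- stats::setNames(1, args$type)
    target <- args$count
  }
  structure(
    list(kind = kind, coefficients = coef, target = target,
         weight = weight, note = note),
    class = "census_constraint"
  )
}

#' Solve the neuron-type census
#'
#' Minimizes the weighted sum of squared residuals of all constraint rows
#' subject to nonnegative counts: `min_x sum_j w_j (a_j . x - b_j)^2`,
#' `x >= 0`, solved by nonnegative least squares on the
#' `sqrt(w)`-row-scaled system. Fraction constraints are additionally
#' scaled so that their (dimensionless) residuals are commensurate with
#' count-valued rows; see `fraction_scale`.
#'
#' @param constraints List of [build_constraint()] rows.
#' @param types Character vector of all type names in scope. Types not
#'   referenced by any constraint get count 0 and are flagged.
#' @param fraction_scale How homogeneous fraction rows are brought onto
#'   count units: `"group"` (default) multiplies each such row by a crude
#'   group-size estimate taken from the count-valued rows (mean target of
#'   total/count rows; 1 when none exist), `"none"` leaves rows as built.
#' @return A `census_solution`: list with `counts` (named nonnegative
#'   numeric over `types`), `residuals` (per constraint, `a . x - b` on the
#'   unscaled rows), `identifiable` (TRUE iff the stacked coefficient
#'   matrix has full column rank), `unconstrained` (names never referenced).
#' @examples
#' cs <- list(
#'   build_constraint("layer_total", total = 100, members = c("A", "B")),
#'   build_constraint("morphology_fraction", fraction = 0.3,
#'                    members = "A", group = c("A", "B"))
#' )
#' solve_census(cs, c("A", "B"))$counts  # A = 30, B = 70
#' @export
solve_census <- function(constraints, types,
                         fraction_scale = c("group", "none")) {
  fraction_scale <- match.arg(fraction_scale)
  if (length(constraints) == 0L) {
    stop("at least one constraint is required", call. = FALSE)
  }
  stopifnot(all(vapply(constraints, inherits, logical(1), "census_constraint")))
  types <- as.character(types)
  if (anyDuplicated(types)) stop("duplicate type names", call. = FALSE)

  named <- unique(unlist(lapply(constraints, function(k) names(k$coefficients))))
  unknown <- setdiff(named, types)
  if (length(unknown) > 0L) {
    stop("constraints reference unknown type(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  m <- length(constraints)
  n <- length(types)
  A <- matrix(0, m, n, dimnames = list(NULL, types))
  b <- numeric(m)
  w <- numeric(m)
  kinds <- character(m)
  for (j in seq_len(m)) {
    k <- constraints[[j]]
    A[j, names(k$coefficients)] <- k$coefficients
    b[j] <- k$target
    w[j] <- k$weight
    kinds[j] <- k$kind
  }

  # unit balancing for homogeneous fraction rows
  if (fraction_scale == "group") {
    is_frac <- kinds %in% c("marker_fraction", "morphology_fraction")
    count_rows <- b[!is_frac & b > 0]
    scale <- if (length(count_rows) > 0L) mean(count_rows) else 1
    w[is_frac] <- w[is_frac] * scale^2
  }

  sw <- sqrt(w)
  Asc <- A * sw
  bsc <- b * sw
  constrained <- colSums(A != 0) > 0
  x <- stats::setNames(numeric(n), types)
  if (any(constrained)) {
    fit <- pracma::lsqnonneg(Asc[, constrained, drop = FALSE], bsc)
    x[constrained] <- fit$x
  }
  residuals <- as.vector(A %*% x) - b
  identifiable <- qr(Asc)$rank == n

  structure(
    list(
      counts = x,
      residuals = residuals,
      identifiable = identifiable,
      unconstrained = types[!constrained]
    ),
    class = "census_solution"
  )
}

#' @export
print.census_solution <- function(x, ...) {
  cat("<census_solution> ", length(x$counts), " types, ",
      length(x$residuals), " constraints; identifiable: ",
      x$identifiable, "\n", sep = "")
  print(round(x$counts, 2))
  if (length(x$unconstrained) > 0L) {
    cat("unconstrained (count forced to 0): ",
        paste(x$unconstrained, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read a constraint table
#'
#' CSV columns: `kind`, `members` (semicolon-separated), `group`
#' (semicolon-separated, fraction kinds only), `value` (total, fraction or
#' count according to kind), `weight`, `note`.
#'
#' @param path CSV file path.
#' @return List of [build_constraint()] rows.
#' @export
read_constraints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("kind", "members", "value")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("constraint table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  split_names <- function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";")[[1L]]
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    wt <- if ("weight" %in% names(df) && !is.na(row$weight)) row$weight else 1
    nt <- if ("note" %in% names(df) && !is.na(row$note)) row$note else ""
    members <- split_names(row$members)
    switch(row$kind,
      layer_total = build_constraint("layer_total", total = row$value,
                                     members = members,
                                     weight = wt, note = nt),
      direct_count = build_constraint("direct_count", type = members[1L],
                                      count = row$value,
                                      weight = wt, note = nt),
      build_constraint(row$kind, fraction = row$value, members = members,
                       group = split_names(row$group),
                       weight = wt, note = nt)
    )
  })
}
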