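#' Full parcel-state table of a type (home plus projecting parcels)
#' @noRd
pattern_states <- function(t) {
  p <- t$pattern
  c(p$presence, p$projecting)
}

#' Potential connection between two neuron types
#'
#' A directed potential connection pre -> post exists iff at least one
#' parcel carries both presynaptic axons (state AXON or BOTH of `pre`) and
#' postsynaptic dendrites (state DENDRITE or BOTH of `post`). Projecting
#' parcels count the same as home parcels. When the axons of `pre` also
#' invade the parcel holding the soma of `post`, the connection is
#' annotated as soma-targeting (a possible perisomatic contact locus), but
#' that apposition is not itself an edge criterion.
#'
#' @param pre,post `neuron_type` objects.
#' @return List with `connected` (flag), `overlap_parcels` (character
#'   vector of parcels with axonal-dendritic co-presence) and
#'   `soma_targeting` (flag).
#' @examples
#' a <- neuron_type("pre",  parse_laminar_code("2210", "DG"), "i")
#' b <- neuron_type("post", parse_laminar_code("2232", "DG"), "i")
#' has_potential_connection(a, b)  # connected via DG.SG
#' @export
has_potential_connection <- function(pre, post) {
  ax <- pattern_states(pre)
  dn <- pattern_states(post)
  ax_parcels <- names(ax)[state_has_axon(ax)]
  dn_parcels <- names(dn)[state_has_dendrite(dn)]
  overlap <- intersect(ax_parcels, dn_parcels)
  soma <- post$pattern$soma_parcel
  list(
    connected = length(overlap) > 0L,
    overlap_parcels = overlap,
    soma_targeting = !is.null(soma) && soma %in% ax_parcels
  )
}

#' Build the potential connectome of a set of types
#'
#' Scans all ordered type pairs (self-pairs included: a type may
#' potentially connect to itself; autapses of individual cells are excluded
#' later, at network wiring) and keeps the pairs with axonal-dendritic
#' overlap in at least one parcel.
#'
#' @param types List of `neuron_type` objects with unique names.
#' @return A `connectome` object: list with `types` (the input), `edges`
#'   (data frame: `pre`, `post`, `class` in E-E/E-I/I-E/I-I,
#'   `overlap_parcels` semicolon-joined, `n_overlap`, `soma_targeting`).
#' @export
build_connectome <- function(types) {
  if (length(types) < 1L) stop("need at least one type", call. = FALSE)
  nm <- vapply(types, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate type names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  cls <- vapply(types, `[[`, character(1), "class")
  lab <- ifelse(cls == "excitatory", "E", "I")

  rows <- list()
  for (i in seq_along(types)) {
    for (j in seq_along(types)) {
      hit <- has_potential_connection(types[[i]], types[[j]])
      if (hit$connected) {
        rows[[length(rows) + 1L]] <- data.frame(
          pre = nm[i], post = nm[j],
          class = paste(lab[i], lab[j], sep = "-"),
          overlap_parcels = paste(hit$overlap_parcels, collapse = ";"),
          n_overlap = length(hit$overlap_parcels),
          soma_targeting = hit$soma_targeting,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  edges <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(pre = character(), post = character(), class = character(),
               overlap_parcels = character(), n_overlap = integer(),
               soma_targeting = logical(), stringsAsFactors = FALSE)
  structure(list(types = types, edges = edges), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", length(x$types), " types, ",
      nrow(x$edges), " potential connections\n", sep = "")
  if (nrow(x$edges) > 0L) print(summarize_connectome(x, "class"))
  invisible(x)
}

#' Summarize a connectome's edges
#'
#' @param graph A [build_connectome()] result.
#' @param by Partition: `"class"` (E-E/E-I/I-E/I-I), `"subregion_pair"`
#'   (home subregion of pre and post), or `"node"` (out- and in-degree per
#'   type).
#' @return A data frame of counts; class and subregion-pair counts
#'   partition the edge set (they sum to the edge total).
#' @export
summarize_connectome <- function(graph, by = c("class", "subregion_pair", "node")) {
  by <- match.arg(by)
  stopifnot(inherits(graph, "connectome"))
  e <- graph$edges
  if (by == "class") {
    lv <- c("E-E", "E-I", "I-E", "I-I")
    tab <- table(factor(e$class, levels = lv))
    return(data.frame(class = lv, n = as.integer(tab),
                      stringsAsFactors = FALSE))
  }
  nm <- vapply(graph$types, `[[`, character(1), "name")
  home <- vapply(graph$types, `[[`, character(1), "home_subregion")
  if (by == "subregion_pair") {
    pre_sub <- home[match(e$pre, nm)]
    post_sub <- home[match(e$post, nm)]
    if (nrow(e) == 0L) {
      return(data.frame(pre_subregion = character(),
                        post_subregion = character(), n = integer(),
                        stringsAsFactors = FALSE))
    }
    agg <- stats::aggregate(
      list(n = rep(1L, nrow(e))),
      by = list(pre_subregion = pre_sub, post_subregion = post_sub), sum)
    return(agg[order(agg$pre_subregion, agg$post_subregion), , drop = FALSE])
  }
  data.frame(
    type = nm,
    out_degree = as.integer(vapply(nm, function(x) sum(e$pre == x), numeric(1))),
    in_degree = as.integer(vapply(nm, function(x) sum(e$post == x), numeric(1))),
    stringsAsFactors = FALSE
  )
}

#' Convert a connectome to an igraph object
#'
#' @param graph A [build_connectome()] result.
#' @return A directed [igraph::graph] with vertex attributes `class` and
#'   `subregion` and edge attributes `class`, `overlap_parcels`.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "connectome"))
  nm <- vapply(graph$types, `[[`, character(1), "name")
  verts <- data.frame(
    name = nm,
    class = vapply(graph$types, `[[`, character(1), "class"),
    subregion = vapply(graph$types, `[[`, character(1), "home_subregion"),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = verts)
}

#' Dense adjacency matrix of a connectome
#'
#' @param graph A [build_connectome()] result.
#' @return 0/1 integer matrix, rows = presynaptic type, columns =
#'   postsynaptic type.
#' @export
adjacency_matrix <- function(graph) {
  stopifnot(inherits(graph, "connectome"))
  nm <- vapply(graph$types, `[[`, character(1), "name")
  A <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
  e <- graph$edges
  if (nrow(e) > 0L) A[cbind(e$pre, e$post)] <- 1L
  A
}

#' Write a connectome edge list (and optionally the adjacency matrix)
#'
#' @param graph A [build_connectome()] result.
#' @param path Edge-list CSV path.
#' @param adjacency_path Optional adjacency-matrix CSV path (row = pre).
#' @return `path`, invisibly.
#' @export
write_connectome <- function(graph, path, adjacency_path = NULL) {
  stopifnot(inherits(graph, "connectome"))
  write_csv_lf(graph$edges, path)
  if (!is.null(adjacency_path)) {
    A <- adjacency_matrix(graph)
    df <- data.frame(pre = rownames(A), A, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_csv_lf(df, adjacency_path)
  }
  invisible(path)
}
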