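#' @noRd
fmt_num <- function(x) {
  # 15 significant digits: decimal -> double -> decimal is the identity at
  # this precision, so export -> import -> export is byte-stable
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = 15, format = "g")
  }, character(1))
  out
}

#' @noRd
csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Write a data frame as deterministic CSV
#'
#' RFC-4180 quoting, UTF-8, LF line endings, fixed column order as given,
#' numerics at 15 significant digits, `NA` as the empty field. Identical
#' input always yields byte-identical output.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csv_lf <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) fmt_num(col)
    else {
      s <- as.character(col)
      s[is.na(s)] <- ""
      csv_quote(s)
    }
  })
  header <- paste(csv_quote(names(df)), collapse = ",")
  body <- if (nrow(df) > 0L) do.call(paste, c(cols, sep = ",")) else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# ---- parameter bundles (the CSV export dialect) ----------------------------

.neuron_num_fields <- c("census_count", "C", "k", "v_r", "v_t", "v_peak",
                        "v_min", "a", "b", "d")
.conn_num_fields <- c("p", "n_contacts", "g", "tau_d", "tau_r", "tau_f",
                      "U", "E_rev", "delay")

#' Select neuron types from a knowledge base
#'
#' Types can be picked individually, by home subregion, and/or by
#' importance rank (keeping types with rank `<= max_rank`); the filters
#' intersect. The returned selection carries only the projections whose
#' two endpoints are both selected.
#'
#' @param kb A knowledge base (e.g. from [generate_fixture_kb()]): a list
#'   with `types`, `izhikevich` (named list), `projections`.
#' @param types Optional character vector of type names.
#' @param subregion Optional subregion filter.
#' @param max_rank Optional rank ceiling (1..5).
#' @return A `kb_selection`: same structure as `kb`, filtered.
#' @export
select_types <- function(kb, types = NULL, subregion = NULL, max_rank = NULL) {
  nm <- vapply(kb$types, `[[`, character(1), "name")
  keep <- rep(TRUE, length(nm))
  if (!is.null(types)) {
    unknown <- setdiff(types, nm)
    if (length(unknown) > 0L) {
      stop("unknown type(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    keep <- keep & nm %in% types
  }
  if (!is.null(subregion)) {
    subregion <- match.arg(subregion, subregions(), several.ok = TRUE)
    home <- vapply(kb$types, `[[`, character(1), "home_subregion")
    keep <- keep & home %in% subregion
  }
  if (!is.null(max_rank)) {
    rk <- vapply(kb$types, `[[`, integer(1), "rank")
    keep <- keep & !is.na(rk) & rk <= max_rank
  }
  sel_names <- nm[keep]
  projections <- Filter(function(p) p$pre %in% sel_names && p$post %in% sel_names,
                        kb$projections)
  structure(
    list(types = kb$types[keep],
         izhikevich = kb$izhikevich[sel_names],
         projections = projections),
    class = "kb_selection"
  )
}

#' Build a parameter bundle from a selection
#'
#' Assembles the two flat tables of the CSV dialect: a neuron-level table
#' (identity, rank, census and Izhikevich parameters) and a
#' connection-level table (probability, contacts, TPM constants, delay),
#' each numeric field accompanied by a `_src` provenance column
#' (`measured` or `default`). Missing projection fields are resolved from
#' the documented class and engine defaults when `resolve_defaults` is
#' TRUE; otherwise any unresolved field is an error.
#'
#' @param selection A [select_types()] result (or a whole kb).
#' @param resolve_defaults Fill missing connection fields (flagged
#'   `default`)?
#' @param seed Seed recorded in the manifest (provenance only).
#' @param description Free-text selection description for the manifest.
#' @return A `parameter_bundle`: list with `neurons` (data frame),
#'   `connections` (data frame), `manifest` (list).
#' @export
build_bundle <- function(selection, resolve_defaults = TRUE, seed = NA,
                         description = "") {
  types <- selection$types
  nm <- vapply(types, `[[`, character(1), "name")
  cls <- vapply(types, `[[`, character(1), "class")

  neurons <- data.frame(
    name = nm,
    subregion = vapply(types, `[[`, character(1), "home_subregion"),
    class = ifelse(cls == "excitatory", "e", "i"),
    code = vapply(types, function(t) encode_laminar_code(t$pattern),
                  character(1)),
    soma_layer = vapply(types, function(t)
      if (is.null(t$pattern$soma_parcel)) "" else t$pattern$soma_parcel,
      character(1)),
    projecting_parcels = vapply(types, function(t)
      paste(names(t$pattern$projecting), t$pattern$projecting,
            sep = ":", collapse = ";"), character(1)),
    rank = vapply(types, `[[`, integer(1), "rank"),
    stringsAsFactors = FALSE
  )
  neurons$census_count <- vapply(types, `[[`, numeric(1), "census_count")
  neurons$census_count_src <- ifelse(is.na(neurons$census_count),
                                     "default", "measured")
  izh <- selection$izhikevich
  for (f in c("C", "k", "v_r", "v_t", "v_peak", "v_min", "a", "b", "d")) {
    neurons[[f]] <- vapply(nm, function(x)
      if (is.null(izh[[x]])) NA_real_ else izh[[x]][[f]], numeric(1))
    neurons[[paste0(f, "_src")]] <- ifelse(is.na(neurons[[f]]),
                                           "default", "measured")
  }

  class_of <- stats::setNames(cls, nm)
  projections <- selection$projections
  conn_rows <- lapply(projections, function(pr) {
    if (resolve_defaults) {
      pr <- resolve_missing(pr, class_of[[pr$pre]], class_of[[pr$post]])
    }
    vals <- unlist(pr[.conn_num_fields])
    if (anyNA(vals)) {
      stop(sprintf("projection %s->%s has unresolved field(s): %s",
                   pr$pre, pr$post,
                   paste(.conn_num_fields[is.na(vals)], collapse = ", ")),
           call. = FALSE)
    }
    row <- data.frame(pre = pr$pre, post = pr$post, stringsAsFactors = FALSE)
    for (f in .conn_num_fields) {
      row[[f]] <- pr[[f]]
      row[[paste0(f, "_src")]] <- pr$provenance[[f]]
    }
    row
  })
  connections <- if (length(conn_rows) > 0L) do.call(rbind, conn_rows) else {
    empty <- data.frame(pre = character(), post = character(),
                        stringsAsFactors = FALSE)
    for (f in .conn_num_fields) {
      empty[[f]] <- numeric(0)
      empty[[paste0(f, "_src")]] <- character(0)
    }
    empty
  }

  bad <- setdiff(unique(c(connections$pre, connections$post)), neurons$name)
  if (length(bad) > 0L) {
    stop("connection endpoints missing from the neuron table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  structure(
    list(
      neurons = neurons,
      connections = connections,
      manifest = list(
        tool = "hippocircuit",
        version = as.character(utils::packageVersion("hippocircuit")),
        seed = seed,
        selection = description
      )
    ),
    class = "parameter_bundle"
  )
}

#' Export a parameter bundle to CSV files
#'
#' Writes `neurons.csv`, `connections.csv` and `manifest.yaml` into `dir`
#' with fixed column order, fixed float formatting and LF line endings:
#' identical bundles always export byte-identical files. An empty
#' selection produces headers-only tables with a warning.
#'
#' @param bundle A [build_bundle()] result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "parameter_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (nrow(bundle$neurons) == 0L) {
    warning("empty selection: exporting headers-only tables")
  }
  paths <- c(
    neurons = file.path(dir, "neurons.csv"),
    connections = file.path(dir, "connections.csv"),
    manifest = file.path(dir, "manifest.yaml")
  )
  write_csv_lf(bundle$neurons, paths[["neurons"]])
  write_csv_lf(bundle$connections, paths[["connections"]])
  man <- bundle$manifest
  man$seed <- if (is.numeric(man$seed) && !is.na(man$seed)) {
    as.integer(man$seed)
  } else if (is.character(man$seed) && !identical(man$seed, "unset")) {
    man$seed
  } else "unset"
  con <- file(paths[["manifest"]], open = "wb")
  writeLines(yaml::as.yaml(man), con, sep = "", useBytes = TRUE)
  close(con)
  invisible(paths)
}

#' Import a parameter bundle from CSV files
#'
#' Lossless inverse of [export_bundle()]: reconstructs the typed tables
#' and provenance flags. Unknown columns are kept out of the bundle but
#' reported; missing mandatory columns and malformed numerics are errors
#' naming the offender.
#'
#' @param dir Directory holding `neurons.csv`, `connections.csv`,
#'   `manifest.yaml`.
#' @return A `parameter_bundle` with an extra `diagnostics` character
#'   vector.
#' @export
import_bundle <- function(dir) {
  np <- file.path(dir, "neurons.csv")
  cp <- file.path(dir, "connections.csv")
  mp <- file.path(dir, "manifest.yaml")
  for (f in c(np, cp)) {
    if (!file.exists(f)) stop("missing bundle file: ", f, call. = FALSE)
  }
  diagnostics <- character(0)

  read_table <- function(path, mandatory, num_fields) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    missing <- setdiff(mandatory, names(df))
    if (length(missing) > 0L) {
      stop(basename(path), " lacks mandatory column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    known <- c(mandatory, num_fields, paste0(num_fields, "_src"))
    extra <- setdiff(names(df), known)
    if (length(extra) > 0L) {
      diagnostics <<- c(diagnostics, paste0(
        basename(path), ": ignoring unknown column(s) ",
        paste(extra, collapse = ", ")))
      df <- df[known[known %in% names(df)]]
    }
    for (f in intersect(num_fields, names(df))) {
      raw <- df[[f]]
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
      if (length(bad) > 0L) {
        stop(sprintf("%s line %d: malformed numeric in column %s: '%s'",
                     basename(path), bad[1L] + 1L, f, raw[bad[1L]]),
             call. = FALSE)
      }
      val[!nzchar(raw)] <- NA_real_
      df[[f]] <- val
    }
    df
  }

  neurons <- read_table(np,
    mandatory = c("name", "subregion", "class", "code", "soma_layer",
                  "projecting_parcels", "rank"),
    num_fields = .neuron_num_fields)
  neurons$rank <- as.integer(neurons$rank)
  connections <- read_table(cp, mandatory = c("pre", "post"),
                            num_fields = .conn_num_fields)
  manifest <- if (file.exists(mp)) yaml::read_yaml(mp) else list()

  out <- structure(
    list(neurons = neurons, connections = connections, manifest = manifest,
         diagnostics = diagnostics),
    class = "parameter_bundle"
  )
  if (length(diagnostics) > 0L) {
    for (d in diagnostics) warning(d, call. = FALSE)
  }
  out
}

#' Rebuild knowledge-base objects from an imported bundle
#'
#' Turns the flat tables of a [import_bundle()] result back into typed
#' objects: `neuron_type`s (with laminar patterns), per-type
#' [izhikevich_params()] and [projection_spec()]s with their provenance
#' flags.
#'
#' @param bundle A `parameter_bundle`.
#' @return A knowledge-base list (`types`, `izhikevich`, `projections`).
#' @export
bundle_to_kb <- function(bundle) {
  stopifnot(inherits(bundle, "parameter_bundle"))
  nd <- bundle$neurons
  types <- vector("list", nrow(nd))
  izh <- list()
  for (i in seq_len(nrow(nd))) {
    projecting <- character()
    if (nzchar(nd$projecting_parcels[i])) {
      parts <- strsplit(strsplit(nd$projecting_parcels[i], ";")[[1L]], ":")
      projecting <- stats::setNames(
        vapply(parts, `[`, character(1), 2L),
        vapply(parts, `[`, character(1), 1L))
    }
    pat <- parse_laminar_code(
      nd$code[i], nd$subregion[i],
      soma_parcel = if (nzchar(nd$soma_layer[i])) nd$soma_layer[i] else NULL,
      projecting = projecting)
    types[[i]] <- neuron_type(
      nd$name[i], pat,
      class = if (nd$class[i] == "e") "excitatory" else "inhibitory",
      census_count = nd$census_count[i], rank = nd$rank[i])
    if (!anyNA(unlist(nd[i, c("C", "k", "v_r", "v_t", "v_peak", "v_min",
                              "a", "b", "d")]))) {
      izh[[nd$name[i]]] <- izhikevich_params(
        C = nd$C[i], k = nd$k[i], v_r = nd$v_r[i], v_t = nd$v_t[i],
        v_peak = nd$v_peak[i], v_min = nd$v_min[i], a = nd$a[i],
        b = nd$b[i], d = nd$d[i])
    }
  }
  cd <- bundle$connections
  projections <- lapply(seq_len(nrow(cd)), function(i) {
    pr <- projection_spec(cd$pre[i], cd$post[i], p = cd$p[i],
                          n_contacts = cd$n_contacts[i], g = cd$g[i],
                          tau_d = cd$tau_d[i], tau_r = cd$tau_r[i],
                          tau_f = cd$tau_f[i], U = cd$U[i],
                          E_rev = cd$E_rev[i], delay = cd$delay[i])
    for (f in .conn_num_fields) {
      src_col <- paste0(f, "_src")
      if (src_col %in% names(cd) && nzchar(cd[[src_col]][i])) {
        pr$provenance[[f]] <- cd[[src_col]][i]
      }
    }
    pr
  })
  list(types = types, izhikevich = izh, projections = projections)
}
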