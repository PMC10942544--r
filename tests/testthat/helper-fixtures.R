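# Shared fixture builders. Everything is generated in code; no stored data.

# a valid random laminar pattern for a subregion
random_pattern <- function(subregion) {
  layers <- subregion_layers(subregion)
  digits <- sample(0:3, length(layers), replace = TRUE)
  parse_laminar_code(paste(digits, collapse = ""), subregion)
}

# a small set of neuron types with known codes for connectome tests
make_types <- function(codes, subregion = "DG", classes = NULL) {
  n <- length(codes)
  if (is.null(classes)) classes <- rep("inhibitory", n)
  lapply(seq_len(n), function(i) {
    neuron_type(paste0("T", i), parse_laminar_code(codes[i], subregion),
                class = classes[i])
  })
}

# independent brute-force potential-connectivity oracle: re-derives the
# axon/dendrite semantics from the digit codes without touching the
# package's state helpers
oracle_edges <- function(types) {
  out <- list()
  for (i in seq_along(types)) {
    for (j in seq_along(types)) {
      pre <- c(types[[i]]$pattern$presence, types[[i]]$pattern$projecting)
      post <- c(types[[j]]$pattern$presence, types[[j]]$pattern$projecting)
      shared <- intersect(names(pre), names(post))
      hit <- any(pre[shared] %in% c("AXON", "BOTH") &
                 post[shared] %in% c("DENDRITE", "BOTH"))
      if (hit) {
        out[[length(out) + 1L]] <- c(types[[i]]$name, types[[j]]$name)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(pre = character(), post = character()))
  }
  m <- do.call(rbind, out)
  data.frame(pre = m[, 1L], post = m[, 2L], stringsAsFactors = FALSE)
}

# sorted edge key for set comparison
edge_key <- function(df) sort(paste(df$pre, df$post, sep = "->"))

expect_close <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(abs(actual - expected)), tol)
}
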