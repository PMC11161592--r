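# internal helpers

resolve_product <- function(id, ids) {
  if (is.numeric(id)) {
    id <- as.integer(id)
    if (id < 1L || id > length(ids))
      stop("product index out of range", call. = FALSE)
    return(id)
  }
  i <- match(id, ids)
  if (is.na(i))
    stop(sprintf("unknown product '%s' (have: %s)", id,
                 paste(ids, collapse = ", ")), call. = FALSE)
  i
}

# unordered-pair key, e.g. "a|b" with a, b sorted
pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

config_error <- function(msg) {
  stop(structure(class = c("transcol_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

is_square_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && all(is.finite(m)) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}
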