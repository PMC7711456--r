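# internal numeric helpers

# row-wise log-sum-exp of a matrix
logsumexp_rows <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
  mx + log(rowSums(exp(m - mx)))
}

clip01 <- function(x) {       # preserves dim attributes, unlike pmin/pmax
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < 1)
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# draw n sub-seeds reproducibly from the current RNG stream; kept below 2^31
draw_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)
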