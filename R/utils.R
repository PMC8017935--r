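# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_kc <- function(..., class = "kincoop_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_kc(name, " must be a probability in [0, 1]",
            class = "kincoop_parameter_error")
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop_kc(name, " must be an integer >= ", min,
            class = "kincoop_parameter_error")
  invisible(as.integer(x))
}

# Deterministic per-stage child seeds fanned out from one global seed.
# Fixed offsets keep stages reproducible when rerun in isolation; kept
# below 2^31 - 1.
child_seed <- function(seed, stage) {
  offsets <- c(simulate = 1000L, relatedness = 2000L, traits = 3000L,
               fit = 4000L, meta = 5000L, path = 6000L, tree = 7000L)
  if (!stage %in% names(offsets))
    stop_kc("unknown pipeline stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

# One multivariate normal draw given a covariance Cholesky factor (upper).
rmvn_chol <- function(mu, chol_upper) {
  drop(mu + crossprod(chol_upper, rnorm(length(mu))))
}

# inverse-gamma draw parameterised by shape/rate
rinvgamma1 <- function(shape, rate) 1 / rgamma(1L, shape = shape, rate = rate)

read_tsv_kc <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

write_tsv_kc <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
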