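# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# FWHM of a Gaussian with standard deviation sigma
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

# Avogadro's number, 1/mol
N_AVOGADRO <- 6.02214076e23

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Gauss-Legendre nodes/weights on [a, b]; cached by order
gauss_legendre <- local({
  cache <- list()
  function(n, a = -1, b = 1) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      # Golub-Welsch: eigen-decomposition of the Jacobi matrix
      i <- seq_len(n - 1)
      beta <- i / sqrt(4 * i^2 - 1)
      J <- matrix(0, n, n)
      J[cbind(i, i + 1)] <- beta
      J[cbind(i + 1, i)] <- beta
      e <- eigen(J, symmetric = TRUE)
      x <- e$values
      w <- 2 * e$vectors[1, ]^2
      o <- order(x)
      cache[[key]] <<- list(x = x[o], w = w[o])
    }
    g <- cache[[key]]
    list(x = (b - a) / 2 * g$x + (a + b) / 2, w = (b - a) / 2 * g$w)
  }
})
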