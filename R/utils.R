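#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Order character strings byte-wise (C locale), deterministically
#' @noRd
c_order <- function(...) order(..., method = "radix")

#' Stop with a classed condition so tests can assert on error classes
#' @noRd
stop_langdx <- function(msg, class) {
  stop(structure(class = c(class, "langdx_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Validate a binary label vector
#' @noRd
check_binary_labels <- function(y, require_both = TRUE) {
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop_langdx("labels must be binary 0/1", "langdx_invalid_input")
  if (require_both && length(unique(y)) < 2L)
    stop_langdx("labels contain a single class", "langdx_degenerate_labels")
  y
}

#' Draw from a symmetric Dirichlet via normalized gammas
#' @noRd
rdirichlet_sym <- function(n, k, concentration) {
  g <- matrix(rgamma(n * k, shape = concentration), nrow = n)
  # guard against all-zero rows at tiny concentrations
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- rgamma(sum(zero) * k, shape = 1)
  g / rowSums(g)
}
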