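# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the state on exit, so no exported function leaks global RNG state.
#'
#' @param seed Integer seed, or `NULL` to evaluate without touching the RNG.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(structure(class = c("fetalvit_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("fetalvit_degenerate_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_invalid(arg, " must be a numeric matrix")
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop_invalid(arg, " must have at least one row and one column")
  if (!all(is.finite(img)))
    stop_invalid(arg, " contains non-finite intensities")
  invisible(img)
}

assert_normalized <- function(img, arg = "img", tol = 1e-8) {
  assert_image(img, arg)
  if (min(img) < -tol || max(img) > 1 + tol)
    stop_invalid(arg, " must be normalized to [0, 1]")
  invisible(img)
}

# Row-wise softmax with max-shift for numerical stability.
softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Recursive map over parallel nested lists of numeric arrays.  All trees must
# share the exact structure of the first.
nl_map <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1L]]
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- do.call(nl_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

nl_zeros_like <- function(tree) nl_map(function(x) x * 0, tree)

# Flatten a nested parameter list into a single named numeric vector
# (used by the finite-difference gradient checker and checkpoint hashing).
nl_flatten <- function(tree, prefix = "") {
  if (is.list(tree)) {
    nms <- names(tree) %||% as.character(seq_along(tree))
    out <- list()
    for (i in seq_along(tree)) {
      out[[i]] <- nl_flatten(tree[[i]], paste0(prefix, nms[i], "."))
    }
    do.call(c, out)
  } else {
    v <- as.numeric(tree)
    names(v) <- paste0(sub("\\.$", "", prefix), "[", seq_along(v), "]")
    v
  }
}

round2 <- function(x, digits) round(x + 0, digits)
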