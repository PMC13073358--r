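#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards. All package-internal randomness flows through this
# so that independent components (augmentation, rendering, init, shuffling)
# are reproducible given their derived seeds.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# Deterministic derived seed; keeps results below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 1000003 + as.double(p) %% 2147483647) %% 2147483647
  as.integer(s)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# ---- parameter-tree utilities ----------------------------------------------
# Model weights are nested named lists with numeric leaves (matrices/vectors).
# These recursions implement elementwise arithmetic over whole weight bundles;
# the optimizer and gradient accumulation are expressed through them.

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(x) tree_map(f, x)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_scale <- function(tree, s) tree_map(function(x) x * s, tree)

tree_n_params <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_n_params, numeric(1))) else length(tree)
}

tree_sum <- function(f, tree) {
  if (is.list(tree)) sum(vapply(tree, function(x) tree_sum(f, x), numeric(1))) else f(tree)
}
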