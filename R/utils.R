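#' @keywords internal
"_PACKAGE"

# Recursively apply f over the leaves (matrices/vectors) of a parameter tree.
tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(el) tree_map(f, el)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    stopifnot(length(x) == length(y))
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else {
    f(x, y)
  }
}

tree_zeros <- function(x) tree_map(function(el) el * 0, x)

tree_sum_sq <- function(x) {
  if (is.list(x)) sum(vapply(x, tree_sum_sq, numeric(1))) else sum(x^2)
}

# Adam optimizer state and update, operating on parameter trees.
adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map(function(m) m / bc1, state$m)
  vhat <- tree_map(function(v) v / bc2, state$v)
  upd <- tree_map2(function(m, v) lr * m / (sqrt(v) + eps), mhat, vhat)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

# Run an expression under a local RNG seed without disturbing the caller's
# random stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream label (stays < 2^31).
derive_seed <- function(seed, stream) {
  h <- fnv1a32(paste0(seed, "/", stream))
  as.integer(h %% 2147483647)
}

# Tiny FNV-1a hash over a string; used for manifests and seed derivation.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(as.character(x)))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  h
}

fnv1a32_hex <- function(x) {
  h <- fnv1a32(x)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten an n x T x D array to an (n*T) x D matrix (row = (patient, period)).
mat3 <- function(A) {
  d <- dim(A)
  dim(A) <- c(d[1L] * d[2L], d[3L])
  A
}

# Inverse of mat3.
arr3 <- function(M, n, Tt) {
  d3 <- ncol(M)
  dim(M) <- c(n, Tt, d3)
  M
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 0

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(x <= 1)
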