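# Internal helpers: seed streams, nested parameter containers, softmax.

# Deterministic sub-seed derivation. Every stochastic component draws from its
# own stream keyed by (purpose, epoch, step, ...), so adding or removing one
# source of randomness never shifts another (e.g. disabling the consistency
# branch leaves the supervised batch order untouched).
seed_for <- function(master, ...) {
  s <- as.double(master) %% 2147483647
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k) * 3121 + 7) %% 2147483647
  }
  as.integer(s)
}

# Run code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Nested numeric-leaf containers hold network parameters, gradients and
# optimizer state with identical shapes.
par_map <- function(p, f) {
  if (is.null(p)) NULL
  else if (is.list(p)) lapply(p, par_map, f = f)
  else f(p)
}

par_map2 <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    # out[i] <- list(v) keeps NULL placeholders instead of deleting them
    for (i in seq_along(a)) out[i] <- list(par_map2(a[[i]], b[[i]], f))
    out
  } else {
    f(a, b)
  }
}

par_count <- function(p) {
  if (is.null(p)) 0
  else if (is.list(p)) sum(vapply(p, par_count, numeric(1)))
  else length(p)
}

par_zeros <- function(p) par_map(p, function(x) x * 0)

par_add <- function(a, b, scale = 1) {
  par_map2(a, b, function(x, y) x + scale * y)
}

par_max_abs_diff <- function(a, b) {
  if (is.null(a)) return(0)
  if (is.list(a)) {
    if (length(a) == 0) return(0)
    max(vapply(seq_along(a), function(i) par_max_abs_diff(a[[i]], b[[i]]),
               numeric(1)))
  } else {
    if (length(a) == 0) 0 else max(abs(a - b))
  }
}

as_feature <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Softmax over the channel (third) dimension of an (h, w, C) array.
softmax3 <- function(z) cpp_softmax3(z)

# d(loss)/d(logits) given d(loss)/d(prob) and the softmax output.
softmax3_bwd <- function(p, gp) {
  C <- dim(p)[3]
  s <- p[, , 1] * gp[, , 1]
  if (C > 1) for (k in 2:C) s <- s + p[, , k] * gp[, , k]
  p * (gp - as.vector(s))
}

concat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2])
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
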