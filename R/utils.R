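# internal numeric helpers

# row-wise log(sum(exp(x))) without overflow
row_log_sum_exp <- function(x) {
  m <- x[, 1L]
  nc <- ncol(x)
  if (nc > 1L) for (j in 2:nc) m <- pmax(m, x[, j])
  m + log(rowSums(exp(x - m)))
}

clamp_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is left untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic per-stage child seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(k)) %% 2147483629)
}

# column index of cell (item, time) in the flat person x cell matrix;
# items vary fastest, matching names i<item>_t<time>
cell_index <- function(item, time, n_items) (time - 1L) * n_items + item

cell_names <- function(n_items, n_time) {
  as.vector(outer(seq_len(n_items), seq_len(n_time),
                  function(i, t) paste0("i", i, "_t", t)))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
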