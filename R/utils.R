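# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. `seed = NULL` uses the current stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible vector of sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_local_seed(seed, sample.int(.Machine$integer.max, n)))
}

stop_calwave <- function(class, msg, ...) {
  stop(structure(class = c(class, "calwave_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

warn_calwave <- function(class, msg, ...) {
  warning(structure(class = c(class, "calwave_warning", "warning", "condition"),
                    list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Logical membership indicator over 0-based half-open [start, end) intervals.
frames_in_intervals <- function(n_frames, starts, ends) {
  ind <- logical(n_frames)
  for (i in seq_along(starts)) {
    a <- max(0L, starts[i]); b <- min(n_frames, ends[i])
    if (b > a) ind[(a + 1L):b] <- TRUE
  }
  ind
}

# Merge possibly-overlapping 0-based half-open intervals into a disjoint,
# sorted set. `starts`/`ends` need not be sorted.
merge_intervals <- function(starts, ends) {
  if (length(starts) == 0L) return(data.frame(start = integer(), end = integer()))
  o <- order(starts, ends)
  s <- starts[o]; e <- ends[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
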