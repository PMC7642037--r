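# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so library functions stay pure from the caller's
#' point of view.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# stop() without the "Error in ..." call prefix; all user-facing validation
# errors go through this.
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

# scalar type checks -------------------------------------------------------

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort("'%s' must be a single finite number", name)
  }
  if (x < min || x > max) {
    abort("'%s' must be in [%s, %s], got %s", name, min, max, x)
  }
  x
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name, min = min)
  if (x != round(x)) abort("'%s' must be an integer, got %s", name, x)
  as.integer(x)
}

check_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort("'%s' must be a single string", name)
  }
  x
}

# Canonical edge ordering: gene_a < gene_b lexicographically.
canonicalize_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  swap <- edges$gene_a > edges$gene_b
  if (any(swap)) {
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
  }
  edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
}

# Fixed-format number rendering for TSV outputs so that identical results
# are byte-identical across runs.
format_num <- function(x, digits = 10L) {
  formatC(x, digits = digits, format = "g")
}
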