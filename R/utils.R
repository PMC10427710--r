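# internal helpers shared across modules

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be supplied", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s", name,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

as_xy_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2L)
    m <- x
  } else if (is.data.frame(x)) {
    check_columns(x, c("x", "y"), "point table")
    m <- cbind(x$x, x$y)
  } else {
    abort("points must be a two-column matrix or a data frame with x, y")
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) abort("coordinates must be finite")
  m
}

# derive a reproducible 32-bit sub-seed from a base seed and a stage tag
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
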