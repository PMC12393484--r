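# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with a temporary RNG seed
#'
#' All stochastic functions in the package take an explicit `seed`; when it is
#' `NULL` the session RNG stream is used unchanged.
#' @noRd
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# deterministic stream of child seeds, kept below 2^31
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %g.", name, lower))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %g.", name, lower))
  }
  if (x > upper) abort(sprintf("`%s` must be <= %g.", name, upper))
  invisible(x)
}

assert_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# feature-column helper: everything numeric that is not an id/label column
feature_columns <- function(tbl, exclude = c("cell_id", "condition",
                                             "center_id", "pool_size")) {
  cand <- setdiff(names(tbl), exclude)
  cand[vapply(tbl[cand], is.numeric, logical(1))]
}
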